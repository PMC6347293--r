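# Internal numerical helpers shared across modules.

# Cumulative integral of y(s) sampled on a uniform grid with step h.
# Corrected (Euler-Maclaurin) trapezoid: 4th-order for smooth integrands,
# exact for constant and linear y. Returns vector of same length, first
# element 0.
cumint <- function(y, h) {
  n <- length(y)
  if (n < 2L) return(rep(0, n))
  d <- finite_gradient(y, h)
  inc <- h / 2 * (y[-1L] + y[-n]) - h^2 / 12 * (d[-1L] - d[-n])
  c(0, cumsum(inc))
}

# Definite integral on a (possibly non-uniform) grid, plain trapezoid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

# Central-difference gradient with one-sided second-order stencils at the
# ends; x spacing h uniform.
finite_gradient <- function(y, h) {
  n <- length(y)
  if (n < 3L) return(c(diff(y) / h, diff(y) / h)[seq_len(n)])
  g <- numeric(n)
  g[2:(n - 1L)] <- (y[3:n] - y[1:(n - 2L)]) / (2 * h)
  g[1L] <- (-3 * y[1L] + 4 * y[2L] - y[3L]) / (2 * h)
  g[n] <- (3 * y[n] - 4 * y[n - 1L] + y[n - 2L]) / (2 * h)
  g
}

# Arc-length parameterisation of a planar polyline: cumulative chord length.
chord_lengths <- function(u, v) {
  c(0, cumsum(sqrt(diff(u)^2 + diff(v)^2)))
}

# Resample a planar curve given by points (u, v) at exactly equidistant arc
# positions `spacing` apart, using interpolating cubic splines in a
# chord-length parameter. One refinement pass converts chord-length to arc
# length so that consecutive point distances match `spacing` closely.
resample_curve <- function(u, v, spacing, n_refine = 2L) {
  t0 <- chord_lengths(u, v)
  fu <- stats::splinefun(t0, u, method = "fmm")
  fv <- stats::splinefun(t0, v, method = "fmm")
  tt <- t0
  for (i in seq_len(n_refine)) {
    # dense arc-length table along the current spline
    td <- seq(0, max(t0), length.out = max(20L * length(u), 2000L))
    ud <- fu(td); vd <- fv(td)
    ad <- chord_lengths(ud, vd)
    total <- ad[length(ad)]
    s_target <- seq(0, total, by = spacing)
    tt <- stats::approx(ad, td, xout = s_target, rule = 2)$y
  }
  list(u = fu(tt), v = fv(tt), t = tt)
}

# Per-replicate RNG seed derived from a master seed and replicate index,
# kept inside the 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 7919) %%
               2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
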