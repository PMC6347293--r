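# Shared fixtures, computed lazily once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# study-condition gradient and parameters
paper_gradient <- function() wall_gradient("pearson", 0.0362, 0.591, 16.81)
paper_params <- function(...) viscoplastic_params(P = 0.495, ...)

# analytic dome + cylinder reference profile (generator truth, defaults)
ref_profile <- function() {
  fixture("ref_profile", function() dome_profile())
}

# coarser reference for simulation tests
ref_profile_coarse <- function() {
  fixture("ref_profile_coarse", function() dome_profile(spacing = 0.15))
}

# default synthetic contour set (n = 17) and its derived average profile
ref_contours <- function() {
  fixture("ref_contours", function() make_contours(synth_spec(), seed = 421))
}

ref_avg_profile <- function() {
  fixture("ref_avg_profile", function() {
    mc <- ref_contours()
    series <- lapply(mc$contours, curvature_series)
    avg <- average_curvature_profile(series)
    list(series = series, avg = avg,
         profile = reconstruct_profile(avg, spacing = 0.05))
  })
}

# default synthetic thickness table (n = 2500) and its Pearson fit
ref_thickness <- function() {
  fixture("ref_thickness", function() {
    th <- make_thickness(synth_spec(), seed = 422)
    th$delta <- correct_thickness(th$a, th$w, 3.27)
    th
  })
}

ref_gradient_fit <- function() {
  fixture("ref_gradient_fit", function() fit_gradient(ref_thickness(),
                                                      "pearson"))
}

# analytic profiles for limit-identity tests
quarter_sphere <- function(R = 2, spacing = 0.01, frac = 0.95) {
  s <- seq(0, frac * pi * R / 2, by = spacing)
  reconstruct_profile(s, rep(1 / R, length(s)), spacing = spacing)
}

sphere_cylinder <- function(R = 2, shank = 10, spacing = 0.01) {
  s <- seq(0, pi * R / 2 + shank, by = spacing)
  kap <- ifelse(s <= pi * R / 2, 1 / R, 0)
  reconstruct_profile(s, kap, spacing = spacing)
}

# circle sample for contour-level tests
circle_points <- function(R = 3, by = 0.2, jitter = 0, seed = 1,
                          arc = c(0.1, pi - 0.1)) {
  set.seed(seed)
  th <- seq(arc[1L], arc[2L], by = by / R)
  rr <- R + rnorm(length(th), 0, jitter)
  cbind(u = rr * cos(th), v = rr * sin(th))
}
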