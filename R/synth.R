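# Synthetic-data generators. Every input the analysis pipeline consumes can
# be produced here with known ground truth; defaults reproduce the study
# conditions of the Ectocarpus apical cell (radius 3.27 um, Pearson
# thickness gradient 36.2 nm / 591 nm / 16.81 um, turgor 0.495 MPa, tip
# speed 2.5 um/h).

#' Default synthetic-data specification
#'
#' A nested list of generator settings with the study conditions as
#' defaults. Override individual entries by passing replacements, e.g.
#' `synth_spec(contour = list(n_cells = 5))` (unnamed entries keep their
#' defaults).
#'
#' @param ... Named sublists merged over the defaults.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(...) {
  spec <- list(
    contour = list(radius = 3.27, tip_curvature = 0.40, length = 60,
                   trace_spacing = 0.25, jitter_sd = 0.03, shape_sd = 0.03,
                   n_cells = 17, spacing = 0.05),
    thickness = list(delta_min = 0.0362, delta_max = 0.591, s_half = 16.81,
                     family = "pearson", R = 3.27, n = 2500, n_cells = 15,
                     s_max = 70, offset_sd = 0.4, offset_max_frac = 0.8,
                     noise_sdlog = 0.05),
    plasmolysis = list(c_pl = 1980, width = 0.08,
                       osmolarities = round(seq(1300, 2900,
                                                length.out = 10)),
                       n_per = 200, n_experiments = 3),
    turgor = list(shrink = 0.658, c_sea = 1100),
    beads = list(v_tip = 2.5 / 60, n_beads = 20, n_frames = 10, dt = 15,
                 angle_noise_sd = 0.1, substeps = 20),
    frap = list(zone_s = c(A = 1, B = 3, C = 5, D = 8, E = 15),
                tau = c(A = 30, B = 20, C = 10, D = 18, E = 25),
                alpha = c(A = 1, B = 1, C = 1, D = 1, E = 1),
                n_traces = 9, t_pre = 6, t_post = 50, background = 50,
                bg_drift = 0.02, unbleached0 = 500, bleach_tau = 200,
                residual = 20, noise_sd = 2),
    params = list(P = 0.495, v_tip = 2.5 / 60, nu = 0.5, K = 1)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(spec)) stop("unknown synth_spec section: ", nm)
    for (k in names(over[[nm]])) spec[[nm]][[k]] <- over[[nm]][[k]]
  }
  structure(spec, class = "synth_spec")
}

#' Analytic dome-plus-cylinder meridional profile
#'
#' Builds a smooth convex dome blending into a cylinder of the requested
#' radius. The meridional curvature follows a generalized-Gaussian bump,
#' `kappa_s(s) = kappa_tip * exp(-(s / s_d)^p)`, whose scale `s_d` is fixed
#' by the quarter-turn condition (total turning angle pi/2) and whose shape
#' exponent `p` is solved so that the asymptotic radius equals `radius`.
#' Tip curvature above `1/radius` gives a tip sharper than a hemisphere, as
#' observed for the alga.
#'
#' @param radius Shank (cylinder) radius, um.
#' @param tip_curvature Meridional curvature at the tip, um^-1 (must exceed
#'   `1/radius`).
#' @param length Meridional length of the profile, um.
#' @param spacing Grid spacing, um.
#' @return A `meridional_profile`.
#' @export
dome_profile <- function(radius = 3.27, tip_curvature = 0.40, length = 60,
                         spacing = 0.05) {
  if (tip_curvature * radius <= 1.001)
    stop("tip_curvature must exceed 1/radius (dome sharper than hemisphere)")
  kfun <- function(s, p) {
    s_d <- (pi / 2) / (tip_curvature * gamma(1 + 1 / p))
    tip_curvature * exp(-(s / s_d)^p)
  }
  end_radius <- function(p) {
    s <- seq(0, length, by = spacing)
    phi <- cumint(kfun(s, p), spacing)
    r <- cumint(cos(phi), spacing)
    r[base::length(r)]
  }
  f <- function(p) end_radius(p) - radius
  lo <- 1.05; hi <- 50
  if (f(lo) < 0 || f(hi) > 0)
    stop("no dome shape with this tip curvature reaches radius ", radius)
  p <- stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  s <- seq(0, length, by = spacing)
  reconstruct_profile(s, kfun(s, p), spacing = spacing)
}

# Two-sided (u, v) contour polyline from a half-meridian profile: u lateral
# (signed radius), v axial with the tip at the top.
profile_to_contour <- function(profile) {
  u <- c(-rev(profile$r[-1L]), profile$r)
  v <- c(rev(profile$x[-1L]), profile$x)
  # outward normal in (u, v): axial component cos(phi), lateral sin(phi)
  nu_ <- c(-rev(sin(profile$phi[-1L])), sin(profile$phi))
  nv_ <- c(rev(cos(profile$phi[-1L])), cos(profile$phi))
  list(u = u, v = v, nu = nu_, nv = nv_,
       s = c(-rev(profile$s[-1L]), profile$s))
}

#' Generate jittered traced contours with known truth
#'
#' Each synthetic cell is the analytic dome-plus-cylinder contour, with a
#' per-cell smooth shape perturbation (log-normal factor on the tip
#' curvature, sd `shape_sd`) and Gaussian tracing jitter applied normal to
#' the contour, sampled at the hand-tracing point distance.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed (mandatory; generators have no implicit
#'   randomness).
#' @return List with `contours` (list of `raw_contour`) and `truth` (the
#'   unperturbed `meridional_profile`).
#' @export
make_contours <- function(spec = synth_spec(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  cs <- spec$contour
  truth <- dome_profile(cs$radius, cs$tip_curvature, cs$length, cs$spacing)
  contours <- vector("list", cs$n_cells)
  for (i in seq_len(cs$n_cells)) {
    kfac <- exp(stats::rnorm(1, 0, cs$shape_sd))
    prof <- if (cs$shape_sd > 0)
      dome_profile(cs$radius, cs$tip_curvature * kfac, cs$length,
                   cs$spacing) else truth
    ct <- profile_to_contour(prof)
    idx <- seq(1L, length(ct$u),
               by = max(1L, round(cs$trace_spacing / cs$spacing)))
    eps <- stats::rnorm(length(idx), 0, cs$jitter_sd)
    pts <- cbind(u = ct$u[idx] + eps * ct$nu[idx],
                 v = ct$v[idx] + eps * ct$nv[idx])
    contours[[i]] <- raw_contour(sprintf("cell_%02d", i), pts)
  }
  list(contours = contours, truth = truth)
}

#' Generate apparent TEM thickness measurements with known truth
#'
#' For each measured point, the true thickness comes from the gradient; a
#' per-cell section offset `d` from the meridional plane then inflates the
#' apparent thickness through the circle-chord geometry
#' (`a = sqrt((R - delta)^2 - d^2)`, `w = sqrt(R^2 - d^2) - a`), and
#' multiplicative log-normal noise is applied to `w`. The construction is
#' exactly inverted by [correct_thickness()] in the noise-free case.
#'
#' @inheritParams make_contours
#' @return Data frame with columns `cell_id`, `s` (signed, um), `w`, `a`,
#'   `d`, `delta_true` (um); the generating `wall_gradient` is attached as
#'   attribute `truth`.
#' @export
make_thickness <- function(spec = synth_spec(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  ts <- spec$thickness
  g <- wall_gradient(ts$family, ts$delta_min, ts$delta_max, ts$s_half)
  per_cell <- diff(round(seq(0, ts$n, length.out = ts$n_cells + 1L)))
  rows <- vector("list", ts$n_cells)
  for (i in seq_len(ts$n_cells)) {
    n_i <- per_cell[i]
    s <- stats::runif(n_i, -ts$s_max, ts$s_max)
    delta <- evaluate_gradient(g, s)
    d_cap <- ts$offset_max_frac * (ts$R - max(delta))
    d <- min(abs(stats::rnorm(1, 0, ts$offset_sd)), d_cap)
    a <- sqrt((ts$R - delta)^2 - d^2)
    w <- sqrt(ts$R^2 - d^2) - a
    w <- w * exp(stats::rnorm(n_i, 0, ts$noise_sdlog))
    w <- pmin(w, ts$R - a)   # keep the section inside the cell
    rows[[i]] <- data.frame(cell_id = sprintf("tem_%02d", i), s = s, w = w,
                            a = a, d = d, delta_true = delta)
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- g
  out
}

#' Generate a plasmolysis count table with known limit osmolarity
#'
#' Binomial counts with plasmolysis probability logistic in `log(c_e)`
#' around the true `c_pl`.
#'
#' @inheritParams make_contours
#' @return Data frame with columns `experiment_id`, `c_e`, `n_total`,
#'   `n_plasmolyzed`; true `c_pl` attached as attribute `truth`.
#' @export
make_plasmolysis <- function(spec = synth_spec(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  ps <- spec$plasmolysis
  rows <- list()
  for (e in seq_len(ps$n_experiments)) {
    p <- if (ps$width == 0) as.numeric(ps$osmolarities >= ps$c_pl) else
      stats::plogis((log(ps$osmolarities) - log(ps$c_pl)) / ps$width)
    k <- stats::rbinom(length(p), ps$n_per, p)
    rows[[e]] <- data.frame(experiment_id = sprintf("exp_%d", e),
                            c_e = ps$osmolarities, n_total = ps$n_per,
                            n_plasmolyzed = k)
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- ps$c_pl
  out
}

#' Generate surface-bead tracks advected by normal growth
#'
#' Beads ride on a self-similarly translating contour: between frames each
#' bead is advected along the local outward normal at the local normal
#' velocity `v_tip cos(phi)` (many small substeps), so that the true angle
#' between trajectory and contour is pi/2 everywhere. Optional angular
#' noise rotates each recorded displacement.
#'
#' @inheritParams make_contours
#' @return List with `tracks` (data frame `bead_id`, `t`, `u`, `v`),
#'   `contours` (list of per-frame two-column point matrices), `times`, and
#'   `truth` (the underlying profile and v_tip).
#' @export
make_beads <- function(spec = synth_spec(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  bs <- spec$beads
  cs <- spec$contour
  prof <- dome_profile(cs$radius, cs$tip_curvature, cs$length, cs$spacing)
  ct <- profile_to_contour(prof)
  times <- (seq_len(bs$n_frames) - 1L) * bs$dt
  # initial bead arc positions spread over the dome, both sides
  s0 <- stats::runif(bs$n_beads, 0.3, 4.5) *
    sample(c(-1, 1), bs$n_beads, replace = TRUE)
  idx0 <- vapply(s0, function(s) which.min(abs(ct$s - s)), integer(1))
  pos <- cbind(ct$u[idx0], ct$v[idx0])
  # project a lab point (after removing the translation) back on the contour
  project <- function(p, shift) {
    q <- c(p[1L], p[2L] - shift)
    which.min((ct$u - q[1L])^2 + (ct$v - q[2L])^2)
  }
  sub_dt <- bs$dt / bs$substeps
  true_pos <- array(NA_real_, c(bs$n_beads, 2L, length(times)))
  true_pos[, , 1L] <- pos
  for (f in seq_along(times)[-length(times)]) {
    for (k in seq_len(bs$substeps)) {
      t_now <- times[f] + (k - 1L) * sub_dt
      shift <- bs$v_tip * t_now
      for (b in seq_len(bs$n_beads)) {
        i <- project(pos[b, ], shift)
        vn <- bs$v_tip * ct$nv[i]   # v_tip * cos(phi)
        pos[b, ] <- pos[b, ] + vn * sub_dt * c(ct$nu[i], ct$nv[i])
      }
    }
    true_pos[, , f + 1L] <- pos
  }
  # measurement noise: rotate each recorded inter-frame displacement
  meas <- true_pos
  for (b in seq_len(bs$n_beads)) {
    for (f in seq_along(times)[-length(times)]) {
      d <- true_pos[b, , f + 1L] - true_pos[b, , f]
      th <- if (bs$angle_noise_sd > 0)
        stats::rnorm(1, 0, bs$angle_noise_sd) else 0
      rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
      meas[b, , f + 1L] <- meas[b, , f] + as.numeric(rot %*% d)
    }
  }
  tracks <- list()
  for (f in seq_along(times)) {
    for (b in seq_len(bs$n_beads)) {
      tracks[[length(tracks) + 1L]] <-
        data.frame(bead_id = sprintf("bead_%02d", b), t = times[f],
                   u = meas[b, 1L, f], v = meas[b, 2L, f])
    }
  }
  contours <- lapply(times, function(t)
    cbind(u = ct$u, v = ct$v + bs$v_tip * t))
  list(tracks = do.call(rbind, tracks), contours = contours, times = times,
       truth = list(profile = prof, v_tip = bs$v_tip, angle = pi / 2))
}

#' Generate FRAP traces with known recovery parameters
#'
#' The bleached-zone raw signal is constructed as background plus a frozen
#' post-bleach residual plus newly delivered fluorophore that photobleaches
#' with imaging at the same relative rate as the unbleached reference, so
#' that the standard background/acquisition correction recovers the clean
#' recovery curve `alpha (1 - exp(-t/tau))` exactly in the noise-free case.
#'
#' @inheritParams make_contours
#' @return Data frame with columns `zone`, `trace`, `t` (s), `intensity`,
#'   `background1..4`, `unbleached`; per-zone truth (`tau`, `alpha`)
#'   attached as attribute `truth`.
#' @export
make_frap <- function(spec = synth_spec(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  fs <- spec$frap
  t <- c(-(fs$t_pre:1), 0:fs$t_post)
  zones <- names(fs$zone_s)
  rows <- list()
  for (z in zones) {
    for (tr in seq_len(fs$n_traces)) {
      z0 <- fs$background
      Z <- z0 + fs$bg_drift * (t - min(t))
      U <- Z + (fs$unbleached0 - z0) * exp(-(t - min(t)) / fs$bleach_tau)
      i0 <- which(t == 0)
      gfac <- (U - Z) / (U[i0] - Z[i0])
      Y <- ifelse(t < 0, NA_real_,
                  fs$alpha[[z]] * fs$unbleached0 *
                    (1 - exp(-t / fs$tau[[z]])) / 10)
      A <- ifelse(t < 0,
                  Z + (fs$unbleached0 - z0) * 0.9 * gfac,
                  Z + fs$residual + Y * gfac)
      noise <- function(x) x + stats::rnorm(length(x), 0, fs$noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        zone = z, trace = tr, t = t,
        intensity = noise(A),
        background1 = noise(Z), background2 = noise(Z),
        background3 = noise(Z), background4 = noise(Z),
        unbleached = noise(U))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(tau = fs$tau,
                             alpha = fs$alpha * fs$unbleached0 / 10,
                             zone_s = fs$zone_s)
  out
}

#' Perturbed gradients and initial shapes for simulation experiments
#'
#' `steep`/`gentle` scale the midpoint `s_half` of a `wall_gradient` by
#' `(1 -/+ magnitude)`; `flat`/`sharp` rebuild a dome profile with the tip
#' curvature scaled by `(1 -/+ magnitude)` while keeping the same shank
#' radius.
#'
#' @param obj A `wall_gradient` (for `steep`/`gentle`) or a
#'   `meridional_profile` built by [dome_profile()] (for `flat`/`sharp`).
#' @param kind One of `"steep"`, `"gentle"`, `"flat"`, `"sharp"`.
#' @param magnitude Relative change (default 0.2).
#' @param spec A [synth_spec()] supplying the dome geometry for profile
#'   variants.
#' @return Object of the same class as `obj`.
#' @export
make_variants <- function(obj, kind = c("steep", "gentle", "flat", "sharp"),
                          magnitude = 0.2, spec = synth_spec()) {
  kind <- match.arg(kind)
  if (kind %in% c("steep", "gentle")) {
    stopifnot(inherits(obj, "wall_gradient"))
    fac <- if (kind == "steep") 1 - magnitude else 1 + magnitude
    wall_gradient(obj$family, obj$delta_min, obj$delta_max,
                  obj$s_half * fac, rse = obj$rse)
  } else {
    stopifnot(inherits(obj, "meridional_profile"))
    fac <- if (kind == "flat") 1 - magnitude else 1 + magnitude
    if (magnitude == 0) return(obj)
    dome_profile(radius = obj$r[nrow(obj)],
                 tip_curvature = obj$kappa_s[1L] * fac,
                 length = max(obj$s), spacing = attr(obj, "spacing"))
  }
}
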