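# Forward simulation of viscoplastic tip growth: normal displacement of a
# discretized meridian under the Lockhart flow rule, with the wall thickness
# gradient anchored at the moving tip, self-similarity scoring and parameter
# optimization.

#' Simulation configuration
#'
#' @param params A [viscoplastic_params()] with `Phi` and `sigma_y` set.
#' @param gradient A `wall_gradient`; thickness is evaluated as a function
#'   of arc distance from the *current* tip at every step (the thickness
#'   field travels with the tip).
#' @param spacing Point spacing of the discretized meridian, um.
#' @param tip_step Tip advance per inner step, um (1 nm default).
#' @param record_every Tip advance between recorded frames, um (`Inf`
#'   records only the first and last frames).
#' @param target_distance Total tip advance, um.
#' @param rd_half_width Half-weight scale of the dome-focused residual
#'   weight, um.
#' @param max_steps Safety cap on inner steps.
#' @param max_time Cap on simulated biological time, min; runs slower than
#'   this are reported as (practically) stalled. Defaults to six times the
#'   time self-similar growth would need to cover `target_distance`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(params, gradient, spacing = 0.05, tip_step = 0.001,
                       record_every = 0.04, target_distance = 25,
                       rd_half_width = 1,
                       max_steps = ceiling(4 * target_distance / tip_step),
                       max_time = 6 * target_distance / params$v_tip) {
  stopifnot(inherits(params, "viscoplastic_params"),
            inherits(gradient, "wall_gradient"),
            is.finite(params$Phi), is.finite(params$sigma_y),
            spacing > 0, tip_step > 0,
            tip_step <= record_every, record_every <= target_distance ||
              is.infinite(record_every))
  structure(list(params = params, gradient = gradient, spacing = spacing,
                 tip_step = tip_step, record_every = record_every,
                 target_distance = target_distance,
                 rd_half_width = rd_half_width, max_steps = max_steps,
                 max_time = max_time),
            class = "sim_config")
}

# Binomial (1/4, 1/2, 1/4) filter with mirror symmetry at the tip; kills
# grid-scale oscillation while leaving smooth features O(h^2)-accurate.
binomial_filter <- function(y, passes = 2L, mirror_first = TRUE) {
  n <- length(y)
  for (k in seq_len(passes)) {
    ym <- if (mirror_first) y[2L] else y[1L]   # kappa(-h) = kappa(h)
    left <- c(ym, y[-n])
    right <- c(y[-1L], y[n])
    y <- 0.25 * left + 0.5 * y + 0.25 * right
  }
  y
}

# Geometry of a discretized half-meridian given as equidistant points
# (x axial, r radial, tip first at r = 0). phi is computed from central
# differences with the tip mirrored across the axis; kappa_s = dphi/ds,
# lightly filtered at grid scale for front-tracking stability.
discrete_geometry <- function(x, r, h) {
  n <- length(x)
  dx <- numeric(n); dr <- numeric(n)
  dx[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * h)
  dr[2:(n - 1L)] <- (r[3:n] - r[1:(n - 2L)]) / (2 * h)
  dx[1L] <- 0                       # mirrored tip: (x2, -r2)
  dr[1L] <- r[2L] / h
  dx[n] <- (3 * x[n] - 4 * x[n - 1L] + x[n - 2L]) / (2 * h)
  dr[n] <- (3 * r[n] - 4 * r[n - 1L] + r[n - 2L]) / (2 * h)
  nrm <- sqrt(dx^2 + dr^2)
  phi <- atan2(-dx / nrm, dr / nrm)
  kap <- numeric(n)
  kap[2:(n - 1L)] <- (phi[3:n] - phi[1:(n - 2L)]) / (2 * h)
  kap[1L] <- phi[2L] / h            # mirrored tip: phi(-s) = -phi(s)
  kap[n] <- (3 * phi[n] - 4 * phi[n - 1L] + phi[n - 2L]) / (2 * h)
  kap <- binomial_filter(kap)
  ktheta <- numeric(n)
  ktheta[1L] <- kap[1L]
  ktheta[-1L] <- sin(phi[-1L]) / r[-1L]
  ktheta <- binomial_filter(ktheta)
  list(phi = phi, kappa_s = kap, kappa_theta = ktheta)
}

# Normal velocity of the wall under the Lockhart flow rule:
# V_n = Phi (sigma_e - sigma_y) (sigma_theta - nu sigma_s) /
#       (sigma_e kappa_theta) where sigma_e > sigma_y, else 0.
flow_normal_velocity <- function(geom, delta, params) {
  P <- params$P; nu <- params$nu
  kt <- geom$kappa_theta
  sigma_s <- P / (2 * delta * kt)
  sigma_theta <- P * (2 * kt - geom$kappa_s) / (2 * delta * kt^2)
  sigma_e <- effective_stress(sigma_s, sigma_theta, nu)
  vn <- numeric(length(kt))
  yld <- sigma_e > params$sigma_y
  vn[yld] <- params$Phi * (sigma_e[yld] - params$sigma_y) *
    (sigma_theta[yld] - nu * sigma_s[yld]) / (sigma_e[yld] * kt[yld])
  binomial_filter(vn, passes = 1L)
}

# One inner step: advance the tip by tip_step via normal displacement, then
# refit an interpolating cubic spline and resample at constant spacing.
# Because the normal velocity responds diffusively to curvature
# perturbations (a sharper apex is slower), the explicit displacement is
# broken into substeps respecting the parabolic stability limit
# dt <= safety * h^2 / max|dV_n/dkappa_s|.
growth_step <- function(x, r, cfg, safety = 0.4, time_budget = Inf) {
  h <- cfg$spacing
  s <- (seq_along(x) - 1L) * h
  delta <- evaluate_gradient(cfg$gradient, s)
  advance <- 0
  elapsed <- 0
  dt_stab <- NA_real_
  repeat {
    if (elapsed > time_budget)
      return(list(stalled = TRUE, x = x, r = r, dt = elapsed))
    g <- discrete_geometry(x, r, h)
    vn <- flow_normal_velocity(g, delta, cfg$params)
    if (vn[1L] <= 0)
      return(list(stalled = TRUE, x = x, r = r, dt = NA_real_))
    if (is.na(dt_stab)) {   # curvature response varies slowly: once per step
      eps <- 1e-4
      g2 <- g
      g2$kappa_s <- g$kappa_s + eps
      c_hat <- max(abs(flow_normal_velocity(g2, delta, cfg$params) -
                         vn)) / eps
      dt_stab <- safety * h^2 / max(c_hat, 1e-12)
    }
    dt <- min(dt_stab, (cfg$tip_step - advance) / vn[1L])
    x <- x + vn * dt * cos(g$phi)
    r <- r + vn * dt * sin(g$phi)
    r[1L] <- 0
    advance <- advance + vn[1L] * dt
    elapsed <- elapsed + dt
    if (advance >= cfg$tip_step * (1 - 1e-9)) break
  }
  xn <- x; rn <- r
  dt <- elapsed
  if (any(diff(xn[-(1:3)]) > h * 1e-4))
    stop("geometry failure: contour self-intersects (non-monotone x)")
  # mirror a few points across the axis so the tip is interior to the
  # interpolating spline (no end-condition artefact at the apex)
  m <- 4L
  xe <- c(rev(xn[2:(m + 1L)]), xn)
  re <- c(-rev(rn[2:(m + 1L)]), rn)
  tt <- chord_lengths(xe, re)
  fx <- stats::splinefun(tt, xe, method = "fmm")
  fr <- stats::splinefun(tt, re, method = "fmm")
  t_tip <- tt[m + 1L]
  sg <- seq(t_tip, tt[length(tt)], by = h)
  rr <- fr(sg); rr[1L] <- 0
  list(stalled = FALSE, x = fx(sg), r = pmax(rr, 0), dt = dt)
}

#' Simulate viscoplastic tip growth
#'
#' Repeats [sim_config()]-calibrated growth steps until the tip has advanced
#' by `target_distance`, recording frames every `record_every` of tip
#' advance and accumulating elapsed biological time.
#'
#' @param initial A `meridional_profile` extending well past the dome.
#' @param cfg A `sim_config`.
#' @return A `sim_result` list with elements `frames` (list of two-column
#'   `x`,`r` matrices), `frame_times` (min), `tip_positions` (um),
#'   `elapsed` (min), `advance` (um), `initial`, `final`, `stalled`.
#' @export
simulate_tip_growth <- function(initial, cfg) {
  h <- cfg$spacing
  x <- initial$x; r <- initial$r
  x0_tip <- x[1L]
  frames <- list(cbind(x = x, r = r))
  frame_times <- 0
  tip_positions <- x[1L]
  elapsed <- 0
  next_record <- cfg$record_every
  stalled <- FALSE
  for (it in seq_len(cfg$max_steps)) {
    st <- growth_step(x, r, cfg, time_budget = cfg$max_time - elapsed)
    if (st$stalled) { stalled <- TRUE; break }
    x <- st$x; r <- st$r
    elapsed <- elapsed + st$dt
    adv <- x[1L] - x0_tip
    if (adv >= next_record - 1e-12 && is.finite(cfg$record_every)) {
      frames[[length(frames) + 1L]] <- cbind(x = x, r = r)
      frame_times <- c(frame_times, elapsed)
      tip_positions <- c(tip_positions, x[1L])
      next_record <- next_record + cfg$record_every
    }
    if (adv >= cfg$target_distance - 1e-12) break
  }
  final <- cbind(x = x, r = r)
  if (!identical(frames[[length(frames)]], final)) {
    frames[[length(frames) + 1L]] <- final
    frame_times <- c(frame_times, elapsed)
    tip_positions <- c(tip_positions, x[1L])
  }
  structure(list(frames = frames, frame_times = frame_times,
                 tip_positions = tip_positions, elapsed = elapsed,
                 advance = x[1L] - x0_tip,
                 initial = frames[[1L]], final = final, spacing = h,
                 stalled = stalled, config = cfg),
            class = "sim_result")
}

#' Dome-weighted residual distance between two meridional shapes
#'
#' Pairs points sharing the same meridional abscissa s (measured from each
#' shape's own tip), translates the reference axially and averages the
#' planar point-to-point distances with the dome-focused weight
#' `w(s) = exp(-(s / half_width)^2 ln 2)`.
#'
#' @param final,reference Two-column `x`,`r` matrices of equidistant points
#'   (tip first), or `meridional_profile` objects on the same spacing.
#' @param translation Axial translation applied to the reference, um.
#' @param half_width Half-weight abscissa of the weight, um.
#' @param spacing Point spacing shared by the two shapes, um.
#' @return List with `rD` (um) and `log_rD` (natural log; `-Inf` when
#'   `rD = 0`).
#' @export
residual_distance <- function(final, reference, translation = 0,
                              half_width = 1, spacing = 0.05) {
  as_xy <- function(p) {
    if (inherits(p, "meridional_profile")) cbind(x = p$x, r = p$r)
    else as.matrix(p)
  }
  a <- as_xy(final); b <- as_xy(reference)
  n <- min(nrow(a), nrow(b))
  if (n < 2L) stop("no overlap between the two shapes")
  s <- (seq_len(n) - 1L) * spacing
  d <- sqrt((a[seq_len(n), 1L] - (b[seq_len(n), 1L] + translation))^2 +
              (a[seq_len(n), 2L] - b[seq_len(n), 2L])^2)
  w <- exp(-(s / half_width)^2 * log(2))
  rD <- sum(w * d) / sum(w)
  list(rD = rD, log_rD = if (rD > 0) log(rD) else -Inf)
}

# Self-similarity objective: run a full simulation and compare the final
# shape to the initial one translated at the expected speed (v_tip times
# the elapsed time), so that both shape distortion and growth-rate error
# are penalized.
selfsim_objective <- function(initial, cfg) {
  sim <- try(simulate_tip_growth(initial, cfg), silent = TRUE)
  if (inherits(sim, "try-error")) return(Inf)
  if (sim$stalled) return(Inf)
  rd <- residual_distance(sim$final, sim$initial,
                          translation = cfg$params$v_tip * sim$elapsed,
                          half_width = cfg$rd_half_width,
                          spacing = cfg$spacing)
  rd$log_rD
}

#' Optimize the plasticity parameters for self-similar growth
#'
#' Steepest descent on `log(rD)` of a full target-distance simulation, in
#' (log Phi, log sigma_y) space, starting from the Lockhart-regression
#' estimates. Probe steps are fixed in log space (deterministic order: Phi
#' then sigma_y) with backtracking halving of the line-search step.
#'
#' @param initial A `meridional_profile`.
#' @param cfg A `sim_config`; its `params$Phi` / `params$sigma_y` are
#'   ignored in favour of `start`.
#' @param start Numeric `c(Phi, sigma_y)` starting values.
#' @param step0 Initial line-search step in natural-log parameter space.
#' @param probe Finite-difference probe step in log space.
#' @param tol Relative convergence tolerance on both parameters.
#' @param max_iter Maximum descent iterations.
#' @param quiet Suppress progress output.
#' @return List with `Phi`, `sigma_y`, `log_rD`, `n_eval`, `converged`.
#' @export
optimize_parameters <- function(initial, cfg, start, step0 = 0.15,
                                probe = 0.02, tol = 1e-3, max_iter = 40,
                                quiet = TRUE) {
  n_eval <- 0L
  fz <- function(z) {
    n_eval <<- n_eval + 1L
    p <- cfg$params
    p$Phi <- exp(z[1L]); p$sigma_y <- exp(z[2L])
    cfg$params <- p
    selfsim_objective(initial, cfg)
  }
  z <- log(start)
  f0 <- fz(z)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- c(fz(z + c(probe, 0)) - f0,
           fz(z + c(0, probe)) - f0) / probe
    gn <- sqrt(sum(g^2))
    if (!is.finite(gn) || gn < 1e-10) { converged <- TRUE; break }
    dir <- -g / gn
    lam <- step0
    improved <- FALSE
    while (lam >= tol) {
      f1 <- fz(z + lam * dir)
      if (f1 < f0 - 1e-12) {
        z <- z + lam * dir; f0 <- f1; improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!quiet)
      message(sprintf("iter %d: logPhi=%.4f logSy=%.4f log_rD=%.4f",
                      it, z[1L], z[2L], f0))
    if (!improved || lam < tol) { converged <- TRUE; break }
  }
  list(Phi = exp(z[1L]), sigma_y = exp(z[2L]), log_rD = f0,
       n_eval = n_eval, converged = converged)
}

#' Grid scan of the self-similarity objective
#'
#' One full simulation per (Phi, sigma_y) grid cell; stalled simulations
#' are recorded as `+Inf`.
#'
#' @param initial A `meridional_profile`.
#' @param cfg A `sim_config`.
#' @param phi_grid,sigma_y_grid Parameter grids.
#' @return Matrix of `log(rD)` with rows indexed by `phi_grid` and columns
#'   by `sigma_y_grid` (dimnames carry the values).
#' @export
scan_parameters <- function(initial, cfg, phi_grid, sigma_y_grid) {
  out <- matrix(NA_real_, length(phi_grid), length(sigma_y_grid),
                dimnames = list(signif(phi_grid, 6),
                                signif(sigma_y_grid, 6)))
  for (i in seq_along(phi_grid)) {
    for (j in seq_along(sigma_y_grid)) {
      p <- cfg$params
      p$Phi <- phi_grid[i]; p$sigma_y <- sigma_y_grid[j]
      cfg$params <- p
      out[i, j] <- selfsim_objective(initial, cfg)
    }
  }
  out
}

#' Extend a profile with an analytic cylinder
#'
#' Appends cylinder points (`phi = pi/2`, constant radius) beyond the traced
#' region so that simulation resampling never runs off the data.
#'
#' @param profile A `meridional_profile`.
#' @param to_length Target meridional length, um.
#' @return A `meridional_profile` of the requested length.
#' @export
extend_profile <- function(profile, to_length) {
  h <- attr(profile, "spacing")
  L <- max(profile$s)
  if (L >= to_length) return(profile)
  n_add <- ceiling((to_length - L) / h)
  s_add <- L + seq_len(n_add) * h
  R <- profile$r[nrow(profile)]
  x_add <- profile$x[nrow(profile)] - seq_len(n_add) * h
  meridional_profile(
    s = c(profile$s, s_add),
    x = c(profile$x, x_add),
    r = c(profile$r, rep(R, n_add)),
    phi = c(profile$phi, rep(pi / 2, n_add)),
    kappa_s = c(profile$kappa_s, rep(0, n_add)),
    kappa_theta = c(profile$kappa_theta, rep(1 / R, n_add)),
    spacing = h)
}
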