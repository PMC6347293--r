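# Bootstrap robustness of the constant-plasticity Lockhart inference:
# resample whole cells (contours and TEM thickness series), rerun the
# averaging / fitting / mechanics pipeline and refit the Lockhart line.

#' Bootstrap the stress / strain-rate Lockhart inference
#'
#' Each replicate draws, with replacement, cells from the contour set and
#' cells from the thickness set (independently), recomputes the average
#' contour, refits the thickness gradient, computes the effective stress
#' and expected strain rate, and refits the Lockhart regression.
#'
#' @param contours List of `raw_contour` objects (or precomputed curvature
#'   series data frames with columns `s`, `kappa`).
#' @param thickness Data frame of thickness measurements with columns
#'   `cell_id`, `s` and `delta` (or `w`/`a`, corrected on the fly).
#' @param params A [viscoplastic_params()] (`P`, `v_tip`, `nu`, `K` used).
#' @param n_rep Number of bootstrap replicates.
#' @param seed Master seed; each replicate uses an RNG stream derived from
#'   `(seed, replicate index)` so replicates are order-independent.
#' @param family Thickness gradient family refitted per replicate.
#' @param window,step Curvature averaging window and step, um.
#' @param spacing Profile spacing, um.
#' @param smoothing Contour smoothing penalty (see [smooth_and_resample()]).
#' @param R Cell radius for thickness correction, um.
#' @param max_failures Maximum tolerated fraction of failed replicates.
#' @param resample Set to `FALSE` to disable resampling (every replicate is
#'   the identity sample), reproducing the point-estimate pipeline.
#' @return A `bootstrap_result` list: `replicates` (data frame with
#'   `delta_min`, `delta_max`, `s_half`, `Phi`, `sigma_y`, `r2`),
#'   `summary` (mean and 5th-percentile r2, mean `delta_max - delta_min`,
#'   correlations), `n_failed`, `seed`.
#' @export
bootstrap_lockhart <- function(contours, thickness, params, n_rep = 3000,
                               seed = 1, family = "pearson", window = 0.2,
                               step = 0.05, spacing = 0.05,
                               smoothing = NULL, R = 3.27,
                               max_failures = 0.01, resample = TRUE) {
  if (length(contours) == 0L || nrow(thickness) == 0L)
    stop("both datasets must be non-empty")
  series <- lapply(contours, function(ct) {
    if (is.data.frame(ct)) ct else
      curvature_series(ct, spacing = spacing, smoothing = smoothing)
  })
  smax <- max(vapply(series, function(d) max(abs(d$s)), numeric(1)))
  grid <- seq(0, smax, by = step)
  ws <- window_stats(series, grid, window)
  if (is.null(thickness$delta)) {
    a <- thickness$a %||% (R - thickness$w)
    thickness$delta <- correct_thickness(a, thickness$w, R)
  }
  cells <- split(thickness[c("s", "delta")], thickness$cell_id)
  n_ct <- length(series); n_th <- length(cells)
  # full-data gradient fit provides fast, stable per-replicate starts
  g0 <- fit_gradient(thickness, family = family, R = R)
  f <- gradient_families[[family]]
  one_rep <- function(b) {
    identity <- !resample
    if (!identity) set.seed(derive_seed(seed, b))
    mult <- if (identity) rep(1, n_ct) else
      tabulate(sample.int(n_ct, n_ct, replace = TRUE), n_ct)
    th_idx <- if (identity) seq_len(n_th) else
      sample.int(n_th, n_th, replace = TRUE)
    avg <- combine_window_stats(ws, mult)
    prof <- reconstruct_profile(avg$s, avg$kappa_mean, spacing = spacing)
    th <- do.call(rbind, cells[th_idx])
    s_th <- abs(th$s); delta <- th$delta
    fit <- minpack.lm::nlsLM(
      delta ~ f(s_th, dmin, dmax, shalf),
      start = list(dmin = g0$delta_min, dmax = g0$delta_max,
                   shalf = g0$s_half),
      lower = c(1e-5, 1e-4, 1e-2),
      control = minpack.lm::nls.lm.control(maxiter = 100))
    co <- stats::coef(fit)
    g <- wall_gradient(family, co[["dmin"]], co[["dmax"]], co[["shalf"]])
    mech <- mechanical_state(prof, g, params)
    lk <- lockhart_fit(mech$sigma_e, mech$eps_star)
    c(delta_min = co[["dmin"]], delta_max = co[["dmax"]],
      s_half = co[["shalf"]], Phi = lk$Phi, sigma_y = lk$sigma_y,
      r2 = lk$r2)
  }
  reps <- vector("list", n_rep)
  n_failed <- 0L
  for (b in seq_len(n_rep)) {
    out <- tryCatch(one_rep(b), error = function(e) NULL)
    if (is.null(out)) n_failed <- n_failed + 1L else reps[[b]] <- out
  }
  if (n_failed > max_failures * n_rep)
    stop(n_failed, " of ", n_rep, " bootstrap replicates failed")
  reps <- as.data.frame(do.call(rbind, reps[!vapply(reps, is.null,
                                                    logical(1))]))
  summ <- list(
    mean_r2 = mean(reps$r2),
    q05_r2 = unname(stats::quantile(reps$r2, 0.05, type = 7)),
    min_r2 = min(reps$r2), max_r2 = max(reps$r2),
    mean_delta_gap = mean(reps$delta_max - reps$delta_min),
    cor_delta = stats::cor(reps$delta_min, reps$delta_max),
    cor_phi_sy = stats::cor(log(reps$Phi), log(reps$sigma_y)))
  structure(list(replicates = reps, summary = summ, n_failed = n_failed,
                 n_rep = n_rep, seed = seed), class = "bootstrap_result")
}

#' Identity-sample check of the bootstrap pipeline
#'
#' Runs the per-replicate pipeline once with resampling disabled (every
#' cell drawn exactly once), reproducing the point-estimate pipeline.
#'
#' @inheritParams bootstrap_lockhart
#' @return One-row data frame as in `bootstrap_lockhart()$replicates`.
#' @export
bootstrap_identity <- function(contours, thickness, params,
                               family = "pearson", window = 0.2,
                               step = 0.05, spacing = 0.05,
                               smoothing = NULL, R = 3.27) {
  res <- bootstrap_lockhart(contours, thickness, params, n_rep = 1,
                            seed = 1, family = family, window = window,
                            step = step, spacing = spacing,
                            smoothing = smoothing, R = R,
                            resample = FALSE)
  res$replicates
}
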