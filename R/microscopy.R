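# Microscopy statistics: bead-trajectory orthogonality and FRAP recovery
# quantification.

#' Angles between bead trajectories and the cell contour
#'
#' Each bead observation lies on (or near) the contour traced at the same
#' time point. The trajectory is interpolated by cubic splines in time and
#' its first derivative compared with the contour tangent at the projection
#' of the bead on the contour, giving one unfolded angle in (0, pi) per
#' usable observation, together with the meridional abscissa `|s|` of the
#' intersection.
#'
#' @param tracks Data frame with columns `bead_id`, `t`, `u`, `v`.
#' @param contours List of two-column (u, v) point matrices, one per time
#'   point (same order as the sorted unique `t` values), or a single matrix
#'   reused for all times.
#' @param spacing Resampling spacing used on the contours, um (fine by
#'   default so that the tangent at the projection point is accurate).
#' @return List with `angles` (data frame `bead_id`, `t`, `angle`,
#'   `s_abs`), and `summary` (`mean`, `sd`, `r` = Pearson correlation
#'   between angle and `|s|`, `n`).
#' @export
trajectory_angles <- function(tracks, contours, spacing = 0.02) {
  times <- sort(unique(tracks$t))
  if (is.matrix(contours) || is.data.frame(contours))
    contours <- rep(list(as.matrix(contours)), length(times))
  if (length(contours) != length(times))
    stop("need one contour per time point")
  # resample every contour and cache tangents and tip position
  ct <- lapply(contours, function(p) {
    pts <- smooth_and_resample(p, spacing = spacing, smoothing = 0)
    tip <- find_tip(pts, spacing = spacing)
    du <- finite_gradient(pts[, 1L], spacing)
    dv <- finite_gradient(pts[, 2L], spacing)
    nrm <- sqrt(du^2 + dv^2)
    list(pts = pts, tu = du / nrm, tv = dv / nrm, tip = tip)
  })
  out <- list()
  for (id in unique(tracks$bead_id)) {
    tr <- tracks[tracks$bead_id == id, , drop = FALSE]
    tr <- tr[order(tr$t), , drop = FALSE]
    if (nrow(tr) < 2L) next
    # parametrize the trajectory by path length (robust to the strong
    # deceleration of beads leaving the dome), oriented forward in time
    tl <- chord_lengths(tr$u, tr$v)
    if (max(tl) < 1e-9) next
    keep_t <- c(TRUE, diff(tl) > 1e-9)
    tr <- tr[keep_t, , drop = FALSE]; tl <- tl[keep_t]
    fu <- stats::splinefun(tl, tr$u, method = "fmm")
    fv <- stats::splinefun(tl, tr$v, method = "fmm")
    for (k in seq_len(nrow(tr))) {
      ti <- match(tr$t[k], times)
      cc <- ct[[ti]]
      i <- which.min((cc$pts[, 1L] - tr$u[k])^2 +
                       (cc$pts[, 2L] - tr$v[k])^2)
      # trajectory direction (forward in time)
      dir <- c(fu(tl[k], deriv = 1), fv(tl[k], deriv = 1))
      nd <- sqrt(sum(dir^2))
      if (nd < 1e-12) next   # tangential / stationary contact, skipped
      dir <- dir / nd
      # contour tangent oriented away from the tip on the bead's side
      tg <- c(cc$tu[i], cc$tv[i])
      s_here <- (i - 1L) * spacing - cc$tip
      if (s_here < 0) tg <- -tg
      ang <- atan2(dir[1L] * tg[2L] - dir[2L] * tg[1L], sum(dir * tg))
      out[[length(out) + 1L]] <-
        data.frame(bead_id = id, t = tr$t[k], angle = abs(ang),
                   s_abs = abs(s_here))
    }
  }
  ang <- do.call(rbind, out)
  if (is.null(ang) || nrow(ang) < 2L) stop("no usable intersections found")
  list(angles = ang,
       summary = list(mean = mean(ang$angle), sd = stats::sd(ang$angle),
                      r = stats::cor(ang$angle, ang$s_abs),
                      n = nrow(ang)))
}

#' Background / acquisition correction of a FRAP trace
#'
#' Applies the standard double normalization
#' `A_c(t) = (A(t) - Z(t) - (A(0) - Z(0))) * (U(0) - Z(0)) / (U(t) - Z(t))`
#' with `Z` the averaged background, `U` the unbleached reference and the
#' index 0 at the bleach time, so that `A_c(0) = 0` by construction.
#'
#' @param t Times, s (bleach at 0, pre-bleach points negative).
#' @param A Raw bleached-zone intensity.
#' @param Z Background intensity (average the four regions beforehand, or
#'   pass a matrix whose rows are averaged here).
#' @param U Unbleached-region intensity.
#' @return Corrected intensity `A_c(t)`.
#' @export
frap_correct <- function(t, A, Z, U) {
  if (is.matrix(Z) || is.data.frame(Z)) Z <- rowMeans(Z)
  i0 <- which(t == 0)
  if (length(i0) != 1L) stop("exactly one observation must be at t = 0")
  if (any(U <= Z)) stop("unbleached signal not above background: ",
                        "correction undefined")
  unname((A - Z - (A[i0] - Z[i0])) * (U[i0] - Z[i0]) / (U - Z))
}

#' Exponential recovery fit of a corrected FRAP trace
#'
#' Fits `Y(t) = Y0 + alpha (1 - exp(-t / tau))` to the post-bleach part of
#' the corrected signal by nonlinear least squares. The normalized initial
#' slope `(1/alpha) dA_c/dt (0) = 1/tau` serves as the exocytosis /
#' turnover proxy.
#'
#' @param t Times, s.
#' @param Ac Corrected intensities (same length); only `t >= 0` is used.
#' @param tau_cap Upper bound flagging quasi-flat traces, s.
#' @return List with `Y0`, `alpha`, `tau` (s), `slope0` (`1/tau`, 1/s),
#'   `rse`, and `degenerate` (`TRUE` when the trace shows no measurable
#'   recovery).
#' @export
frap_fit <- function(t, Ac, tau_cap = 1e4) {
  keep <- t >= 0 & is.finite(Ac)
  t <- as.numeric(t[keep]); Ac <- as.numeric(Ac[keep])
  if (length(t) < 10L) stop("need at least 10 post-bleach points")
  amp <- max(Ac) - min(Ac)
  if (amp <= 0 || stats::sd(Ac) < 1e-12)
    return(list(Y0 = Ac[1L], alpha = 0, tau = NA_real_, slope0 = NA_real_,
                rse = 0, degenerate = TRUE))
  half <- t[which(Ac - Ac[1L] >= amp / 2)[1L]]
  start <- list(Y0 = unname(Ac[1L]), alpha = amp,
                tau = max(half / log(2), min(diff(t))))
  fit <- NULL
  for (k in 0:3) {
    st <- start
    if (k > 0) st$tau <- start$tau * 2^(k - 2)
    fit <- tryCatch(
      minpack.lm::nlsLM(Ac ~ Y0 + alpha * (1 - exp(-t / tau)), start = st,
                        lower = c(-Inf, 0, 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    # a trace with no trend (e.g. zero recovery, noise only) cannot anchor
    # the exponential: flag it instead of failing
    if (stats::cor.test(t, Ac)$p.value > 0.01)
      return(list(Y0 = mean(Ac), alpha = 0, tau = NA_real_,
                  slope0 = NA_real_, rse = stats::sd(Ac),
                  degenerate = TRUE))
    stop("FRAP recovery fit did not converge")
  }
  co <- stats::coef(fit)
  rse <- sqrt(sum(stats::residuals(fit)^2) / max(1, length(t) - 3))
  degenerate <- co[["tau"]] > tau_cap || co[["alpha"]] <= 2 * rse
  list(Y0 = co[["Y0"]], alpha = co[["alpha"]], tau = co[["tau"]],
       slope0 = 1 / co[["tau"]], rse = rse, degenerate = degenerate)
}

#' Correct and fit every trace of a FRAP table
#'
#' @param tab Data frame as produced by [make_frap()]: columns `zone`,
#'   `trace`, `t`, `intensity`, `background1..4`, `unbleached`.
#' @return Data frame with one row per trace: `zone`, `trace`, `alpha`,
#'   `tau`, `slope0`, `degenerate`.
#' @export
frap_analyze <- function(tab) {
  out <- list()
  for (key in unique(paste(tab$zone, tab$trace))) {
    d <- tab[paste(tab$zone, tab$trace) == key, , drop = FALSE]
    Z <- rowMeans(d[paste0("background", 1:4)])
    Ac <- frap_correct(d$t, d$intensity, Z, d$unbleached)
    ft <- frap_fit(d$t, Ac)
    out[[key]] <- data.frame(zone = d$zone[1L], trace = d$trace[1L],
                             alpha = ft$alpha, tau = ft$tau,
                             slope0 = ft$slope0,
                             degenerate = ft$degenerate)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
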