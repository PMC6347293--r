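# Contour geometry: from hand-traced cell outlines to a symmetric averaged
# meridional profile with both principal curvatures.

#' Read traced cell contours from a delimited table
#'
#' Expects a CSV/TSV file with columns `cell_id`, `u`, `v` giving, per cell,
#' the ordered 2-D coordinates (micrometres) of a hand-traced outline of the
#' apical cell, spanning the dome and part of the shanks.
#'
#' @param path Path to a CSV (or tab-separated) file.
#' @return A list of `raw_contour` objects (one per `cell_id`, point order
#'   preserved), each a list with elements `cell_id` and `points` (two-column
#'   matrix `u`, `v`).
#' @export
read_contours <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("cell_id", "u", "v")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L)
    stop("contour table is missing column(s): ", paste(miss, collapse = ", "))
  ids <- unique(tab$cell_id)
  out <- lapply(ids, function(id) {
    sub <- tab[tab$cell_id == id, , drop = FALSE]
    raw_contour(id, cbind(u = sub$u, v = sub$v))
  })
  names(out) <- as.character(ids)
  out
}

#' Construct a raw traced contour
#'
#' @param cell_id Cell identifier.
#' @param points Two-column matrix of ordered (u, v) coordinates in um.
#' @return A `raw_contour` object.
#' @export
raw_contour <- function(cell_id, points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stop("contour points must be a two-column (u, v) matrix")
  # drop exactly duplicated consecutive points (tracing artefacts)
  keep <- c(TRUE, rowSums(abs(diff(points))) > 0)
  points <- points[keep, , drop = FALSE]
  if (nrow(points) < 20L)
    stop("contour for cell '", cell_id, "' has fewer than 20 points")
  structure(list(cell_id = as.character(cell_id), points = points),
            class = "raw_contour")
}

#' Smooth a traced contour and resample it at constant arc spacing
#'
#' Fits a smoothing cubic spline to each coordinate against arc length and
#' extracts points exactly equidistant along the fitted curve.
#'
#' @param contour A `raw_contour`, or a two-column matrix of (u, v) points.
#' @param spacing Point-to-point arc distance of the output, um.
#' @param smoothing Smoothing control: `NULL` (default) fixes the spline
#'   flexibility at one equivalent degree of freedom per `df_scale` um of
#'   arc length (bandwidth-stable for hand-traced contours, where
#'   cross-validation is prone to undersmoothing); `0` interpolates the
#'   points exactly; a positive number is passed as penalty `lambda` to
#'   [stats::smooth.spline()].
#' @param df_scale Arc length per equivalent degree of freedom, um.
#' @return Two-column matrix of resampled (u, v) points.
#' @export
smooth_and_resample <- function(contour, spacing = 0.05, smoothing = NULL,
                                df_scale = 1.5) {
  pts <- if (inherits(contour, "raw_contour")) contour$points else
    as.matrix(contour)
  if (spacing <= 0) stop("spacing must be positive")
  t0 <- chord_lengths(pts[, 1L], pts[, 2L])
  total <- t0[length(t0)]
  if (spacing > total / 10) stop("spacing larger than a tenth of the contour")
  # evaluate the fitted smoothing splines on a dense parameter grid (so no
  # secondary interpolation error is introduced), then resample by arc
  # length
  td <- seq(0, total, by = spacing / 4)
  if (!is.null(smoothing) && smoothing == 0) {
    fu <- stats::splinefun(t0, pts[, 1L], method = "fmm")
    fv <- stats::splinefun(t0, pts[, 2L], method = "fmm")
    us <- fu(td); vs <- fv(td)
  } else {
    args <- list(x = t0, all.knots = TRUE)
    if (is.null(smoothing)) {
      args$df <- max(10, min(length(t0) - 1L, total / df_scale))
    } else {
      args$lambda <- smoothing
    }
    fu <- do.call(stats::smooth.spline, c(list(y = pts[, 1L]), args))
    fv <- do.call(stats::smooth.spline, c(list(y = pts[, 2L]), args))
    us <- stats::predict(fu, td)$y
    vs <- stats::predict(fv, td)$y
  }
  rs <- resample_curve(us, vs, spacing, n_refine = 1L)
  cbind(u = rs$u, v = rs$v)
}

#' Signed meridional curvature of an equidistant point sequence
#'
#' Curvature from first and second arc-length derivatives of the discretised
#' curve, `kappa = (u' v'' - v' u'') / (u'^2 + v'^2)^(3/2)`. A convex dome
#' traced so that the interior lies to the right of the travel direction has
#' positive curvature.
#'
#' @param points Two-column matrix of equidistant (u, v) points (um).
#' @param spacing Arc spacing; inferred from the points when `NULL`.
#' @return Numeric vector of curvatures, um^-1.
#' @export
meridional_curvature <- function(points, spacing = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 5L) stop("need at least 5 points to estimate curvature")
  if (is.null(spacing)) {
    d <- sqrt(diff(points[, 1L])^2 + diff(points[, 2L])^2)
    spacing <- mean(d)
    if (max(abs(d - spacing)) > 0.05 * spacing)
      warning("points are not equidistant; curvature may be biased")
  }
  du <- finite_gradient(points[, 1L], spacing)
  dv <- finite_gradient(points[, 2L], spacing)
  ddu <- finite_gradient(du, spacing)
  ddv <- finite_gradient(dv, spacing)
  (du * ddv - dv * ddu) / (du^2 + dv^2)^1.5
}

#' Locate the tip point along a traced dome contour
#'
#' The tip is first taken as the point farthest from the chord joining the
#' contour endpoints and then refined to the extremum of a local quadratic in
#' the distance-from-chord coordinate, giving a sub-spacing arc position.
#'
#' @param points Two-column matrix of equidistant (u, v) points.
#' @param spacing Arc spacing between points.
#' @return Arc-length position of the tip from the first point, um.
#' @export
find_tip <- function(points, spacing = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (is.null(spacing))
    spacing <- mean(sqrt(diff(points[, 1L])^2 + diff(points[, 2L])^2))
  a <- points[1L, ]; b <- points[n, ]
  ab <- b - a
  nrm <- c(-ab[2L], ab[1L]) / sqrt(sum(ab^2))
  d <- (points[, 1L] - a[1L]) * nrm[1L] + (points[, 2L] - a[2L]) * nrm[2L]
  d <- d * sign(d[which.max(abs(d))])
  i <- which.max(d)
  if (i <= 1L || i >= n) return((i - 1L) * spacing)
  # quadratic refinement on the three points around the maximum
  y1 <- d[i - 1L]; y2 <- d[i]; y3 <- d[i + 1L]
  denom <- y1 - 2 * y2 + y3
  off <- if (abs(denom) < .Machine$double.eps) 0 else
    0.5 * (y1 - y3) / denom
  ((i - 1L) + max(-0.5, min(0.5, off))) * spacing
}

#' Per-cell meridional curvature series with the tip at s = 0
#'
#' Smooths and resamples a traced contour, estimates the signed curvature and
#' re-centres the arc coordinate on the tip, flipping the sign convention if
#' needed so that the convex dome has positive curvature.
#'
#' @inheritParams smooth_and_resample
#' @return Data frame with columns `s` (signed arc distance from the tip, um)
#'   and `kappa` (meridional curvature, um^-1).
#' @export
curvature_series <- function(contour, spacing = 0.05, smoothing = NULL) {
  pts <- smooth_and_resample(contour, spacing = spacing, smoothing = smoothing)
  kap <- meridional_curvature(pts, spacing = spacing)
  tip <- find_tip(pts, spacing = spacing)
  s <- (seq_len(nrow(pts)) - 1L) * spacing - tip
  # dome convex = positive: anchor the sign on the curvature near the tip
  near <- abs(s) <= max(1, 5 * spacing)
  if (mean(kap[near]) < 0) kap <- -kap
  data.frame(s = s, kappa = kap)
}

# Per-cell sliding-window statistics used by the averaging step and reused
# (precomputed) by the bootstrap. For each window centre |s| = grid[k],
# values from both sides of the tip falling in [grid[k] - w/2, grid[k] + w/2]
# are pooled. Returns matrices (cells x grid) of sums, sums of squares and
# counts.
window_stats <- function(series_list, grid, window) {
  ncell <- length(series_list)
  S <- SS <- N <- matrix(0, ncell, length(grid))
  half <- window / 2
  for (i in seq_len(ncell)) {
    s <- abs(series_list[[i]]$s)
    k <- series_list[[i]]$kappa
    for (j in seq_along(grid)) {
      sel <- s >= grid[j] - half & s <= grid[j] + half
      if (any(sel)) {
        S[i, j] <- sum(k[sel])
        SS[i, j] <- sum(k[sel]^2)
        N[i, j] <- sum(sel)
      }
    }
  }
  list(sum = S, sumsq = SS, n = N, grid = grid, window = window)
}

# Combine per-cell window statistics with cell multiplicities (bootstrap
# weights); multiplicity 1 for every cell reproduces the plain average.
combine_window_stats <- function(ws, mult) {
  n <- as.numeric(mult %*% ws$n)
  keep <- n > 0
  if (!all(keep)) {
    last <- match(FALSE, keep) - 1L
    keep <- seq_along(n) <= last
  }
  m <- as.numeric(mult %*% ws$sum)[keep] / n[keep]
  ssq <- as.numeric(mult %*% ws$sumsq)[keep]
  v <- pmax(0, ssq / n[keep] - m^2)
  sd <- ifelse(n[keep] > 1, sqrt(v * n[keep] / (n[keep] - 1)), 0)
  data.frame(s = ws$grid[keep], kappa_mean = m, kappa_sd = sd, n = n[keep])
}

#' Average meridional curvature over cells with a sliding window
#'
#' Pools, for each window centred at |s|, the curvature values from both
#' sides of the tip of every cell, yielding a symmetric mean curvature
#' profile with its pooled standard deviation.
#'
#' @param series_list List of per-cell curvature series as returned by
#'   [curvature_series()] (columns `s`, `kappa`, tip at `s = 0`).
#' @param window Window width, um.
#' @param step Sliding step between window centres, um.
#' @return Data frame with columns `s`, `kappa_mean`, `kappa_sd`, `n`. The
#'   grid is truncated (with a warning) at the first window containing no
#'   observations.
#' @export
average_curvature_profile <- function(series_list, window = 0.2,
                                      step = 0.05) {
  if (length(series_list) == 0L) stop("no curvature series supplied")
  smax <- max(vapply(series_list, function(d) max(abs(d$s)), numeric(1)))
  grid <- seq(0, smax, by = step)
  ws <- window_stats(series_list, grid, window)
  out <- combine_window_stats(ws, rep(1, length(series_list)))
  if (nrow(out) < length(grid))
    warning("curvature grid truncated to ", max(out$s),
            " um (empty averaging window beyond)")
  out
}

#' Reconstruct an axisymmetric meridional profile from kappa_s(s)
#'
#' Integrates the Frenet-type system `dphi/ds = kappa_s`, `dr/ds = cos(phi)`,
#' `dx/ds = -sin(phi)` from the tip (`s = 0`, `r = 0`, `phi = 0`), where
#' `phi` is the angle between the symmetry axis and the outward normal. The
#' circumferential curvature is `kappa_theta = sin(phi) / r`, with the
#' analytic limit `kappa_theta(0) = kappa_s(0)` used at the first grid
#' points.
#'
#' @param s Grid of meridional abscissae (um) on which `kappa_s` is given.
#' @param kappa_s Meridional curvature values on `s` (um^-1).
#' @param spacing Output grid spacing, um.
#' @return A `meridional_profile`: data frame with columns `s`, `x`, `r`,
#'   `phi`, `kappa_s`, `kappa_theta` and attribute `spacing`.
#' @export
reconstruct_profile <- function(s, kappa_s, spacing = 0.05) {
  if (is.data.frame(s)) {
    kappa_s <- s$kappa_mean %||% s$kappa
    s <- s$s
  }
  if (kappa_s[1L] <= 0) stop("tip curvature kappa_s(0) must be positive")
  sg <- seq(0, max(s), by = spacing)
  kfun <- stats::splinefun(s, kappa_s, method = "fmm")
  kap <- kfun(sg)
  phi <- cumint(kap, spacing)
  r <- cumint(cos(phi), spacing)
  x <- -cumint(sin(phi), spacing)
  if (any(r[-1L] <= 0))
    stop("inconsistent curvature: reconstructed radius is not positive")
  ktheta <- numeric(length(sg))
  ktheta[-(1:2)] <- sin(phi[-(1:2)]) / r[-(1:2)]
  kp0 <- (kap[2L] - kap[1L]) / spacing
  ktheta[1:2] <- kap[1L] + kp0 * sg[1:2] / 2
  meridional_profile(sg, x, r, phi, kap, ktheta, spacing)
}

#' @rdname reconstruct_profile
#' @param x,r,phi,kappa_theta Per-point profile arrays (see Details).
#' @export
meridional_profile <- function(s, x, r, phi, kappa_s, kappa_theta,
                               spacing = NULL) {
  p <- data.frame(s = s, x = x, r = r, phi = phi, kappa_s = kappa_s,
                  kappa_theta = kappa_theta)
  attr(p, "spacing") <- spacing %||% mean(diff(s))
  class(p) <- c("meridional_profile", "data.frame")
  p
}

# Invariant checks used in tests and before simulation.
validate_profile <- function(p, tol = 1e-6) {
  stopifnot(inherits(p, "meridional_profile"))
  h <- attr(p, "spacing")
  stopifnot(all(diff(p$s) > 0),
            max(abs(diff(p$s) - h)) < 1e-6 * max(1, h),
            abs(p$r[1L]) < tol, abs(p$phi[1L]) < tol,
            all(p$r >= -tol), all(p$kappa_theta >= -tol))
  ratio <- p$kappa_theta[2L] / p$kappa_s[2L]
  stopifnot(abs(ratio - 1) < 1e-2)
  invisible(TRUE)
}
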