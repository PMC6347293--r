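# Cell wall thickness: correction of apparent TEM thickness for off-meridian
# sectioning, and fitting of the tip-to-shank thickness gradient.

#' Correct apparent wall thickness for off-meridian sectioning
#'
#' A longitudinal section cut at a distance from the true meridional plane
#' shows the wall thicker than it is. Modelling the cell locally as a
#' cylinder of radius `R`, the apparent inner radius `a` and apparent
#' thickness `w` seen on the section determine the true thickness
#' `delta = R - sqrt(a^2 + R^2 - (a + w)^2)`.
#'
#' @param a Apparent inner radius at the measurement, um.
#' @param w Apparent wall thickness, um.
#' @param R Actual cell radius, um (default 3.27).
#' @return Corrected thickness `delta` in um, with `0 < delta <= w`.
#' @export
correct_thickness <- function(a, w, R = 3.27) {
  if (any(w <= 0)) stop("apparent thickness w must be positive")
  if (any(a < 0)) stop("apparent inner radius a must be non-negative")
  if (any(a + w > R * (1 + 1e-6)))
    stop("section wider than the cell: a + w exceeds R")
  rad <- a^2 + R^2 - pmin(a + w, R)^2
  R - sqrt(rad)
}

# Gradient family formulas: inverted-bell functions of |s| rising from
# delta_min at the tip to the asymptote delta_max, all with value
# (delta_min + delta_max)/2 at s = s_half.
gradient_families <- list(
  gauss   = function(s, dmin, dmax, shalf)
    dmax - (dmax - dmin) * exp(-(s / shalf)^2 * log(2)),
  lorentz = function(s, dmin, dmax, shalf)
    dmax - (dmax - dmin) / (1 + (s / shalf)^2),
  pearson = function(s, dmin, dmax, shalf)
    dmax - (dmax - dmin) / sqrt(1 + 3 * (s / shalf)^2)
)

# Analytic d delta / d s for each family (s >= 0).
gradient_slopes <- list(
  gauss   = function(s, dmin, dmax, shalf)
    (dmax - dmin) * 2 * log(2) * s / shalf^2 * exp(-(s / shalf)^2 * log(2)),
  lorentz = function(s, dmin, dmax, shalf)
    (dmax - dmin) * 2 * s / shalf^2 / (1 + (s / shalf)^2)^2,
  pearson = function(s, dmin, dmax, shalf)
    (dmax - dmin) * 3 * s / shalf^2 * (1 + 3 * (s / shalf)^2)^-1.5
)

#' Construct a wall thickness gradient model
#'
#' @param family One of `"gauss"`, `"lorentz"`, `"pearson"`.
#' @param delta_min Wall thickness at the tip, um.
#' @param delta_max Asymptotic wall thickness on the shanks, um.
#' @param s_half Midpoint abscissa where the thickness is halfway between
#'   `delta_min` and `delta_max`, um.
#' @param rse Residual standard error of the fit that produced the model, um
#'   (`NA` for an exact/assumed gradient).
#' @return A `wall_gradient` object.
#' @export
wall_gradient <- function(family = c("pearson", "lorentz", "gauss"),
                          delta_min, delta_max, s_half, rse = NA_real_) {
  family <- match.arg(family)
  if (!(delta_min > 0 && delta_min < delta_max))
    stop("need 0 < delta_min < delta_max")
  if (s_half <= 0) stop("s_half must be positive")
  structure(list(family = family, delta_min = delta_min,
                 delta_max = delta_max, s_half = s_half, rse = rse),
            class = "wall_gradient")
}

#' @export
print.wall_gradient <- function(x, ...) {
  cat(sprintf(
    "wall thickness gradient (%s): delta_min = %.1f nm, delta_max = %.1f nm, s_1/2 = %.2f um",
    x$family, 1e3 * x$delta_min, 1e3 * x$delta_max, x$s_half))
  if (is.finite(x$rse)) cat(sprintf(", rse = %.4f um", x$rse))
  cat("\n")
  invisible(x)
}

#' Evaluate a wall thickness gradient
#'
#' @param g A `wall_gradient`.
#' @param s Meridional abscissa(e), um; signed values are folded to `|s|`.
#' @param derivative If `TRUE`, return the analytic slope `d delta / d s`
#'   (with respect to `|s|`) instead of the thickness.
#' @return Thickness (or slope) values, um (um per um).
#' @export
evaluate_gradient <- function(g, s, derivative = FALSE) {
  stopifnot(inherits(g, "wall_gradient"))
  fam <- if (derivative) gradient_slopes[[g$family]] else
    gradient_families[[g$family]]
  if (is.null(fam)) stop("unknown gradient family: ", g$family)
  fam(abs(s), g$delta_min, g$delta_max, g$s_half)
}

#' Fit a thickness gradient model to corrected measurements
#'
#' Nonlinear least squares of corrected thickness `delta` against folded
#' `|s|`, over the three parameters (`delta_min`, `delta_max`, `s_half`),
#' with jittered restarts if the first fit fails to converge.
#'
#' @param meas Data frame with columns `s` (um, signed allowed) and `delta`
#'   (corrected thickness, um). If `delta` is absent but `w` and `a` are
#'   present, the correction is applied first with radius `R`.
#' @param family Gradient family to fit.
#' @param R Cell radius used if the correction has to be applied, um.
#' @param n_restarts Number of jittered restarts on failure.
#' @return A `wall_gradient` with the fitted parameters and `rse` in um
#'   (`sqrt(SSR / (n - 3))`).
#' @export
fit_gradient <- function(meas, family = c("pearson", "lorentz", "gauss"),
                         R = 3.27, n_restarts = 5L) {
  family <- match.arg(family)
  if (is.null(meas$delta)) {
    if (is.null(meas$w)) stop("need a 'delta' or 'w' column")
    a <- meas$a %||% (R - meas$w)   # meridional assumption when a is absent
    meas$delta <- correct_thickness(a, meas$w, R)
  }
  s <- abs(meas$s)
  delta <- meas$delta
  if (length(s) < 10L) stop("need at least 10 measurements")
  f <- gradient_families[[family]]
  start <- list(dmin = max(min(delta), 1e-4), dmax = max(delta),
                shalf = stats::median(s))
  fit <- NULL
  for (k in 0:n_restarts) {
    st <- start
    if (k > 0) {
      jit <- stats::runif(3, 0.5, 1.6)
      st <- list(dmin = start$dmin * jit[1L], dmax = start$dmax * jit[2L],
                 shalf = start$shalf * jit[3L])
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(delta ~ f(s, dmin, dmax, shalf), start = st,
                        lower = c(1e-5, 1e-4, 1e-2),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("gradient fit did not converge after ", n_restarts, " restarts (",
         family, " family, n = ", length(s), ")")
  co <- stats::coef(fit)
  rse <- sqrt(sum(stats::residuals(fit)^2) / (length(s) - 3))
  wall_gradient(family, co[["dmin"]], co[["dmax"]], co[["shalf"]], rse = rse)
}
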