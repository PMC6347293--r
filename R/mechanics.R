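# Axisymmetric thin-shell wall stresses, the expected strain rate under
# self-similar growth, and Lockhart parameter inference.

#' Viscoplastic model parameters
#'
#' @param P Turgor pressure, MPa.
#' @param Phi Wall extensibility, MPa^-1 min^-1.
#' @param sigma_y Yield threshold, MPa.
#' @param nu Flow coupling coefficient (0.5 for a transversely isotropic
#'   wall).
#' @param K Normalization factor of the expected strain rate (1 in the
#'   um/MPa/min unit system).
#' @param v_tip Tip elongation speed, um min^-1 (default 2.5 um/h).
#' @return A `viscoplastic_params` list.
#' @export
viscoplastic_params <- function(P = 0.495, Phi = NA_real_,
                                sigma_y = NA_real_, nu = 0.5, K = 1,
                                v_tip = 2.5 / 60) {
  stopifnot(P > 0, nu >= 0, nu <= 0.5, v_tip > 0, K > 0)
  if (is.finite(Phi)) stopifnot(Phi >= 0)
  if (is.finite(sigma_y)) stopifnot(sigma_y >= 0)
  structure(list(P = P, Phi = Phi, sigma_y = sigma_y, nu = nu, K = K,
                 v_tip = v_tip), class = "viscoplastic_params")
}

#' Thin-shell membrane stresses on an axisymmetric profile
#'
#' For a pressurized axisymmetric membrane of local thickness `delta`, the
#' meridional and circumferential stresses are
#' `sigma_s = P / (2 delta kappa_theta)` and
#' `sigma_theta = P (2 kappa_theta - kappa_s) / (2 delta kappa_theta^2)`.
#' At the tip (`kappa_theta = kappa_s`) the two are equal; on a cylinder
#' (`kappa_s = 0`) the hoop stress is twice the meridional one.
#'
#' @param profile A `meridional_profile`.
#' @param delta Wall thickness: a `wall_gradient`, or a vector of
#'   thicknesses on the profile grid (um).
#' @param P Turgor, MPa.
#' @return List with vectors `sigma_s` and `sigma_theta` (MPa).
#' @export
shell_stresses <- function(profile, delta, P) {
  if (inherits(delta, "wall_gradient"))
    delta <- evaluate_gradient(delta, profile$s)
  if (any(delta <= 0)) stop("wall thickness must be positive everywhere")
  kt <- profile$kappa_theta
  ks <- profile$kappa_s
  if (any(kt <= 0)) stop("kappa_theta must be positive everywhere")
  sigma_s <- P / (2 * delta * kt)
  sigma_theta <- P * (2 * kt - ks) / (2 * delta * kt^2)
  list(sigma_s = sigma_s, sigma_theta = sigma_theta)
}

#' Effective (scalar) wall stress
#'
#' Generalized plane-stress von Mises form
#' `sigma_e = sqrt(sigma_s^2 + sigma_theta^2 - 2 nu sigma_s sigma_theta)`;
#' with `nu = 0.5` and equal stresses it reduces to the common value.
#'
#' @param sigma_s,sigma_theta Stress components, MPa.
#' @param nu Flow coupling coefficient.
#' @return Effective stress, MPa (non-negative).
#' @export
effective_stress <- function(sigma_s, sigma_theta, nu = 0.5) {
  if (any(!is.finite(sigma_s)) || any(!is.finite(sigma_theta)))
    stop("stresses must be finite")
  sqrt(pmax(0, sigma_s^2 + sigma_theta^2 - 2 * nu * sigma_s * sigma_theta))
}

#' Normal surface velocity under self-similar growth
#'
#' Growth without shape distortion is an axial translation of the profile at
#' the tip speed, whose normal component is `V_n = v_tip cos(phi)`.
#'
#' @param profile A `meridional_profile`.
#' @param v_tip Tip elongation speed, um min^-1.
#' @return Normal velocity V_n(s), um min^-1.
#' @export
normal_velocity_selfsimilar <- function(profile, v_tip) {
  v_tip * cos(profile$phi)
}

#' Expected strain rate from geometry and kinematics alone
#'
#' Combining the kinematic identity for the circumferential strain rate,
#' `eps_theta = V_n kappa_theta`, with the transversely isotropic flow rule
#' `eps_theta = eps (sigma_theta - nu sigma_s) / sigma_e` gives the strain
#' rate the wall must realize for self-similar growth,
#' `eps* = K kappa_theta sigma_e V_n / (sigma_theta - nu sigma_s)`,
#' without any knowledge of the wall plasticity parameters.
#'
#' @param profile A `meridional_profile`.
#' @param sigma_s,sigma_theta,sigma_e Stress arrays, MPa.
#' @param V_n Normal velocity, um min^-1.
#' @param nu Flow coupling coefficient.
#' @param K Normalization factor.
#' @return Expected strain rate, min^-1.
#' @export
expected_strain_rate <- function(profile, sigma_s, sigma_theta, sigma_e,
                                 V_n, nu = 0.5, K = 1) {
  denom <- sigma_theta - nu * sigma_s
  bad <- denom <= 0 & V_n > 1e-12
  if (any(bad))
    stop("sigma_theta - nu*sigma_s <= 0 at ", sum(bad),
         " growing point(s): outside the model domain")
  eps <- K * profile$kappa_theta * sigma_e / denom * V_n
  eps[V_n <= 1e-12] <- 0
  pmax(eps, 0)
}

#' Full mechanical state of a profile
#'
#' Convenience wrapper computing thickness, stresses, effective stress,
#' self-similar normal velocity and expected strain rate on a profile.
#'
#' @param profile A `meridional_profile`.
#' @param gradient A `wall_gradient` (or thickness vector).
#' @param params A `viscoplastic_params`.
#' @return Data frame with columns `s`, `delta`, `sigma_s`, `sigma_theta`,
#'   `sigma_e`, `V_n`, `eps_star`.
#' @export
mechanical_state <- function(profile, gradient, params) {
  delta <- if (inherits(gradient, "wall_gradient"))
    evaluate_gradient(gradient, profile$s) else gradient
  st <- shell_stresses(profile, delta, params$P)
  se <- effective_stress(st$sigma_s, st$sigma_theta, params$nu)
  vn <- normal_velocity_selfsimilar(profile, params$v_tip)
  eps <- expected_strain_rate(profile, st$sigma_s, st$sigma_theta, se, vn,
                              nu = params$nu, K = params$K)
  data.frame(s = profile$s, delta = delta, sigma_s = st$sigma_s,
             sigma_theta = st$sigma_theta, sigma_e = se, V_n = vn,
             eps_star = eps)
}

#' Fit the Lockhart law to a stress / strain-rate relation
#'
#' Ordinary least squares of the expected strain rate on the effective
#' stress, restricted to the increasing branch (points with `eps_star`
#' above a threshold, by default 1% of its maximum). Under the Lockhart law
#' `eps = Phi (sigma_e - sigma_y)`, the slope is the extensibility `Phi`
#' and `sigma_y = -intercept / slope`.
#'
#' @param sigma_e Effective stress, MPa.
#' @param eps_star Expected strain rate, min^-1.
#' @param threshold Absolute strain-rate threshold selecting the increasing
#'   branch; default `rel_threshold * max(eps_star)`.
#' @param rel_threshold Relative threshold (fraction of the maximum).
#' @return List with `Phi` (MPa^-1 min^-1), `sigma_y` (MPa), `r2`, `n_used`
#'   and the fitted `lm` object (`fit`).
#' @export
lockhart_fit <- function(sigma_e, eps_star, threshold = NULL,
                         rel_threshold = 0.01) {
  if (is.null(threshold)) threshold <- rel_threshold * max(eps_star)
  sel <- eps_star > threshold
  if (sum(sel) < 5L)
    stop("fewer than 5 points above the strain-rate threshold")
  fit <- stats::lm(eps_star[sel] ~ sigma_e[sel])
  b <- stats::coef(fit)
  slope <- b[[2L]]; intercept <- b[[1L]]
  if (slope <= 0)
    warning("non-Lockhart relation: fitted slope is not positive")
  r2 <- summary(fit)$r.squared
  list(Phi = slope, sigma_y = -intercept / slope, r2 = r2,
       n_used = sum(sel), fit = fit)
}

#' Pointwise wall properties under the equal-partition convention
#'
#' When the stress / strain-rate relation is not a single Lockhart line
#' (graded wall properties, as in the pollen tube), the product
#' `Phi(s) (sigma_e(s) - sigma_y(s)) = eps*(s)` is split equally between its
#' two factors: `Phi = sqrt(eps*)` and `sigma_y = sigma_e - sqrt(eps*)`.
#'
#' @param sigma_e Effective stress, MPa.
#' @param eps_star Expected strain rate, min^-1 (non-negative).
#' @return List with vectors `Phi` and `sigma_y`.
#' @export
pollen_wall_properties <- function(sigma_e, eps_star) {
  if (any(eps_star < 0)) stop("eps_star must be non-negative")
  root <- sqrt(eps_star)
  list(Phi = root, sigma_y = sigma_e - root)
}
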