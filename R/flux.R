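# Cell wall material deposition flux required to maintain the thickness
# gradient during self-similar growth.

#' Wall deposition rate along the meridian
#'
#' In the tip co-moving frame the wall material streams backwards along the
#' meridian at `v_m = v_tip sin(phi)` while the surface stretches; keeping
#' the thickness profile `delta(s)` steady requires a deposition rate (wall
#' volume per surface area per time)
#' `D(s) = v_m d(delta)/ds + delta (eps_s + eps_theta)`,
#' with `eps_theta = V_n kappa_theta`. The meridional strain rate can be
#' taken from the kinematics of self-similar normal growth
#' (`eps_s = V_n kappa_s`, the default, under which the deposition exactly
#' balances the wall volume advected out at the back) or from the
#' anisotropic-viscoplastic flow rule
#' (`eps_s = eps* (sigma_s - nu sigma_theta) / sigma_e`).
#'
#' @param profile A `meridional_profile`.
#' @param gradient A `wall_gradient` (its analytic slope is used for
#'   `d delta / d s`).
#' @param params A [viscoplastic_params()].
#' @param strain `"kinematic"` (default) or `"flow"` meridional strain rate.
#' @return Data frame with columns `s`, `D` (um min^-1, per unit area),
#'   `D_per_length` (`2 pi r D`, um^2 min^-1, per unit meridional length),
#'   `thinning_term` (`delta (eps_s + eps_theta)`) and `advection_term`
#'   (`v_m d delta/ds`).
#' @export
deposition_rate <- function(profile, gradient, params,
                            strain = c("kinematic", "flow")) {
  strain <- match.arg(strain)
  mech <- mechanical_state(profile, gradient, params)
  v_m <- params$v_tip * sin(profile$phi)
  dslope <- evaluate_gradient(gradient, profile$s, derivative = TRUE)
  eps_theta <- mech$V_n * profile$kappa_theta
  eps_s <- if (strain == "kinematic") mech$V_n * profile$kappa_s else
    mech$eps_star * (mech$sigma_s - params$nu * mech$sigma_theta) /
      mech$sigma_e
  advection <- v_m * dslope
  thinning <- mech$delta * (eps_s + eps_theta)
  D <- advection + thinning
  data.frame(s = profile$s, D = D, D_per_length = 2 * pi * profile$r * D,
             thinning_term = thinning, advection_term = advection)
}

#' Global conservation check of the deposition flux
#'
#' Integrates `D` over the cell surface and compares with the wall volume
#' advected out at the back of the profile,
#' `2 pi R delta_max v_tip`.
#'
#' @param flux Output of [deposition_rate()].
#' @param profile The profile the flux was computed on.
#' @param gradient,params As in [deposition_rate()].
#' @return List with `integral`, `outflow` (um^3 min^-1) and their `ratio`.
#' @export
flux_conservation <- function(flux, profile, gradient, params) {
  integral <- trapz(flux$s, flux$D_per_length)
  R_shank <- profile$r[nrow(profile)]
  delta_end <- evaluate_gradient(gradient, max(profile$s))
  outflow <- 2 * pi * R_shank * delta_end * params$v_tip *
    sin(profile$phi[nrow(profile)])
  list(integral = integral, outflow = outflow,
       ratio = integral / outflow)
}
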