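#' Scalar damage function
#'
#' Damage is driven by accumulated plastic strain: zero up to the activation
#' threshold `k0`, then `1 - exp(-kp * (kappa - k0))`, continuous at the
#' threshold and confined to `[0, 1)`. Damage multiplies the stiffness by
#' `(1 - D)`, modelling microcrack-induced stiffness loss.
#'
#' @param kappa accumulated plastic strain (vectorised, >= 0).
#' @param dp a [damage_parameters()] object.
#' @return Damage values in `[0, 1)`, same length as `kappa`.
#' @export
#' @examples
#' dp <- damage_parameters(k0 = 1e-4, kp = 5)
#' damage_value(1e-4 + log(2) / 5, dp)  # 0.5
damage_value <- function(kappa, dp) {
  stopifnot(inherits(dp, "damage_parameters"))
  if (any(!is.finite(kappa)) || any(kappa < 0)) {
    stop_bonevpd("'kappa' must be finite and >= 0", "bonevpd_state_error")
  }
  ifelse(kappa < dp$k0, 0, 1 - exp(-dp$kp * (kappa - dp$k0)))
}

## dD/dkappa, needed by the analytic Jacobian of the return map.
damage_rate <- function(kappa, dp) {
  ifelse(kappa < dp$k0, 0, dp$kp * exp(-dp$kp * (kappa - dp$k0)))
}

#' Isotropic hardening/softening function
#'
#' In `"original"` mode r(kappa) grows monotonically from 1 towards the
#' saturation ratio `yr`:
#' `r = 1 + (yr - 1) * (1 - exp(-sh * kappa))`.
#' In `"softening"` mode the same branch applies for `kappa <= ks` and
#' decays as `r(ks) * exp(-ss * (kappa - ks))` beyond it, continuously at
#' the switch; this captures the post-peak softening visible in compression
#' tests on bone.
#'
#' @param kappa accumulated plastic strain (vectorised, >= 0).
#' @param hp a [hardening_parameters()] object.
#' @param mode `"original"` or `"softening"`; defaults to the mode stored in
#'   `hp`.
#' @return Hardening ratio r, same length as `kappa`.
#' @export
hardening_value <- function(kappa, hp, mode = hp$mode) {
  stopifnot(inherits(hp, "hardening_parameters"))
  mode <- match.arg(mode, c("softening", "original"))
  if (any(!is.finite(kappa)) || any(kappa < 0)) {
    stop_bonevpd("'kappa' must be finite and >= 0", "bonevpd_state_error")
  }
  r <- 1 + (hp$yr - 1) * (1 - exp(-hp$sh * kappa))
  if (mode == "softening") {
    rks <- 1 + (hp$yr - 1) * (1 - exp(-hp$sh * hp$ks))
    r <- ifelse(kappa <= hp$ks, r, rks * exp(-hp$ss * (kappa - hp$ks)))
  }
  r
}

## dr/dkappa for the analytic Jacobian (one-sided at the ks kink).
hardening_rate <- function(kappa, hp, mode = hp$mode) {
  mode <- match.arg(mode, c("softening", "original"))
  d <- (hp$yr - 1) * hp$sh * exp(-hp$sh * kappa)
  if (mode == "softening") {
    rks <- 1 + (hp$yr - 1) * (1 - exp(-hp$sh * hp$ks))
    d <- ifelse(kappa <= hp$ks, d, -hp$ss * rks * exp(-hp$ss * (kappa - hp$ks)))
  }
  d
}

#' Perzyna viscoplastic consistency parameter
#'
#' Rate of plastic flow as a function of the overstress:
#' `gamma = (Y^2 + m * Y) / eta`. Strictly increasing in Y, zero at zero
#' overstress. Only defined for `Y >= 0`; callers must gate on the yield
#' check.
#'
#' @param Y overstress (dimensionless, vectorised, >= 0).
#' @param vp a [viscosity_parameters()] object.
#' @return Consistency parameter gamma (1/s).
#' @export
#' @examples
#' perzyna_rate(0.1, viscosity_parameters(m = 5, eta = 0.01))  # 51
perzyna_rate <- function(Y, vp) {
  stopifnot(inherits(vp, "viscosity_parameters"))
  if (any(!is.finite(Y)) || any(Y < 0)) {
    stop_bonevpd("'Y' must be finite and >= 0 (elastic states carry no flow)",
                 "bonevpd_state_error")
  }
  (Y^2 + vp$m * Y) / vp$eta
}

#' Overstress function (inverse of the Perzyna rate)
#'
#' `phi(gamma) = -m/2 + sqrt(m^2/4 + eta * gamma)`; the exact algebraic
#' inverse of [perzyna_rate()] on `Y >= 0`. During viscoplastic flow the
#' yield function equals `phi(gamma)`, so overstress decays to zero as flow
#' stops.
#'
#' @param gamma consistency parameter (1/s, vectorised, >= 0).
#' @param vp a [viscosity_parameters()] object.
#' @return Overstress Y (dimensionless).
#' @export
overstress_phi <- function(gamma, vp) {
  stopifnot(inherits(vp, "viscosity_parameters"))
  if (any(!is.finite(gamma)) || any(gamma < 0)) {
    stop_bonevpd("'gamma' must be finite and >= 0", "bonevpd_state_error")
  }
  phi_unchecked(gamma, vp)
}

## Unguarded phi: tolerates the slightly negative gammas probed by
## finite-difference Jacobians (argument of the sqrt stays positive there).
phi_unchecked <- function(gamma, vp) {
  -vp$m / 2 + sqrt(vp$m^2 / 4 + vp$eta * gamma)
}

## d phi / d gamma
phi_rate <- function(gamma, vp) {
  vp$eta / (2 * sqrt(vp$m^2 / 4 + vp$eta * gamma))
}
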