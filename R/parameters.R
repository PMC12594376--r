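#' @keywords internal
"_PACKAGE"

## Voigt convention used throughout the package:
## order (11, 22, 33, 12, 23, 31); strain vectors carry engineering shear
## components (gamma_ij = 2 eps_ij). Internal stress unit is MPa.

VOIGT_LABELS <- c("11", "22", "33", "12", "23", "31")

stop_bonevpd <- function(msg, class, data = list()) {
  cond <- structure(
    class = c(class, "bonevpd_error", "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), data)
  )
  stop(cond)
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_bonevpd(sprintf("'%s' must be a finite numeric scalar", name),
                 "bonevpd_parameter_error")
  }
  if (positive && x <= 0) {
    stop_bonevpd(sprintf("'%s' must be > 0 (got %g)", name, x),
                 "bonevpd_parameter_error")
  }
  if (nonneg && x < 0) {
    stop_bonevpd(sprintf("'%s' must be >= 0 (got %g)", name, x),
                 "bonevpd_parameter_error")
  }
  as.numeric(x)
}

#' Orthotropic elastic parameters
#'
#' Bundles the nine engineering constants of an orthotropic material:
#' Young's moduli along the three material axes, the three Poisson ratios
#' `nu12`, `nu23`, `nu31`, and the three shear moduli. Transverse isotropy is
#' the degenerate case `E2 = E3`, `G12 = G31`, `nu12 = nu31` (both bone
#' presets satisfy it, axis 1 being the stiff longitudinal axis).
#'
#' The assembled stiffness matrix must be symmetric positive definite; this
#' is checked at construction and thermodynamically inadmissible parameter
#' sets are rejected.
#'
#' @param E1,E2,E3 Young's moduli (MPa, > 0).
#' @param nu12,nu23,nu31 Poisson ratios (dimensionless). `nuij` couples a
#'   load along axis `i` to contraction along axis `j`, with the symmetry
#'   `nuij/Ei = nuji/Ej`.
#' @param G12,G23,G31 shear moduli (MPa, > 0).
#' @return An object of class `elastic_parameters`.
#' @export
#' @examples
#' ep <- elastic_parameters(19900, 11200, 11200, 0.3, 0.4, 0.3,
#'                          5700, 4300, 5700)
#' build_stiffness(ep)[1, 1]
elastic_parameters <- function(E1, E2, E3, nu12, nu23, nu31, G12, G23, G31) {
  p <- list(
    E1 = check_scalar(E1, "E1", positive = TRUE),
    E2 = check_scalar(E2, "E2", positive = TRUE),
    E3 = check_scalar(E3, "E3", positive = TRUE),
    nu12 = check_scalar(nu12, "nu12"),
    nu23 = check_scalar(nu23, "nu23"),
    nu31 = check_scalar(nu31, "nu31"),
    G12 = check_scalar(G12, "G12", positive = TRUE),
    G23 = check_scalar(G23, "G23", positive = TRUE),
    G31 = check_scalar(G31, "G31", positive = TRUE)
  )
  class(p) <- "elastic_parameters"
  build_stiffness(p)  # rejects non-SPD sets with a diagnostic
  p
}

#' Damage parameters
#'
#' Scalar damage `D(kappa)` is zero below the activation threshold `k0` of
#' accumulated plastic strain and saturates exponentially towards 1 above it
#' at rate `kp`, so `D` stays in `[0, 1)` for any finite loading history.
#'
#' @param k0 damage activation threshold on accumulated plastic strain
#'   (dimensionless, >= 0).
#' @param kp damage evolution rate (dimensionless, > 0).
#' @return An object of class `damage_parameters`.
#' @export
damage_parameters <- function(k0, kp) {
  p <- list(k0 = check_scalar(k0, "k0", nonneg = TRUE),
            kp = check_scalar(kp, "kp", positive = TRUE))
  class(p) <- "damage_parameters"
  p
}

#' Isotropic hardening/softening parameters
#'
#' The hardening function r(kappa) starts at 1, grows exponentially towards
#' the saturation ratio `yr` at rate `sh`, and (in `"softening"` mode) decays
#' exponentially at rate `ss` once kappa exceeds the softening onset `ks`,
#' continuously at the switch.
#'
#' @param yr saturation ratio (> 1).
#' @param sh hardening rate (> 0).
#' @param ks softening onset threshold on accumulated plastic strain (> 0).
#' @param ss softening rate (> 0).
#' @param mode default hardening branch, `"softening"` (hardening followed
#'   by exponential softening) or `"original"` (monotone saturation only).
#' @return An object of class `hardening_parameters`.
#' @export
hardening_parameters <- function(yr, sh, ks, ss, mode = c("softening", "original")) {
  mode <- match.arg(mode)
  yr <- check_scalar(yr, "yr")
  if (yr <= 1) {
    stop_bonevpd("'yr' must be > 1", "bonevpd_parameter_error")
  }
  p <- list(yr = yr,
            sh = check_scalar(sh, "sh", positive = TRUE),
            ks = check_scalar(ks, "ks", positive = TRUE),
            ss = check_scalar(ss, "ss", positive = TRUE),
            mode = mode)
  class(p) <- "hardening_parameters"
  p
}

#' Perzyna viscosity parameters
#'
#' The viscoplastic consistency parameter is `gamma = (Y^2 + m*Y)/eta` for
#' overstress `Y >= 0`; its inverse is the overstress function
#' `phi(gamma) = -m/2 + sqrt(m^2/4 + eta*gamma)`.
#'
#' @param m overstress shape parameter (dimensionless, > 0).
#' @param eta viscosity (s, > 0).
#' @return An object of class `viscosity_parameters`.
#' @export
viscosity_parameters <- function(m, eta) {
  p <- list(m = check_scalar(m, "m", positive = TRUE),
            eta = check_scalar(eta, "eta", positive = TRUE))
  class(p) <- "viscosity_parameters"
  p
}

#' Yield-surface parameters
#'
#' Three scalars calibrate the Tsai-Wu-type yield surface: the uniaxial
#' tensile and compressive yield strains `eps0p`, `eps0m` (both stored
#' positive) and the strain interaction coefficient `xi0`. The fabric
#' vectors `m1`, `m2`, `m3` are the orthotropy directions; for both shipped
#' presets they coincide with the global axes.
#'
#' @param eps0p uniaxial tensile yield strain (> 0).
#' @param eps0m uniaxial compressive yield strain (> 0, stored positive).
#' @param xi0 strain interaction coefficient (dimensionless).
#' @param m1,m2,m3 mutually orthogonal unit fabric vectors (length-3).
#' @return An object of class `yield_parameters`.
#' @export
yield_parameters <- function(eps0p, eps0m, xi0,
                             m1 = c(1, 0, 0), m2 = c(0, 1, 0), m3 = c(0, 0, 1)) {
  M <- rbind(as.numeric(m1), as.numeric(m2), as.numeric(m3))
  if (any(dim(M) != c(3L, 3L)) || any(!is.finite(M))) {
    stop_bonevpd("fabric vectors must be three finite length-3 vectors",
                 "bonevpd_parameter_error")
  }
  if (max(abs(M %*% t(M) - diag(3))) > 1e-8) {
    stop_bonevpd("fabric vectors m1, m2, m3 must be mutually orthogonal unit vectors",
                 "bonevpd_parameter_error")
  }
  p <- list(eps0p = check_scalar(eps0p, "eps0p", positive = TRUE),
            eps0m = check_scalar(eps0m, "eps0m", positive = TRUE),
            xi0 = check_scalar(xi0, "xi0"),
            m1 = M[1, ], m2 = M[2, ], m3 = M[3, ])
  class(p) <- "yield_parameters"
  p
}

#' Full material parameter bundle
#'
#' @param elastic an [elastic_parameters()] object.
#' @param damage a [damage_parameters()] object.
#' @param hardening a [hardening_parameters()] object.
#' @param viscosity a [viscosity_parameters()] object.
#' @param yield a [yield_parameters()] object.
#' @return An object of class `material_parameters`.
#' @seealso [preset_parameters()] for the calibrated bone presets.
#' @export
material_parameters <- function(elastic, damage, hardening, viscosity, yield) {
  stopifnot(inherits(elastic, "elastic_parameters"),
            inherits(damage, "damage_parameters"),
            inherits(hardening, "hardening_parameters"),
            inherits(viscosity, "viscosity_parameters"),
            inherits(yield, "yield_parameters"))
  p <- list(elastic = elastic, damage = damage, hardening = hardening,
            viscosity = viscosity, yield = yield)
  class(p) <- "material_parameters"
  p
}

#' @export
print.material_parameters <- function(x, ...) {
  cat("<material_parameters>\n")
  cat(sprintf("  elastic:   E = (%g, %g, %g) MPa, G = (%g, %g, %g) MPa\n",
              x$elastic$E1, x$elastic$E2, x$elastic$E3,
              x$elastic$G12, x$elastic$G23, x$elastic$G31))
  cat(sprintf("             nu = (%g, %g, %g)\n",
              x$elastic$nu12, x$elastic$nu23, x$elastic$nu31))
  cat(sprintf("  damage:    k0 = %g, kp = %g\n", x$damage$k0, x$damage$kp))
  cat(sprintf("  hardening: yr = %g, sh = %g, ks = %g, ss = %g (%s)\n",
              x$hardening$yr, x$hardening$sh, x$hardening$ks, x$hardening$ss,
              x$hardening$mode))
  cat(sprintf("  viscosity: m = %g, eta = %g s\n", x$viscosity$m, x$viscosity$eta))
  cat(sprintf("  yield:     eps0+ = %g, eps0- = %g, xi0 = %g\n",
              x$yield$eps0p, x$yield$eps0m, x$yield$xi0))
  invisible(x)
}

#' Material state at a point
#'
#' Carries the stress, plastic strain, accumulated plastic strain `kappa`
#' and the damage variable `D`, which is always the damage function
#' evaluated at `kappa`.
#'
#' @param sigma Voigt stress 6-vector (MPa).
#' @param eps_p Voigt plastic strain 6-vector (engineering shear convention).
#' @param kappa accumulated plastic strain (>= 0).
#' @param dp [damage_parameters()] used to derive `D` from `kappa`.
#' @return An object of class `material_state`.
#' @export
material_state <- function(sigma = rep(0, 6), eps_p = rep(0, 6), kappa = 0, dp) {
  sigma <- as.numeric(sigma); eps_p <- as.numeric(eps_p)
  stopifnot(length(sigma) == 6L, length(eps_p) == 6L)
  kappa <- check_scalar(kappa, "kappa", nonneg = TRUE)
  s <- list(sigma = sigma, eps_p = eps_p, kappa = kappa,
            D = damage_value(kappa, dp))
  class(s) <- "material_state"
  s
}

#' Virgin (undeformed, undamaged) material state
#'
#' @param params a [material_parameters()] bundle.
#' @return A `material_state` with zero stress, plastic strain and kappa.
#' @export
initial_state <- function(params) {
  material_state(dp = params$damage)
}
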