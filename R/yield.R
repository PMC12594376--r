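#' Build the Tsai-Wu-type yield tensors
#'
#' Constructs the second-order tensor `A` (Voigt 6-vector, the yield-surface
#' centre direction) and the fourth-order tensor `Afour` (6x6 Voigt matrix)
#' of the orthotropic yield criterion from the yield strains and the elastic
#' constants.
#'
#' The construction maps yield strains to uniaxial yield stresses along each
#' material axis (`sigma0i+ = Ei * eps0p`, `sigma0i- = Ei * eps0m`) and to
#' shear yield stresses `tau0ij = Gij * sqrt(eps0p * eps0m)`, assembles the
#' Tsai-Wu coefficients
#' `Fi = 1/sigma0i+ - 1/sigma0i-`, `Fii = 1/(sigma0i+ sigma0i-)`,
#' `Fij = -xi0 * sqrt(Fii * Fjj)` (normal-normal interaction) and
#' `1/tau0ij^2` on the shear diagonal, and converts the quadric
#' `s:F:s + f.s = 1` to centred form with centre `c = -F^-1 f / 2` on the
#' normal-stress subspace, `A = c` and `Afour = F / (1 + c:F:c)`. The
#' resulting surface passes through all six uniaxial calibration stress
#' states exactly; this is verified at construction rather than assumed.
#'
#' When the fabric vectors of `yp` differ from the global axes, the tensors
#' are assembled in the material frame and transformed to the global frame,
#' so [yield_value()] can be fed global-frame stresses directly.
#'
#' @param yp a [yield_parameters()] object.
#' @param ep an [elastic_parameters()] object.
#' @return An object of class `yield_tensors` with elements `A` (6-vector,
#'   MPa) and `Afour` (6x6, 1/MPa^2).
#' @export
build_yield_tensors <- function(yp, ep) {
  stopifnot(inherits(yp, "yield_parameters"), inherits(ep, "elastic_parameters"))
  E <- c(ep$E1, ep$E2, ep$E3)
  G <- c(ep$G12, ep$G23, ep$G31)
  sig_p <- E * yp$eps0p
  sig_m <- E * yp$eps0m                      # stored positive
  tau0 <- G * sqrt(yp$eps0p * yp$eps0m)

  Fvec <- 1 / sig_p - 1 / sig_m
  Fii <- 1 / (sig_p * sig_m)
  Fn <- diag(Fii)
  for (i in 1:2) for (j in (i + 1):3) {
    Fn[i, j] <- Fn[j, i] <- -yp$xi0 * sqrt(Fii[i] * Fii[j])
  }
  ev <- eigen(Fn, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop_bonevpd(
      sprintf("interaction coefficient xi0 = %g makes the yield quadric indefinite (normal-block eigenvalue %g)",
              yp$xi0, min(ev)),
      "bonevpd_yield_error", data = list(eigenvalues = ev))
  }

  F6 <- matrix(0, 6, 6)
  F6[1:3, 1:3] <- Fn
  diag(F6)[4:6] <- 1 / tau0^2

  cn <- -0.5 * solve(Fn, Fvec)
  centre <- c(cn, 0, 0, 0)
  denom <- 1 + sum(cn * (Fn %*% cn))
  A <- centre
  Afour <- F6 / denom

  ## rotate to the global frame if the fabric triad is not the identity
  Q <- rbind(yp$m1, yp$m2, yp$m3)
  if (max(abs(Q - diag(3))) > 1e-12) {
    M <- bond_stress_matrix(Q)        # sigma_material = M sigma_global
    A <- solve(M, A)
    Afour <- t(M) %*% Afour %*% M
  }
  Afour <- (Afour + t(Afour)) / 2

  yt <- list(A = as.numeric(A), Afour = Afour)
  class(yt) <- "yield_tensors"

  ## construction constraint: Y = 0 at the six uniaxial calibration states
  ## (in the material frame, with r = 1)
  Minv <- if (max(abs(Q - diag(3))) > 1e-12) solve(bond_stress_matrix(Q)) else diag(6)
  for (i in 1:3) {
    for (s in c(sig_p[i], -sig_m[i])) {
      sg <- Minv %*% replace(rep(0, 6), i, s)
      d <- as.numeric(sg) - yt$A
      Yc <- sqrt(sum(d * (yt$Afour %*% d))) - 1
      if (abs(Yc) > 1e-8) {
        stop_bonevpd(
          sprintf("yield surface misses calibration state on axis %d (Y = %g)", i, Yc),
          "bonevpd_yield_error")
      }
    }
  }
  yt
}

#' Yield function value
#'
#' `Y(sigma, kappa) = sqrt((sigma - r A) : Afour : (sigma - r A)) - r` with
#' `r = hardening_value(kappa)`. The square-root form makes Y dimensionless
#' and degree-1 homogeneous about the centre `r A`, so it is directly
#' comparable with the overstress `phi(gamma)`. Negative inside the elastic
#' domain, zero on the yield surface, positive overstress during
#' viscoplastic flow.
#'
#' @param sigma Voigt stress 6-vector (MPa).
#' @param kappa accumulated plastic strain.
#' @param yt a [build_yield_tensors()] object.
#' @param hp a [hardening_parameters()] object.
#' @param mode hardening mode override (see [hardening_value()]).
#' @return Scalar yield value (dimensionless).
#' @export
yield_value <- function(sigma, kappa, yt, hp, mode = hp$mode) {
  stopifnot(inherits(yt, "yield_tensors"), length(sigma) == 6L)
  r <- hardening_value(kappa, hp, mode)
  d <- as.numeric(sigma) - r * yt$A
  sqrt(sum(d * (yt$Afour %*% d))) - r
}

#' Yield-function gradient in stress space
#'
#' `Afour (sigma - r A) / sqrt((sigma - r A) : Afour : (sigma - r A))`;
#' the associated flow direction of the plastic strain rate. Degree-0
#' homogeneous about the centre. Undefined at `sigma = r A` (rejected).
#'
#' @inheritParams yield_value
#' @return Voigt 6-vector gradient (1/MPa); conjugate to engineering-shear
#'   strain components.
#' @export
yield_gradient <- function(sigma, kappa, yt, hp, mode = hp$mode) {
  stopifnot(inherits(yt, "yield_tensors"), length(sigma) == 6L)
  r <- hardening_value(kappa, hp, mode)
  d <- as.numeric(sigma) - r * yt$A
  Ad <- as.numeric(yt$Afour %*% d)
  q <- sum(d * Ad)
  if (q <= 0) {
    stop_bonevpd("yield gradient undefined at the surface centre (sigma = r A)",
                 "bonevpd_yield_error")
  }
  Ad / sqrt(q)
}

## Tensor-consistent norm of a Voigt flow/strain-rate vector: engineering
## shear entries enter with weight 1/2 so the result equals the Euclidean
## norm of the underlying symmetric tensor.
flow_norm <- function(v) {
  sqrt(sum(v[1:3]^2) + 0.5 * sum(v[4:6]^2))
}

#' Generalized yield function
#'
#' `Ybar(sigma, kappa, gamma) = Y(sigma, kappa) - phi(gamma)`. Its zero
#' level set is the viscoplastic consistency condition; together with
#' `gamma >= 0` and `gamma * Ybar = 0` it forms the generalized Kuhn-Tucker
#' conditions. In a converged plastic step `|Ybar| < tol2`.
#'
#' @param sigma Voigt stress 6-vector (MPa).
#' @param kappa accumulated plastic strain.
#' @param gamma consistency parameter (1/s, >= 0).
#' @param params a [material_parameters()] bundle.
#' @return Scalar generalized yield value.
#' @export
generalized_yield <- function(sigma, kappa, gamma, params) {
  stopifnot(inherits(params, "material_parameters"))
  yt <- build_yield_tensors(params$yield, params$elastic)
  yield_value(sigma, kappa, yt, params$hardening) -
    overstress_phi(gamma, params$viscosity)
}
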