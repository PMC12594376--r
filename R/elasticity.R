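#' Orthotropic compliance matrix
#'
#' Assembles the 6x6 compliance in Voigt order (11, 22, 33, 12, 23, 31) with
#' engineering shear strains. The normal-normal couplings are
#' `-nu12/E1` between axes 1-2, `-nu23/E2` between axes 2-3 and `-nu31/E1`
#' between axes 3-1 (the 31-plane ratio is attached to the stiff axis 1, so
#' that `E2 = E3`, `G12 = G31`, `nu12 = nu31` yields exact transverse
#' isotropy about axis 1, as both bone presets do); the shear block is
#' `diag(1/G12, 1/G23, 1/G31)`.
#'
#' @param ep an [elastic_parameters()] object.
#' @return Symmetric 6x6 compliance matrix (1/MPa).
#' @export
build_compliance <- function(ep) {
  stopifnot(inherits(ep, "elastic_parameters"))
  S <- matrix(0, 6, 6)
  diag(S) <- c(1 / ep$E1, 1 / ep$E2, 1 / ep$E3,
               1 / ep$G12, 1 / ep$G23, 1 / ep$G31)
  S[1, 2] <- S[2, 1] <- -ep$nu12 / ep$E1
  S[2, 3] <- S[3, 2] <- -ep$nu23 / ep$E2
  S[3, 1] <- S[1, 3] <- -ep$nu31 / ep$E1
  if (max(abs(S - t(S))) > 1e-8 * max(abs(S))) {
    stop_bonevpd("assembled compliance is not symmetric (Poisson convention violation)",
                 "bonevpd_elasticity_error")
  }
  dimnames(S) <- list(VOIGT_LABELS, VOIGT_LABELS)
  S
}

#' Orthotropic stiffness matrix
#'
#' Inverts the compliance of [build_compliance()] and checks positive
#' definiteness; a parameter set whose stiffness has a non-positive
#' eigenvalue is thermodynamically inadmissible and rejected.
#'
#' @param ep an [elastic_parameters()] object.
#' @return Symmetric positive-definite 6x6 stiffness matrix (MPa).
#' @export
build_stiffness <- function(ep) {
  S <- build_compliance(ep)
  C <- solve(S)
  C <- (C + t(C)) / 2
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop_bonevpd(
      sprintf("stiffness matrix is not positive definite (smallest eigenvalue %g MPa); parameter set is inadmissible",
              min(ev)),
      "bonevpd_elasticity_error", data = list(eigenvalues = ev))
  }
  dimnames(C) <- list(VOIGT_LABELS, VOIGT_LABELS)
  C
}

## Bond-type 6x6 transformation for Voigt stress vectors under a frame
## change with rotation Q (rows = material axes in global coordinates):
## sigma_material = M %*% sigma_global. Built column-wise from the action of
## Q . E_j . Q' on the six symmetric basis tensors.
bond_stress_matrix <- function(Q) {
  M <- matrix(0, 6, 6)
  ij <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(2, 3), c(3, 1))
  for (j in 1:6) {
    E <- matrix(0, 3, 3)
    E[ij[[j]][1], ij[[j]][2]] <- 1
    E[ij[[j]][2], ij[[j]][1]] <- 1
    Tm <- Q %*% E %*% t(Q)
    M[, j] <- c(Tm[1, 1], Tm[2, 2], Tm[3, 3], Tm[1, 2], Tm[2, 3], Tm[3, 1])
  }
  M
}
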