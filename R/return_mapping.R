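#' Return-mapping solver settings
#'
#' @param tol1 residual tolerance on the full nonlinear system (norm of the
#'   stacked residual); default 1e-6.
#' @param tol2 tolerance on the generalized yield function; default 1e-8.
#'   Must be smaller than `tol1`.
#' @param max_iter Newton iteration cap (>= 1).
#' @param jacobian_mode `"finite_difference"` (central differences,
#'   relative perturbation 1e-7) or `"analytic"`.
#' @param polish extra Newton steps taken after both tolerances are met,
#'   driving the residual to near machine level so that nested solvers (the
#'   mixed-control uniaxial driver) see a smooth step response; default 1.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(tol1 = 1e-6, tol2 = 1e-8, max_iter = 50L,
                            jacobian_mode = c("finite_difference", "analytic"),
                            polish = 1L) {
  jacobian_mode <- match.arg(jacobian_mode)
  tol1 <- check_scalar(tol1, "tol1", positive = TRUE)
  tol2 <- check_scalar(tol2, "tol2", positive = TRUE)
  if (tol2 >= tol1) {
    stop_bonevpd("'tol2' must be smaller than 'tol1'", "bonevpd_parameter_error")
  }
  max_iter <- as.integer(check_scalar(max_iter, "max_iter", positive = TRUE))
  s <- list(tol1 = tol1, tol2 = tol2, max_iter = max_iter,
            jacobian_mode = jacobian_mode, polish = as.integer(polish))
  class(s) <- "solver_settings"
  s
}

#' Precompute the matrices a simulation needs
#'
#' Builds the stiffness, the compliance and the yield tensors once so that
#' per-step work is matrix-vector products only.
#'
#' @param params a [material_parameters()] bundle.
#' @return An object of class `compiled_material` with elements `C`
#'   (stiffness), `Einv` (compliance), `yt` (yield tensors) and `params`.
#' @export
compile_material <- function(params) {
  stopifnot(inherits(params, "material_parameters"))
  cm <- list(C = build_stiffness(params$elastic),
             Einv = build_compliance(params$elastic),
             yt = build_yield_tensors(params$yield, params$elastic),
             params = params)
  class(cm) <- "compiled_material"
  cm
}

#' Elastic trial stress
#'
#' Freezes the plastic internal variables at their start-of-step values and
#' computes `sigma_t = (1 - D(kappa_n)) * C * (eps_new - eps_p_n)`.
#'
#' @param state_n start-of-step [material_state()].
#' @param eps_new end-of-step total strain (Voigt 6-vector, engineering
#'   shear).
#' @param params a [material_parameters()] bundle or a
#'   [compile_material()] object.
#' @return Trial stress Voigt 6-vector (MPa).
#' @export
elastic_trial <- function(state_n, eps_new, params) {
  cm <- if (inherits(params, "compiled_material")) params else compile_material(params)
  stopifnot(inherits(state_n, "material_state"), length(eps_new) == 6L)
  as.numeric((1 - state_n$D) * (cm$C %*% (as.numeric(eps_new) - state_n$eps_p)))
}

## Context bundle shared by residual/jacobian/solver.
rm_context <- function(state_n, eps_new, dt, cm, settings) {
  list(state_n = state_n, eps_new = as.numeric(eps_new), dt = dt, cm = cm,
       settings = settings,
       sigma_trial = elastic_trial(state_n, eps_new, cm))
}

#' Return-mapping residual vector
#'
#' Stacks the three blocks of the plastic-corrector system for the unknown
#' vector `x = [sigma (6), gamma, kappa]`:
#' the generalized yield `Ybar = Y(sigma, kappa) - phi(gamma)`, the
#' strain-dimensioned stress residual
#' `R = Einv sigma_t / (1 - D(kappa_n)) - Einv sigma / (1 - D(kappa)) - dt * gamma * gradY`
#' (with `Einv` the undamaged compliance), and the accumulated-plastic-strain
#' evolution `h = kappa_n - kappa + dt * gamma * |gradY|` with the
#' tensor-consistent flow norm. The elastic trial `x = [sigma_t, 0, kappa_n]`
#' zeroes `R` and `h` exactly.
#'
#' @param x numeric 8-vector `[sigma, gamma, kappa]`.
#' @param context as built internally by [integrate_step()]; a list with
#'   `state_n`, `eps_new`, `dt`, `cm` (compiled material) and `sigma_trial`.
#' @return Numeric 8-vector `b = [Ybar, R, h]`.
#' @export
residual_vector <- function(x, context) {
  cm <- context$cm
  p <- cm$params
  sigma <- x[1:6]; gamma <- x[7]; kappa <- x[8]
  D0 <- context$state_n$D
  Dk <- damage_value(max(kappa, 0), p$damage)
  if (Dk >= 1) {
    stop_bonevpd("fully damaged material point (D >= 1)", "bonevpd_state_error")
  }
  r <- hardening_value(max(kappa, 0), p$hardening)
  d <- sigma - r * cm$yt$A
  Ad <- as.numeric(cm$yt$Afour %*% d)
  q <- sum(d * Ad)
  sq <- sqrt(q)
  g <- Ad / sq
  Ybar <- (sq - r) - phi_unchecked(gamma, p$viscosity)
  R <- as.numeric(cm$Einv %*% (context$sigma_trial / (1 - D0) - sigma / (1 - Dk))) -
    context$dt * gamma * g
  h <- context$state_n$kappa - kappa + context$dt * gamma * flow_norm(g)
  c(Ybar, R, h)
}

#' Jacobian of the return-mapping residual
#'
#' Either central finite differences with relative perturbation 1e-7
#' (default) or the closed-form derivative of every block. The two must
#' agree to about 1e-5 relative at any admissible state, which is exercised
#' in the test suite.
#'
#' @inheritParams residual_vector
#' @param mode `"finite_difference"` or `"analytic"`.
#' @return 8x8 Jacobian matrix (rows: Ybar, R, h; columns: sigma, gamma,
#'   kappa).
#' @export
rm_jacobian <- function(x, context, mode = c("finite_difference", "analytic")) {
  mode <- match.arg(mode)
  if (mode == "finite_difference") {
    B <- matrix(0, 8, 8)
    for (i in 1:8) {
      h <- 1e-7 * max(abs(x[i]), 1)
      xp <- x; xp[i] <- x[i] + h
      xm <- x; xm[i] <- x[i] - h
      B[, i] <- (residual_vector(xp, context) - residual_vector(xm, context)) / (2 * h)
    }
    return(B)
  }
  cm <- context$cm
  p <- cm$params
  sigma <- x[1:6]; gamma <- x[7]; kappa <- max(x[8], 0)
  Dk <- damage_value(kappa, p$damage)
  Dk_d <- damage_rate(kappa, p$damage)
  r <- hardening_value(kappa, p$hardening)
  r_d <- hardening_rate(kappa, p$hardening)
  A <- cm$yt$A; AF <- cm$yt$Afour
  d <- sigma - r * A
  Ad <- as.numeric(AF %*% d)
  q <- sum(d * Ad); sq <- sqrt(q)
  g <- Ad / sq
  dg_dd <- (AF - tcrossprod(g)) / sq       # d g / d d (6x6)
  dg_dk <- as.numeric(dg_dd %*% (-r_d * A))
  w <- c(1, 1, 1, 0.5, 0.5, 0.5)
  ng <- flow_norm(g)
  dn_dg <- w * g / ng

  B <- matrix(0, 8, 8)
  ## row 1: Ybar
  B[1, 1:6] <- g
  B[1, 7] <- -phi_rate(gamma, p$viscosity)
  B[1, 8] <- -r_d * (sum(A * Ad) / sq + 1)
  ## rows 2-7: R
  B[2:7, 1:6] <- -cm$Einv / (1 - Dk) - context$dt * gamma * dg_dd
  B[2:7, 7] <- -context$dt * g
  B[2:7, 8] <- -as.numeric(cm$Einv %*% sigma) * Dk_d / (1 - Dk)^2 -
    context$dt * gamma * dg_dk
  ## row 8: h
  B[8, 1:6] <- context$dt * gamma * as.numeric(dn_dg %*% dg_dd)
  B[8, 7] <- context$dt * ng
  B[8, 8] <- -1 + context$dt * gamma * sum(dn_dg * dg_dk)
  B
}

#' Integrate one strain-driven time step
#'
#' Elastic-predictor / plastic-corrector update of a material point. The
#' elastic trial is accepted when its yield value is non-positive;
#' otherwise the three-block system (generalized yield, stress residual,
#' kappa evolution) is solved by Newton-Raphson from
#' `x0 = [sigma_trial, 0, kappa_n]` until the stacked residual norm is below
#' `tol1` and `|Ybar|` below `tol2`. The converged step updates the plastic
#' strain through the flow rule, kappa (non-decreasing) and the damage
#' variable.
#'
#' @param state_n start-of-step [material_state()].
#' @param eps_new end-of-step total strain (Voigt 6-vector).
#' @param dt time step (s, > 0).
#' @param params a [material_parameters()] bundle or a
#'   [compile_material()] object.
#' @param settings a [solver_settings()] object.
#' @return An object of class `step_result`: list with `state`
#'   (end-of-step `material_state`), `regime` (`"elastic"` or `"plastic"`),
#'   `iterations`, `residual_norm`, `gamma` and `Ybar`.
#' @export
integrate_step <- function(state_n, eps_new, dt, params,
                           settings = solver_settings()) {
  cm <- if (inherits(params, "compiled_material")) params else compile_material(params)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop_bonevpd("'dt' must be a positive scalar", "bonevpd_parameter_error")
  }
  p <- cm$params
  ctx <- rm_context(state_n, eps_new, dt, cm, settings)
  Yt <- yield_value(ctx$sigma_trial, state_n$kappa, cm$yt, p$hardening)

  if (Yt <= 0) {
    st <- material_state(sigma = ctx$sigma_trial, eps_p = state_n$eps_p,
                         kappa = state_n$kappa, dp = p$damage)
    out <- list(state = st, regime = "elastic", iterations = 0L,
                residual_norm = 0, gamma = 0, Ybar = Yt)
    class(out) <- "step_result"
    return(out)
  }

  x <- c(ctx$sigma_trial, 0, state_n$kappa)
  iter <- 0L
  b <- residual_vector(x, ctx)
  res <- sqrt(sum(b^2))
  repeat {
    if (res < settings$tol1 && abs(b[1]) < settings$tol2) break
    if (iter >= settings$max_iter) {
      stop_bonevpd(
        sprintf("return mapping did not converge in %d iterations (residual %g, |Ybar| %g)",
                settings$max_iter, res, abs(b[1])),
        "bonevpd_convergence_error",
        data = list(residual_norm = res, x = x))
    }
    B <- rm_jacobian(x, ctx, settings$jacobian_mode)
    dx <- tryCatch(solve(B, b), error = function(e) {
      stop_bonevpd(
        sprintf("singular return-mapping Jacobian (reciprocal condition number %g)",
                rcond(B)),
        "bonevpd_convergence_error", data = list(residual_norm = res, x = x))
    })
    x <- x - dx
    iter <- iter + 1L
    b <- residual_vector(x, ctx)
    newres <- sqrt(sum(b^2))
    if (!is.finite(newres)) {
      stop_bonevpd("NaN in return-mapping residual", "bonevpd_convergence_error",
                   data = list(residual_norm = res, x = x))
    }
    res <- newres
  }

  ## polish: extra Newton steps sharpen the converged point to ~machine
  ## precision (kept only if they do not degrade the residual)
  for (k in seq_len(settings$polish)) {
    B <- rm_jacobian(x, ctx, settings$jacobian_mode)
    xp <- tryCatch(x - solve(B, b), error = function(e) NULL)
    if (is.null(xp)) break
    bp <- residual_vector(xp, ctx)
    resp <- sqrt(sum(bp^2))
    if (is.finite(resp) && resp < res) {
      x <- xp; b <- bp; res <- resp; iter <- iter + 1L
    } else break
  }

  gamma <- x[7]; kappa <- x[8]
  if (gamma < -1e-10 || kappa < state_n$kappa - 1e-12) {
    stop_bonevpd(
      sprintf("return mapping converged to an inadmissible state (gamma = %g, dkappa = %g)",
              gamma, kappa - state_n$kappa),
      "bonevpd_convergence_error", data = list(residual_norm = res, x = x))
  }
  gamma <- max(gamma, 0)
  kappa <- max(kappa, state_n$kappa)
  g <- yield_gradient(x[1:6], kappa, cm$yt, p$hardening)
  st <- material_state(sigma = x[1:6],
                       eps_p = state_n$eps_p + dt * gamma * g,
                       kappa = kappa, dp = p$damage)
  out <- list(state = st, regime = "plastic", iterations = iter,
              residual_norm = res, gamma = gamma, Ybar = b[1])
  class(out) <- "step_result"
  out
}

## Driver-level rescue: on Newton failure, bisect the strain increment (and
## the time step with it) recursively, up to max_bisect levels. Returns the
## step_result of the final sub-increment (whose state is the end state).
integrate_substep <- function(state_n, eps_from, eps_new, dt, cm, settings,
                              max_bisect = 10L) {
  tryCatch(
    integrate_step(state_n, eps_new, dt, cm, settings),
    bonevpd_convergence_error = function(e) {
      if (max_bisect <= 0L) stop(e)
      eps_mid <- (as.numeric(eps_from) + as.numeric(eps_new)) / 2
      half <- integrate_substep(state_n, eps_from, eps_mid, dt / 2, cm,
                                settings, max_bisect - 1L)
      integrate_substep(half$state, eps_mid, eps_new, dt / 2, cm,
                        settings, max_bisect - 1L)
    }
  )
}
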