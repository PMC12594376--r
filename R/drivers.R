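#' Define a material-point loading program
#'
#' A program is either an explicit strain path (`kind = "strain_path"`,
#' supply `times` and `strains`), a mixed-control uniaxial test
#' (`kind = "uniaxial"`: the axial strain is ramped while the lateral normal
#' strains are solved so the transverse normal stresses vanish), or a
#' ramp-and-hold relaxation test (`kind = "relaxation"`).
#'
#' The time discretisation is given by `dt_schedule`, an ordered
#' data.frame with columns `until` (s) and `dt` (s): each row's `dt`
#' applies up to its `until` time. Defaults mirror the calibration-style
#' runs (`dt = 0.01` s over a 1 s ramp) and, for relaxation holds, a
#' variable step growing from 10 s to 500 s out to `t_hold`.
#'
#' @param kind `"strain_path"`, `"uniaxial"` or `"relaxation"`.
#' @param axis material direction index (1-3) for uniaxial/relaxation.
#' @param amplitude target axial strain (signed, dimensionless).
#' @param t_ramp ramp duration (s, > 0).
#' @param t_hold hold duration (s, relaxation only).
#' @param dt_schedule data.frame(until, dt); `NULL` for the defaults.
#' @param times,strains explicit path (strain_path only): `times` of length
#'   n+1 starting at 0, `strains` an (n+1) x 6 Voigt strain matrix.
#' @return An object of class `loading_program`.
#' @export
loading_program <- function(kind = c("strain_path", "uniaxial", "relaxation"),
                            axis = 1L, amplitude = 0, t_ramp = 1, t_hold = 1e4,
                            dt_schedule = NULL, times = NULL, strains = NULL) {
  kind <- match.arg(kind)
  if (kind == "strain_path") {
    stopifnot(!is.null(times), !is.null(strains))
    times <- as.numeric(times)
    strains <- as.matrix(strains)
    if (nrow(strains) != length(times) || ncol(strains) != 6L) {
      stop_bonevpd("'strains' must be a length(times) x 6 matrix",
                   "bonevpd_program_error")
    }
    if (times[1] != 0 || any(diff(times) <= 0)) {
      stop_bonevpd("'times' must start at 0 and be strictly increasing",
                   "bonevpd_program_error")
    }
    prog <- list(kind = kind, times = times, strains = strains)
  } else {
    axis <- as.integer(axis)
    stopifnot(axis %in% 1:3)
    check_scalar(t_ramp, "t_ramp", positive = TRUE)
    if (kind == "relaxation") check_scalar(t_hold, "t_hold", positive = TRUE)
    t_end <- if (kind == "relaxation") t_ramp + t_hold else t_ramp
    if (is.null(dt_schedule)) {
      dt_schedule <- data.frame(until = t_ramp, dt = t_ramp / 100)
      if (kind == "relaxation") {
        dt_schedule <- rbind(dt_schedule, data.frame(
          until = pmin(t_ramp + c(100, 1000, 5000, t_hold), t_ramp + t_hold),
          dt = c(10, 50, 200, 500)))
        dt_schedule <- dt_schedule[!duplicated(dt_schedule$until), ]
      }
    }
    stopifnot(is.data.frame(dt_schedule),
              all(c("until", "dt") %in% names(dt_schedule)))
    if (any(dt_schedule$dt <= 0) || any(diff(dt_schedule$until) <= 0)) {
      stop_bonevpd("'dt_schedule' must have positive dt and increasing until times",
                   "bonevpd_program_error")
    }
    if (max(dt_schedule$until) < t_end - 1e-9) {
      stop_bonevpd("'dt_schedule' does not cover the full program duration",
                   "bonevpd_program_error")
    }
    prog <- list(kind = kind, axis = axis, amplitude = as.numeric(amplitude),
                 t_ramp = t_ramp, t_hold = if (kind == "relaxation") t_hold else 0,
                 dt_schedule = dt_schedule,
                 times = schedule_times(dt_schedule, t_end))
  }
  class(prog) <- "loading_program"
  prog
}

## Expand a (until, dt) schedule into the step-time vector [0, ..., t_end].
schedule_times <- function(schedule, t_end) {
  t <- 0
  times <- 0
  while (t < t_end - 1e-9) {
    row <- which(schedule$until > t + 1e-9)[1]
    if (is.na(row)) break
    t <- min(t + schedule$dt[row], t_end)
    times <- c(times, t)
  }
  times
}

record_row <- function(t, eps, state, cm, regime, iterations,
                       gamma = 0, residual = 0, Ybar = NA_real_) {
  Y <- yield_value(state$sigma, state$kappa, cm$yt, cm$params$hardening)
  as.data.frame(c(
    list(t = t),
    stats::setNames(as.list(eps), paste0("eps_", VOIGT_LABELS)),
    stats::setNames(as.list(state$sigma), paste0("sig_", VOIGT_LABELS)),
    list(kappa = state$kappa, D = state$D, Y = Y,
         regime = regime, iterations = iterations,
         gamma = gamma, residual = residual, Ybar = Ybar)
  ))
}

finish_record <- function(rows) {
  rec <- do.call(rbind, rows)
  rownames(rec) <- NULL
  class(rec) <- c("response_record", "data.frame")
  rec
}

#' Run a strain-controlled path
#'
#' Integrates every increment of an explicit strain path with
#' [integrate_step()], bisecting increments that fail to converge. The
#' returned record has one row per step plus the initial state.
#'
#' @param program a `"strain_path"` [loading_program()].
#' @param params a [material_parameters()] bundle.
#' @param settings a [solver_settings()] object.
#' @return A `response_record` data.frame with columns `t`, the six strain
#'   and six stress components, `kappa`, `D`, `Y`, `regime`, `iterations`,
#'   and the per-step solver diagnostics `gamma`, `residual`, `Ybar`.
#' @export
run_strain_path <- function(program, params, settings = solver_settings()) {
  stopifnot(inherits(program, "loading_program"), program$kind == "strain_path")
  cm <- compile_material(params)
  state <- initial_state(cm$params)
  n <- length(program$times)
  rows <- vector("list", n)
  rows[[1]] <- record_row(program$times[1], program$strains[1, ], state, cm,
                          "initial", 0L)
  for (i in 2:n) {
    res <- tryCatch(
      integrate_substep(state, program$strains[i - 1, ], program$strains[i, ],
                        program$times[i] - program$times[i - 1], cm, settings),
      bonevpd_convergence_error = function(e) {
        stop_bonevpd(sprintf("step %d (t = %g s): %s", i - 1,
                             program$times[i], conditionMessage(e)),
                     "bonevpd_driver_error")
      })
    state <- res$state
    rows[[i]] <- record_row(program$times[i], program$strains[i, ], state, cm,
                            res$regime, res$iterations,
                            res$gamma, res$residual_norm, res$Ybar)
  }
  finish_record(rows)
}

## Mixed-control driver shared by run_uniaxial and run_relaxation: the axial
## strain follows axial_of_t; the two lateral normal strains are solved by a
## small Newton loop so the transverse normal stresses vanish (< tol_trans
## MPa); shear components stay identically zero.
run_mixed_uniaxial <- function(times, axial, axis, cm, settings,
                               tol_trans = 1e-6, max_inner = 30L) {
  lat <- setdiff(1:3, axis)
  S <- cm$Einv
  ratio <- S[lat, axis] / S[axis, axis]    # elastic lateral/axial strain ratio
  state <- initial_state(cm$params)
  n <- length(times)
  rows <- vector("list", n)
  eps_prev <- rep(0, 6)
  rows[[1]] <- record_row(times[1], eps_prev, state, cm, "initial", 0L)
  u <- c(0, 0)

  for (i in 2:n) {
    dt <- times[i] - times[i - 1]
    a_new <- axial[i]
    u <- u + ratio * (a_new - axial[i - 1])
    make_eps <- function(u) {
      e <- rep(0, 6); e[axis] <- a_new; e[lat] <- u; e
    }
    eval_step <- function(u) {
      integrate_substep(state, eps_prev, make_eps(u), dt, cm, settings)
    }
    res <- eval_step(u)
    g <- res$state$sigma[lat]
    J <- NULL
    inner <- 0L
    while (max(abs(g)) >= tol_trans) {
      if (inner >= max_inner) {
        stop_bonevpd(
          sprintf("uniaxial driver: transverse stresses did not vanish at step %d (t = %g s, residual %g MPa)",
                  i - 1, times[i], max(abs(g))),
          "bonevpd_driver_error")
      }
      if (is.null(J) || inner %% 8L == 7L) {
        h <- 1e-6
        J <- matrix(0, 2, 2)
        for (j in 1:2) {
          up <- u; up[j] <- u[j] + h
          um <- u; um[j] <- u[j] - h
          J[, j] <- (eval_step(up)$state$sigma[lat] -
                       eval_step(um)$state$sigma[lat]) / (2 * h)
        }
      }
      du <- tryCatch(solve(J, g), error = function(e) {
        stop_bonevpd(sprintf("uniaxial driver: singular lateral Jacobian at step %d", i - 1),
                     "bonevpd_driver_error")
      })
      u <- u - du
      res <- eval_step(u)
      g <- res$state$sigma[lat]
      inner <- inner + 1L
    }
    state <- res$state
    eps_prev <- make_eps(u)
    rows[[i]] <- record_row(times[i], eps_prev, state, cm, res$regime,
                            res$iterations, res$gamma, res$residual_norm,
                            res$Ybar)
  }
  finish_record(rows)
}

#' Run a mixed-control uniaxial test
#'
#' Ramps the axial strain along the chosen material axis while solving the
#' two lateral normal strains at every step so the transverse normal
#' stresses vanish (within 1e-6 MPa); shear components are identically
#' zero. This reproduces a monotonic uniaxial tension/compression test on a
#' homogeneous specimen core.
#'
#' @param program a `"uniaxial"` [loading_program()].
#' @inheritParams run_strain_path
#' @return A `response_record` (see [run_strain_path()]).
#' @export
run_uniaxial <- function(program, params, settings = solver_settings()) {
  stopifnot(inherits(program, "loading_program"), program$kind == "uniaxial")
  cm <- compile_material(params)
  axial <- program$amplitude * program$times / program$t_ramp
  run_mixed_uniaxial(program$times, axial, program$axis, cm, settings)
}

#' Run a ramp-and-hold relaxation test
#'
#' Ramps the axial strain to `amplitude` over `t_ramp`, then holds it fixed
#' for `t_hold`. An elastic state carries no overstress and relaxes not at
#' all; from a plastic state the overstress decays monotonically towards
#' zero, leaving the rate-independent equilibrium stress for the attained
#' kappa as a nonzero asymptote.
#'
#' @param program a `"relaxation"` [loading_program()].
#' @inheritParams run_strain_path
#' @return A `response_record` (see [run_strain_path()]).
#' @export
run_relaxation <- function(program, params, settings = solver_settings()) {
  stopifnot(inherits(program, "loading_program"), program$kind == "relaxation")
  cm <- compile_material(params)
  axial <- ifelse(program$times < program$t_ramp,
                  program$amplitude * program$times / program$t_ramp,
                  program$amplitude)
  rec <- run_mixed_uniaxial(program$times, axial, program$axis, cm, settings)
  if (!any(rec$regime == "plastic")) {
    warning("relaxation program never entered the plastic regime; stress will not relax")
  }
  rec
}
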