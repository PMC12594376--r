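## Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Calibrated bone material presets
#'
#' Loads the packaged parameter set for cortical (bovine femoral) or
#' trabecular (human lumbar spine) bone. Cortical elastic constants are
#' stored in GPa in the preset file and converted to the package's internal
#' MPa unit at load time. With `reduced = TRUE` the tensile/compressive
#' yield strains are swapped for their long-time equilibrium values
#' (the calibrated strains scaled by the mean relaxation reduction), the
#' set appropriate for viscoplastic simulations.
#'
#' @param tissue `"cortical"` or `"trabecular"`.
#' @param reduced use the reduced (equilibrium) yield strains; default
#'   `FALSE`.
#' @return A [material_parameters()] bundle.
#' @export
#' @examples
#' preset_parameters("cortical")$elastic$E1  # 19900 MPa
preset_parameters <- function(tissue = c("cortical", "trabecular"),
                              reduced = FALSE) {
  tissue <- match.arg(tissue)
  path <- system.file("extdata", paste0(tissue, ".yaml"), package = "bonevpd",
                      mustWork = TRUE)
  lst <- yaml::read_yaml(path)
  if (reduced) {
    lst$yield$eps0p <- lst$reduced_yield$eps0p
    lst$yield$eps0m <- lst$reduced_yield$eps0m
  }
  params_from_list(lst)
}

#' Generate a synthetic relaxation series with known ground truth
#'
#' Samples `s = a * t^(-b) * (1 + e)`, `e ~ Normal(0, noise_sd)`, at `n`
#' log-spaced times on [1, 1e3] s. Deterministic given the seed; the ground
#' truth for power-law recovery tests.
#'
#' @param a prefactor (> 0).
#' @param b exponent (>= 0).
#' @param n number of samples (>= 3).
#' @param noise_sd multiplicative noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return A [relaxation_series()].
#' @export
make_relaxation_series <- function(a, b, n = 50L, noise_sd = 0, seed = 1L) {
  check_scalar(a, "a", positive = TRUE)
  check_scalar(b, "b", nonneg = TRUE)
  n <- as.integer(check_scalar(n, "n", positive = TRUE))
  if (n < 3L) stop_bonevpd("'n' must be >= 3", "bonevpd_parameter_error")
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  t <- 10^seq(0, 3, length.out = n)
  s <- with_seed(seed, a * t^(-b) * (1 + stats::rnorm(n, 0, noise_sd)))
  if (any(s <= 0)) {
    stop_bonevpd("noise drove a stress sample non-positive; reduce 'noise_sd'",
                 "bonevpd_parameter_error")
  }
  # noise intentionally breaks strict monotonicity; no need to warn here
  suppressWarnings(
    relaxation_series(t, s, label = sprintf("synthetic(a=%g, b=%g)", a, b)))
}

#' Analytic orientation frame fields
#'
#' Evaluates the triad of one of the synthetic frame fields at arbitrary
#' positions: `"uniform"` (global axes everywhere), `"cylindrical"`
#' (axis 1 tangential, axis 2 radial, axis 3 along z) or `"torus_like"`
#' (axis 1 toroidal, axis 2 pointing out of the tube). All frames are
#' orthonormal and right-handed by construction.
#'
#' @param field field name.
#' @param positions M x 3 matrix.
#' @return M x 3 x 3 array of triads (rows of `[i, , ]` = axes 1, 2, 3).
#' @export
orientation_field <- function(field = c("uniform", "cylindrical", "torus_like"),
                              positions) {
  field <- match.arg(field)
  positions <- as.matrix(positions)
  m <- nrow(positions)
  triads <- array(0, c(m, 3L, 3L))
  for (i in seq_len(m)) {
    p <- positions[i, ]
    if (field == "uniform") {
      R <- diag(3)
    } else if (field == "cylindrical") {
      th <- atan2(p[2], p[1])
      a1 <- c(sin(th), -cos(th), 0)          # tangential
      a2 <- c(cos(th), sin(th), 0)           # radial (axis 2 = +x on the +x axis)
      R <- rbind(a1, a2, c(0, 0, 1))
    } else {
      u <- atan2(p[2], p[1])                 # toroidal angle
      rho <- sqrt(p[1]^2 + p[2]^2)
      v <- atan2(p[3], rho - TORUS_R0)       # poloidal angle
      a1 <- c(-sin(u), cos(u), 0)            # toroidal tangent
      a2 <- c(cos(u) * cos(v), sin(u) * cos(v), sin(v))  # out of the tube
      a3 <- c(a1[2] * a2[3] - a1[3] * a2[2],
              a1[3] * a2[1] - a1[1] * a2[3],
              a1[1] * a2[2] - a1[2] * a2[1])
      R <- rbind(a1, a2, a3)
    }
    triads[i, , ] <- R
  }
  triads
}

TORUS_R0 <- 10  # major radius (mm) of the torus_like field

#' Generate a synthetic orientation cloud
#'
#' Samples positions in a simple analytic solid and attaches the triads of
#' the corresponding [orientation_field()]: `"uniform"` fills the unit
#' cube, `"cylindrical"` a thick cylindrical shell (radii 5-10 mm, height
#' 20 mm), `"torus_like"` half a torus (major radius 10 mm, tube radius
#' 1-3 mm). Deterministic given the seed.
#'
#' @param field field name (see [orientation_field()]).
#' @param n number of points (>= 1).
#' @param seed RNG seed.
#' @return An [orientation_cloud()].
#' @export
make_orientation_cloud <- function(field = c("uniform", "cylindrical", "torus_like"),
                                   n = 1000L, seed = 1L) {
  field <- match.arg(field)
  n <- as.integer(check_scalar(n, "n", positive = TRUE))
  pts <- with_seed(seed, {
    if (field == "uniform") {
      cbind(stats::runif(n), stats::runif(n), stats::runif(n))
    } else if (field == "cylindrical") {
      r <- sqrt(stats::runif(n, 5^2, 10^2))
      th <- stats::runif(n, 0, 2 * pi)
      cbind(r * cos(th), r * sin(th), stats::runif(n, 0, 20))
    } else {
      u <- stats::runif(n, 0, pi)
      v <- stats::runif(n, 0, 2 * pi)
      rr <- sqrt(stats::runif(n, 1, 3^2))
      cbind((TORUS_R0 + rr * cos(v)) * cos(u),
            (TORUS_R0 + rr * cos(v)) * sin(u),
            rr * sin(v))
    }
  })
  orientation_cloud(pts, orientation_field(field, pts))
}

#' Generate a strain-path loading program
#'
#' Builds an explicit strain-controlled program along one material axis:
#' `"ramp"` (linear to `amplitude`), `"ramp_hold"` (linear ramp, then the
#' strain held on a coarsening 10-500 s step schedule) or `"sawtooth"`
#' (ramp up, back through zero to `-amplitude`, and return). Defaults
#' mirror calibration-style runs: 1 s total, 100 steps, dt = 0.01 s.
#'
#' @param kind `"ramp"`, `"ramp_hold"` or `"sawtooth"`.
#' @param amplitude target strain (signed).
#' @param n_steps ramp step count (>= 1).
#' @param rate strain rate (1/s); when given it sets the ramp duration
#'   `abs(amplitude)/rate`, otherwise `total_time` is used.
#' @param axis strained material direction (1-6 Voigt index).
#' @param total_time ramp duration (s) when `rate` is `NULL`.
#' @param t_hold hold duration for `"ramp_hold"` (s).
#' @return A `"strain_path"` [loading_program()].
#' @export
make_strain_program <- function(kind = c("ramp", "ramp_hold", "sawtooth"),
                                amplitude, n_steps = 100L, rate = NULL,
                                axis = 1L, total_time = 1, t_hold = 1e4) {
  kind <- match.arg(kind)
  n_steps <- as.integer(check_scalar(n_steps, "n_steps", positive = TRUE))
  axis <- as.integer(axis)
  stopifnot(axis %in% 1:6)
  t_ramp <- if (is.null(rate)) total_time else abs(amplitude) / rate
  if (amplitude == 0) t_ramp <- total_time
  check_scalar(t_ramp, "ramp duration", positive = TRUE)

  times <- seq(0, t_ramp, length.out = n_steps + 1L)
  ax <- amplitude * times / t_ramp
  if (kind == "sawtooth") {
    seg <- function(from, to) from + (to - from) * seq_len(n_steps) / n_steps
    ax <- c(ax, seg(amplitude, -amplitude), seg(-amplitude, 0))
    times <- seq(0, 3 * t_ramp, length.out = 3L * n_steps + 1L)
  } else if (kind == "ramp_hold") {
    sched <- data.frame(until = pmin(c(100, 1000, 5000, t_hold), t_hold),
                        dt = c(10, 50, 200, 500))
    sched <- sched[!duplicated(sched$until), ]
    hold_times <- t_ramp + schedule_times(sched, t_hold)[-1]
    times <- c(times, hold_times)
    ax <- c(ax, rep(amplitude, length(hold_times)))
  }
  strains <- matrix(0, length(times), 6L)
  strains[, axis] <- ax
  loading_program(kind = "strain_path", times = times, strains = strains)
}
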