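## Assemble a material_parameters bundle from a plain list (parsed YAML or
## JSON). Elastic constants may carry a `units` field ("GPa" or "MPa").
params_from_list <- function(lst) {
  el <- lst$elastic
  scale <- switch(tolower(el$units %||% "MPa"), gpa = 1000, mpa = 1,
                  stop_bonevpd(sprintf("unknown elastic units '%s'", el$units),
                               "bonevpd_io_error"))
  hmode <- lst$hardening$mode %||% "softening"
  material_parameters(
    elastic = elastic_parameters(el$E1 * scale, el$E2 * scale, el$E3 * scale,
                                 el$nu12, el$nu23, el$nu31,
                                 el$G12 * scale, el$G23 * scale, el$G31 * scale),
    damage = damage_parameters(k0 = lst$damage$k0, kp = lst$damage$kp),
    hardening = hardening_parameters(yr = lst$hardening$yr, sh = lst$hardening$sh,
                                     ks = lst$hardening$ks, ss = lst$hardening$ss,
                                     mode = hmode),
    viscosity = viscosity_parameters(m = lst$viscosity$m, eta = lst$viscosity$eta),
    yield = yield_parameters(eps0p = lst$yield$eps0p, eps0m = lst$yield$eps0m,
                             xi0 = lst$yield$xi0,
                             m1 = lst$yield$m1 %||% c(1, 0, 0),
                             m2 = lst$yield$m2 %||% c(0, 1, 0),
                             m3 = lst$yield$m3 %||% c(0, 0, 1))
  )
}

params_to_list <- function(params) {
  el <- params$elastic
  list(
    elastic = list(units = "MPa", E1 = el$E1, E2 = el$E2, E3 = el$E3,
                   nu12 = el$nu12, nu23 = el$nu23, nu31 = el$nu31,
                   G12 = el$G12, G23 = el$G23, G31 = el$G31),
    damage = list(kp = params$damage$kp, k0 = params$damage$k0),
    hardening = list(yr = params$hardening$yr, ks = params$hardening$ks,
                     sh = params$hardening$sh, ss = params$hardening$ss,
                     mode = params$hardening$mode),
    viscosity = list(m = params$viscosity$m, eta = params$viscosity$eta),
    yield = list(eps0p = params$yield$eps0p, eps0m = params$yield$eps0m,
                 xi0 = params$yield$xi0, m1 = params$yield$m1,
                 m2 = params$yield$m2, m3 = params$yield$m3)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read material parameters from a YAML or JSON file
#'
#' The file mirrors the parameter tables: sections `elastic` (with an
#' optional `units` field, GPa or MPa), `damage`, `hardening`, `viscosity`
#' and `yield`. The format is chosen by file extension.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return A [material_parameters()] bundle (internal unit MPa).
#' @export
read_material_parameters <- function(path) {
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  params_from_list(lst)
}

#' Write material parameters to a YAML or JSON file
#'
#' @param params a [material_parameters()] bundle.
#' @param path destination path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_material_parameters <- function(params, path) {
  stopifnot(inherits(params, "material_parameters"))
  lst <- params_to_list(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' Write a response record to CSV
#'
#' @param record a `response_record` from one of the drivers.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_response_csv <- function(record, path) {
  stopifnot(inherits(record, "response_record"))
  utils::write.csv(record, path, row.names = FALSE)
  invisible(path)
}

#' Read a relaxation series from a two-column CSV
#'
#' Expects columns `t_seconds` and `normalized_stress` (or any two first
#' columns in that order).
#'
#' @param path CSV path.
#' @param label curve identifier; defaults to the file name.
#' @return A [relaxation_series()].
#' @export
read_relaxation_csv <- function(path, label = basename(path)) {
  d <- utils::read.csv(path)
  relaxation_series(d[[1]], d[[2]], label = label)
}

#' Read an orientation cloud from CSV
#'
#' Expects 12 columns: `x, y, z` positions and the 9 triad components
#' `a1x, a1y, a1z, a2x, ..., a3z` (axes as rows).
#'
#' @param path CSV path.
#' @return An [orientation_cloud()].
#' @export
read_cloud_csv <- function(path) {
  d <- as.matrix(utils::read.csv(path))
  if (ncol(d) != 12L) {
    stop_bonevpd("cloud CSV must have 12 columns (x,y,z,a1x..a3z)",
                 "bonevpd_io_error")
  }
  n <- nrow(d)
  triads <- array(0, c(n, 3L, 3L))
  for (i in seq_len(n)) triads[i, , ] <- matrix(d[i, 4:12], 3, 3, byrow = TRUE)
  orientation_cloud(d[, 1:3, drop = FALSE], triads)
}

#' Write an orientation cloud to CSV
#'
#' @param cloud an [orientation_cloud()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_cloud_csv <- function(cloud, path) {
  stopifnot(inherits(cloud, "orientation_cloud"))
  n <- nrow(cloud$points)
  tri <- t(vapply(seq_len(n), function(i) as.numeric(t(cloud$triads[i, , ])),
                  numeric(9)))
  d <- cbind(cloud$points, tri)
  colnames(d) <- c("x", "y", "z",
                   paste0("a", rep(1:3, each = 3), c("x", "y", "z")))
  utils::write.csv(as.data.frame(d), path, row.names = FALSE)
  invisible(path)
}

#' Write an axis assignment to CSV
#'
#' One row per query: source cloud index, distance and the 9 assigned triad
#' components.
#'
#' @param assignment an [assign_axes()] result.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_assignment_csv <- function(assignment, path) {
  stopifnot(inherits(assignment, "axis_assignment"))
  m <- length(assignment$source_index)
  tri <- t(vapply(seq_len(m), function(i) as.numeric(t(assignment$triads[i, , ])),
                  numeric(9)))
  d <- data.frame(source_index = assignment$source_index,
                  distance = assignment$distance)
  d <- cbind(d, as.data.frame(tri))
  names(d)[3:11] <- paste0("a", rep(1:3, each = 3), c("x", "y", "z"))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Export an assigned orientation field as legacy-VTK polydata
#'
#' Writes query positions with the three assigned axes as point-data vector
#' fields for visual inspection in ParaView or similar.
#'
#' @param queries M x 3 matrix of query positions.
#' @param assignment an [assign_axes()] result for those queries.
#' @param path destination `.vtk` path (ASCII legacy format).
#' @return `path`, invisibly.
#' @export
write_orientation_vtk <- function(queries, assignment, path) {
  stopifnot(inherits(assignment, "axis_assignment"))
  queries <- as.matrix(queries)
  m <- nrow(queries)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "assigned orthotropic axes", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", m)), con)
  utils::write.table(queries, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("POINT_DATA %d", m), con)
  for (a in 1:3) {
    writeLines(c(sprintf("VECTORS axis%d double", a)), con)
    utils::write.table(assignment$triads[, a, ], con,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
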