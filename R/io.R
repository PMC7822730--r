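## Columnar text formats shared across the analysis: all files are plain
## whitespace-separated tables with "# key: value" header lines carrying
## units and metadata.

.write_header <- function(path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    v <- meta[[k]]
    if (!is.na(v) && nzchar(as.character(v))) {
      writeLines(sprintf("# %s: %s", k, format(v, digits = 15)), con)
    }
  }
  invisible(path)
}

.read_meta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  meta
}

.append_table <- function(path, df) {
  # write.table warns when appending column names below the header lines
  suppressWarnings(utils::write.table(df, path, append = TRUE,
                                      row.names = FALSE, col.names = TRUE,
                                      quote = FALSE))
}

.read_table <- function(path) {
  utils::read.table(path, header = TRUE, comment.char = "#")
}

#' Write a scattering curve to a three-column text file
#'
#' Columns \code{q I err} with header lines declaring the q unit and the
#' concentration.
#'
#' @param curve A [scattering_curve()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_scattering_curve <- function(curve, path) {
  stopifnot(inherits(curve, "scattering_curve"))
  .write_header(path, list(q_unit = "per_nm",
                           concentration_mg_ml = curve$concentration,
                           label = curve$label))
  .append_table(path, data.frame(q = curve$q, I = curve$I, err = curve$err))
  invisible(path)
}

#' Read a scattering curve written by [write_scattering_curve()]
#'
#' @param path Input path.
#' @return A [scattering_curve()].
#' @export
read_scattering_curve <- function(path) {
  meta <- .read_meta(path)
  d <- .read_table(path)
  qu <- if (!is.null(meta$q_unit)) meta$q_unit else "per_nm"
  conc <- if (!is.null(meta$concentration_mg_ml))
    as.numeric(meta$concentration_mg_ml) else NA_real_
  scattering_curve(d$q, d$I, d$err, q_unit = qu, concentration = conc,
                   label = if (!is.null(meta$label)) meta$label else "")
}

#' Write a DLS correlogram
#'
#' Columns \code{lag_us g2 err} with q, temperature and solvent-viscosity
#' metadata in the header.
#'
#' @param corr A [correlogram()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_correlogram <- function(corr, path) {
  stopifnot(inherits(corr, "correlogram"))
  .write_header(path, list(q_per_nm = corr$q, temperature_K = corr$temperature,
                           solvent_viscosity_mPas = corr$solvent_viscosity))
  .append_table(path, data.frame(lag_us = corr$lag, g2 = corr$g2,
                                 err = corr$err))
  invisible(path)
}

#' Read a DLS correlogram written by [write_correlogram()]
#'
#' @param path Input path.
#' @return A [correlogram()].
#' @export
read_correlogram <- function(path) {
  meta <- .read_meta(path)
  d <- .read_table(path)
  correlogram(d$lag_us, d$g2, d$err, q = as.numeric(meta$q_per_nm),
              temperature = as.numeric(meta$temperature_K),
              solvent_viscosity = as.numeric(meta$solvent_viscosity_mPas))
}

#' Write an NSE intermediate scattering function
#'
#' Columns \code{t_ns isf err}; q (1/nm) in the header.
#'
#' @param isf An [isf_curve()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_isf_curve <- function(isf, path) {
  stopifnot(inherits(isf, "isf_curve"))
  .write_header(path, list(q_per_nm = isf$q))
  .append_table(path, data.frame(t_ns = isf$times, isf = isf$isf,
                                 err = isf$err))
  invisible(path)
}

#' Read an NSE curve written by [write_isf_curve()]
#'
#' @param path Input path.
#' @return An [isf_curve()].
#' @export
read_isf_curve <- function(path) {
  meta <- .read_meta(path)
  d <- .read_table(path)
  isf_curve(d$t_ns, d$isf, d$err, q = as.numeric(meta$q_per_nm))
}

#' Write a relative-viscosity series
#'
#' Columns \code{c_mg_ml eta_r err}.
#'
#' @param series A [viscosity_series()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_viscosity_series <- function(series, path) {
  stopifnot(inherits(series, "viscosity_series"))
  .write_header(path, list(format = "viscosity_series"))
  .append_table(path, data.frame(c_mg_ml = series$concentrations,
                                 eta_r = series$relative_viscosities,
                                 err = series$errors))
  invisible(path)
}

#' Read a series written by [write_viscosity_series()]
#'
#' @param path Input path.
#' @return A [viscosity_series()].
#' @export
read_viscosity_series <- function(path) {
  d <- .read_table(path)
  viscosity_series(d$c_mg_ml, d$eta_r,
                   if (all(is.na(d$err))) NULL else d$err)
}

#' Write a simulation snapshot
#'
#' Columns \code{id radius x y z} with box length and volume fraction in
#' the header.
#'
#' @param config A \code{"particle_config"}.
#' @param path Output path.
#' @param extra Named list of extra header fields (e.g. u, seed).
#' @return The path, invisibly.
#' @export
write_configuration <- function(config, path, extra = list()) {
  stopifnot(inherits(config, "particle_config"))
  meta <- c(list(box_length = config$box_length, phi = config$phi,
                 time = config$time), extra)
  .write_header(path, meta)
  .append_table(path, data.frame(id = seq_along(config$radii),
                                 radius = config$radii,
                                 x = config$positions[, 1],
                                 y = config$positions[, 2],
                                 z = config$positions[, 3]))
  invisible(path)
}

#' Read a snapshot written by [write_configuration()]
#'
#' Velocities are not stored; fresh Maxwell-Boltzmann velocities are drawn
#' (structure is velocity-independent).
#'
#' @param path Input path.
#' @param seed Seed for the redrawn velocities.
#' @return A \code{"particle_config"}.
#' @export
read_configuration <- function(path, seed = 1L) {
  meta <- .read_meta(path)
  d <- .read_table(path)
  n <- nrow(d)
  vel <- withr::with_seed(seed, matrix(stats::rnorm(3 * n), n, 3))
  vel <- sweep(vel, 2, colMeans(vel))
  structure(list(radii = d$radius,
                 positions = as.matrix(d[, c("x", "y", "z")]),
                 velocities = vel,
                 box_length = as.numeric(meta$box_length),
                 phi = as.numeric(meta$phi),
                 time = as.numeric(meta$time)),
            class = "particle_config")
}

#' Serialize ground truth as JSON
#'
#' @param truth A [ground_truth()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  x <- list(distribution = unclass(truth$distribution),
            D0 = truth$D0,
            interaction = unclass(truth$interaction),
            c_star = truth$c_star, gamma = truth$gamma,
            noise = truth$noise, seed = truth$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ground truth written by [write_ground_truth()]
#'
#' @param path Input path.
#' @return A [ground_truth()].
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ground_truth(
    distribution = schulz_dist(x$distribution$mean_radius,
                               x$distribution$sigma_star),
    D0 = x$D0,
    interaction = interaction_model(x$interaction$stickiness_tau,
                                    x$interaction$well_depth,
                                    x$interaction$well_width,
                                    x$interaction$voluminosity),
    c_star = x$c_star, gamma = x$gamma, noise = x$noise, seed = x$seed)
}
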