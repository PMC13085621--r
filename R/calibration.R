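#' Load a cohort calibration table
#'
#' The calibration table carries the group-level moments (mean, SD) of the
#' eight hemodynamic parameters at both occlusion pressures, the continuous
#' covariate moments, and the categorical covariate proportions that the
#' synthetic cohort generator reproduces. A versioned copy ships with the
#' package.
#'
#' @param path Path to a tab-delimited calibration file; default is the
#'   packaged version-1 table.
#' @return Object of class `dvos_calibration`: list of data frames `features`,
#'   `covariates`, `proportions`, plus `version`.
#' @export
load_calibration <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "calibration_v1.tsv", package = "dvos",
                        mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("table", "group", "pressure", "parameter", "mean", "sd")
  if (!all(need %in% names(tab)))
    stop("calibration file lacks required columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  split_tab <- function(kind) tab[tab$table == kind, -1, drop = FALSE]
  structure(list(features = split_tab("features"),
                 covariates = split_tab("covariates"),
                 proportions = split_tab("proportions"),
                 version = basename(path)),
            class = "dvos_calibration")
}

the_calibration <- new.env(parent = emptyenv())

default_calibration <- function() {
  if (is.null(the_calibration$cal))
    the_calibration$cal <- load_calibration()
  the_calibration$cal
}

# Physiologic truncation bounds used when sampling from the calibration
# moments. Features are positive; Tp is additionally bounded so the falling
# 90% crossing can occur inside the recovery phase (see vignette).
calibration_bounds <- function(parameter) {
  switch(parameter,
    tp = c(5, 50),
    age = c(18, Inf),
    bmi = c(15, Inf),
    dm_duration = c(0, Inf),
    htn_duration = c(0, Inf),
    abi_left = c(0.3, 2.5),
    abi_right = c(0.3, 2.5),
    # hemodynamic features: strictly positive with a small floor at the
    # device's effective resolution, so per-subject relative round-trip
    # tolerances remain meaningful
    delta_hbo = c(0.2, Inf),
    hf = c(0.05, Inf),
    vo2 = c(0.002, Inf),
    c(0, Inf)
  )
}

calibration_moments <- function(calib, kind, group, parameter, pressure = NULL) {
  tab <- calib[[kind]]
  sel <- tab$group == group & tab$parameter == parameter
  if (!is.null(pressure)) sel <- sel & tab$pressure == pressure
  row <- tab[sel, , drop = FALSE]
  if (nrow(row) != 1)
    stop("calibration entry not found: ", kind, "/", group, "/", parameter)
  row
}

# calibrated truncated-normal parameters, cached per (kind, group, parameter,
# pressure) within a calibration object
tn_for <- function(calib, kind, group, parameter, pressure = NULL,
                   sd_scale = 1) {
  row <- calibration_moments(calib, kind, group, parameter, pressure)
  b <- calibration_bounds(parameter)
  if (sd_scale == 0) {
    return(list(mu = row$mean, sigma = 0, lower = b[1], upper = b[2],
                degenerate = TRUE))
  }
  tn_calibrate(row$mean, row$sd * sd_scale, b[1], b[2])
}
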