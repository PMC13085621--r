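# Width of the slope-estimation intervals (s): the first 30 s of occlusion are
# subdivided into six such windows.
HF_INTERVAL_S <- 5
N_SLOPE_INTERVALS <- 6L

#' Conversion from an HbD accumulation rate to tissue oxygen consumption
#'
#' Dimensional constant converting the maximal HbD rise rate (umol/L/s) into
#' VO2 in mL O2 per 100 mL tissue per minute: each hemoglobin tetramer carries
#' 4 O2, one umol O2 occupies 0.0224 mL at standard conditions, 60 s/min, and
#' per-litre concentrations are rescaled to per-100-mL tissue.
#'
#' @return The factor 4 x 0.0224 x 60 / 10 = 0.5376.
#' @export
vo2_conversion_factor <- function() {
  o2_per_tetramer <- 4
  ml_per_umol_o2 <- 22.4 / 1000   # ideal-gas molar volume, mL per umol
  s_per_min <- 60
  per_l_to_per_100ml <- 1 / 10
  o2_per_tetramer * ml_per_umol_o2 * s_per_min * per_l_to_per_100ml
}

occ_window_idx <- function(time_s, start_s, end_s) {
  which(time_s >= start_s & time_s < end_s)
}

#' Occlusion-phase rise in oxyhemoglobin
#'
#' Maximum HbO during the occlusion minus the mean HbO over the 5 s
#' immediately preceding occlusion onset.
#'
#' @param trace A [hemo_trace()].
#' @param protocol A [cuff_protocol()].
#' @param pressure Occlusion pressure (mmHg) selecting the phase.
#' @param series Which species to use (`"hbo"` default; `"hbt"` yields the
#'   analogous total-hemoglobin rise used in the correlation analysis).
#' @return Concentration change in umol/L.
#' @export
delta_hbo <- function(trace, protocol = cuff_protocol(), pressure = 60,
                      series = c("hbo", "hbt")) {
  series <- match.arg(series)
  ph <- occlusion_phases(protocol, pressure)
  x <- trace[[series]]
  pre <- occ_window_idx(trace$time_s, ph$start_s - 5, ph$start_s)
  if (length(pre) < 2)
    stop("trace does not cover 5 s before occlusion onset")
  occ <- occ_window_idx(trace$time_s, ph$start_s, ph$start_s + ph$duration_s)
  if (length(occ) < 2) stop("trace does not cover the occlusion phase")
  max(x[occ]) - mean(x[pre])
}

#' Least-squares slopes over the six 5-s occlusion intervals
#'
#' Subdivides the first 30 s after occlusion onset into six half-open 5-s
#' windows `[start + 5k, start + 5(k+1))` and fits an ordinary least-squares
#' slope of the series against time within each.
#'
#' @param x Numeric series (concentration, umol/L).
#' @param time_s Sample times (s).
#' @param occlusion_start_s Occlusion onset (s).
#' @return Numeric vector of 6 slopes (umol/L/s), class `slope_grid`.
#' @export
interval_slopes <- function(x, time_s, occlusion_start_s) {
  if (max(time_s) < occlusion_start_s + N_SLOPE_INTERVALS * HF_INTERVAL_S)
    stop("need at least 30 s of occlusion data")
  slopes <- vapply(seq_len(N_SLOPE_INTERVALS) - 1L, function(k) {
    idx <- occ_window_idx(time_s,
                          occlusion_start_s + k * HF_INTERVAL_S,
                          occlusion_start_s + (k + 1) * HF_INTERVAL_S)
    if (length(idx) < 3) stop("slope window contains fewer than 3 samples")
    tt <- time_s[idx] - mean(time_s[idx])
    sum(tt * (x[idx] - mean(x[idx]))) / sum(tt^2)
  }, numeric(1))
  structure(slopes, class = "slope_grid")
}

#' Hemoglobin flow: maximal HbT interval slope
#'
#' The highest of the six 5-s least-squares HbT slopes during early occlusion,
#' in umol/L/s. Negative maxima (pathological monotone-decreasing traces) are
#' not clipped. Group statistics and the calibration table express HF as the
#' HbT rise over the steepest interval, i.e. this slope times the 5-s window
#' (see [extract_features()]).
#'
#' @inheritParams delta_hbo
#' @return Maximal slope in umol/L/s.
#' @export
hemoglobin_flow <- function(trace, protocol = cuff_protocol(), pressure = 60) {
  ph <- occlusion_phases(protocol, pressure)
  max(interval_slopes(trace$hbt, trace$time_s, ph$start_s))
}

#' Tissue oxygen consumption from the HbD rise rate
#'
#' The maximal 5-s least-squares HbD slope over the first 30 s of occlusion,
#' converted by [vo2_conversion_factor()] to mL O2 / 100 mL tissue / min.
#'
#' @inheritParams delta_hbo
#' @return VO2 in mL O2/100 mL/min.
#' @export
oxygen_consumption <- function(trace, protocol = cuff_protocol(),
                               pressure = 60) {
  ph <- occlusion_phases(protocol, pressure)
  max(interval_slopes(trace$hbd, trace$time_s, ph$start_s)) *
    vo2_conversion_factor()
}

#' HbT plateau time around cuff deflation
#'
#' Time for HbT to pass from 90% of its occlusion maximum (rising, before
#' deflation) to 90% of that maximum (falling, after deflation starts). Both
#' crossings are located by linear interpolation between adjacent samples;
#' the falling crossing uses first-crossing semantics. If HbT never falls
#' below the 90% level during the recovery phase, Tp is truncated at the
#' recovery end and flagged via attribute `"truncated"`.
#'
#' @inheritParams delta_hbo
#' @return Plateau time in seconds.
#' @export
plateau_time <- function(trace, protocol = cuff_protocol(), pressure = 60) {
  ph <- occlusion_phases(protocol, pressure)
  t <- trace$time_s
  x <- trace$hbt
  t_defl <- ph$start_s + ph$duration_s
  occ <- occ_window_idx(t, ph$start_s, t_defl)
  m <- max(x[occ])
  degenerate <- diff(range(x[occ])) == 0
  lev <- 0.9 * m
  cross_up <- function() {
    i <- occ[which(x[occ] >= lev)[1]]
    if (is.na(i)) stop("HbT never reaches 90% of its occlusion maximum")
    if (i == occ[1] || x[i - 1] >= lev) return(t[i])
    t[i - 1] + (lev - x[i - 1]) / (x[i] - x[i - 1]) * (t[i] - t[i - 1])
  }
  i_rec <- match(ph$label, protocol$phases$label) + 1L
  rec_end <- protocol$phases$start_s[i_rec] +
    protocol$phases$duration_s[i_rec]
  post <- occ_window_idx(t, t_defl, rec_end)
  if (length(post) < 2 || max(t[post]) < t_defl + 30)
    stop("trace does not cover at least 30 s of recovery")
  truncated <- FALSE
  j <- post[which(x[post] <= lev)[1]]
  if (is.na(j)) {
    t2 <- rec_end
    truncated <- TRUE
  } else if (j == 1 || x[j - 1] <= lev) {
    t2 <- t[j]
  } else {
    t2 <- t[j - 1] + (x[j - 1] - lev) / (x[j - 1] - x[j]) * (t[j] - t[j - 1])
  }
  structure(t2 - cross_up(), truncated = truncated, degenerate = degenerate)
}

#' Extract the four hemodynamic parameters at each occlusion pressure
#'
#' Applies [delta_hbo()], [hemoglobin_flow()], [oxygen_consumption()], and
#' [plateau_time()] at every occlusion phase of the protocol. HF is reported
#' on the scale used by the group statistics and calibration table: the HbT
#' rise over the steepest 5-s interval (maximal slope x 5 s). The
#' total-hemoglobin rise `delta_hbt` is computed alongside for the
#' redundancy/correlation analysis. A failing sub-operation invalidates only
#' its own entry (set `NA`, with the completeness flag cleared).
#'
#' @param trace A [hemo_trace()] spanning the full protocol.
#' @param protocol A [cuff_protocol()].
#' @param hf_scale Multiplier from the maximal HbT slope (umol/L/s) to the
#'   reported HF; default the 5-s interval width.
#' @return Data frame of class `feature_set`: one row per occlusion pressure
#'   with columns `pressure`, `delta_hbo`, `delta_hbt`, `hf`, `vo2`, `tp`,
#'   `tp_truncated`, `complete`.
#' @export
extract_features <- function(trace, protocol = cuff_protocol(),
                             hf_scale = HF_INTERVAL_S) {
  occ <- occlusion_phases(protocol)
  rows <- lapply(occ$pressure_mmHg, function(p) {
    grab <- function(expr) tryCatch(expr, error = function(e) NA_real_)
    tp <- grab(plateau_time(trace, protocol, p))
    row <- data.frame(
      pressure = p,
      delta_hbo = grab(delta_hbo(trace, protocol, p)),
      delta_hbt = grab(delta_hbo(trace, protocol, p, series = "hbt")),
      hf = grab(hemoglobin_flow(trace, protocol, p) * hf_scale),
      vo2 = grab(oxygen_consumption(trace, protocol, p)),
      tp = as.numeric(tp),
      tp_truncated = isTRUE(attr(tp, "truncated"))
    )
    row$complete <- !anyNA(row)
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("feature_set", "data.frame")
  out
}
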