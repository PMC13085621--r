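#' Five-phase cuff occlusion protocol
#'
#' Defines the pressure timeline that anchors every analysis window: baseline,
#' 60-mmHg venous occlusion, recovery, 100-mmHg occlusion (venous plus partial
#' arterial), and a second recovery. Defaults reproduce the clinical protocol:
#' five contiguous one-minute phases sampled at 2.56 Hz, with cuff pressure
#' below 5 mmHg outside the occlusions.
#'
#' @param phase_durations_s Numeric length-5 vector of phase durations in
#'   seconds (default all 60).
#' @param pressures_mmHg Numeric length-5 vector of cuff pressures in mmHg
#'   (default `c(0, 60, 0, 100, 0)`). Phases with pressure > 5 mmHg are treated
#'   as occlusions.
#' @param sampling_rate_hz Scans per second (default 2.56). Must exceed twice
#'   the low-pass cutoff used downstream so filtering remains well posed.
#' @return An object of class `cuff_protocol`: a list with `phases` (data frame
#'   of label, start_s, duration_s, pressure_mmHg) and `sampling_rate_hz`.
#' @examples
#' p <- cuff_protocol()
#' p$phases
#' @export
cuff_protocol <- function(phase_durations_s = rep(60, 5),
                          pressures_mmHg = c(0, 60, 0, 100, 0),
                          sampling_rate_hz = 2.56) {
  if (length(phase_durations_s) != 5L || length(pressures_mmHg) != 5L)
    stop("a cuff protocol has exactly 5 phases")
  if (any(phase_durations_s <= 0)) stop("phase durations must be positive")
  if (any(pressures_mmHg < 0)) stop("pressures must be non-negative")
  if (pressures_mmHg[1] > 5 || pressures_mmHg[3] > 5 || pressures_mmHg[5] > 5)
    stop("baseline and recovery phases must have pressure <= 5 mmHg")
  if (sampling_rate_hz <= 2 * DEFAULT_LP_CUTOFF_HZ)
    stop("sampling_rate_hz must exceed twice the low-pass cutoff (",
         2 * DEFAULT_LP_CUTOFF_HZ, " Hz)")
  labels <- c("baseline", "occ1", "recovery1", "occ2", "recovery2")
  phases <- data.frame(
    label = labels,
    start_s = cumsum(c(0, phase_durations_s[-5])),
    duration_s = phase_durations_s,
    pressure_mmHg = pressures_mmHg,
    stringsAsFactors = FALSE
  )
  structure(list(phases = phases, sampling_rate_hz = sampling_rate_hz),
            class = "cuff_protocol")
}

# default 2nd-order Butterworth cutoff applied to optical channels
DEFAULT_LP_CUTOFF_HZ <- 0.51

#' @export
print.cuff_protocol <- function(x, ...) {
  cat("<cuff_protocol> ", nrow(x$phases), " phases, ",
      protocol_duration(x), " s at ", x$sampling_rate_hz, " Hz\n", sep = "")
  print(x$phases)
  invisible(x)
}

protocol_duration <- function(protocol) {
  with(protocol$phases, start_s[5] + duration_s[5])
}

#' Sample time base of a protocol
#'
#' @param protocol A [cuff_protocol()].
#' @return Vector of sample times in seconds, `k / fs` for
#'   `k = 0, ..., n - 1`.
#' @export
protocol_times <- function(protocol) {
  n <- round(protocol_duration(protocol) * protocol$sampling_rate_hz)
  (seq_len(n) - 1) / protocol$sampling_rate_hz
}

#' Occlusion phases of a protocol
#'
#' @param protocol A [cuff_protocol()].
#' @param pressure Optional occlusion pressure (mmHg) to select a single phase.
#' @return Data frame of occlusion phases (pressure > 5 mmHg).
#' @export
occlusion_phases <- function(protocol, pressure = NULL) {
  occ <- protocol$phases[protocol$phases$pressure_mmHg > 5, , drop = FALSE]
  if (!is.null(pressure)) {
    occ <- occ[occ$pressure_mmHg == pressure, , drop = FALSE]
    if (nrow(occ) == 0)
      stop("no occlusion phase at ", pressure, " mmHg in this protocol")
  }
  occ
}

phase_by_label <- function(protocol, label) {
  ph <- protocol$phases[protocol$phases$label == label, , drop = FALSE]
  if (nrow(ph) == 0) stop("unknown phase label: ", label)
  ph
}

#' Hemoglobin concentration trace
#'
#' Container for reconstructed (or ground-truth) concentration changes from
#' baseline, in umol/L. The additive identity HbT = HbO + HbD is enforced at
#' construction.
#'
#' @param time_s Strictly increasing, regularly spaced sample times (s).
#' @param hbo,hbd Oxy- and deoxyhemoglobin concentration changes (umol/L).
#' @param hbt Optional; defaults to `hbo + hbd` and must equal it if supplied.
#' @return Object of class `hemo_trace` (list of `time_s`, `hbo`, `hbd`,
#'   `hbt`).
#' @export
hemo_trace <- function(time_s, hbo, hbd, hbt = NULL) {
  n <- length(time_s)
  if (length(hbo) != n || length(hbd) != n)
    stop("time_s, hbo, hbd must have equal length")
  if (n >= 2) {
    dt <- diff(time_s)
    if (any(dt <= 0)) stop("time_s must be strictly increasing")
    if (max(dt) - min(dt) > 1e-9 * max(dt)) stop("time_s must be regular")
  }
  if (is.null(hbt)) hbt <- hbo + hbd
  else if (max(abs(hbt - (hbo + hbd))) > 1e-8 * max(1, max(abs(hbt))))
    stop("hbt must equal hbo + hbd")
  structure(list(time_s = as.numeric(time_s), hbo = as.numeric(hbo),
                 hbd = as.numeric(hbd), hbt = as.numeric(hbt)),
            class = "hemo_trace")
}

#' @export
print.hemo_trace <- function(x, ...) {
  cat("<hemo_trace> ", length(x$time_s), " samples, ",
      round(x$time_s[length(x$time_s)] - x$time_s[1], 2), " s span, ",
      "HbT range [", round(min(x$hbt), 2), ", ", round(max(x$hbt), 2),
      "] umol/L\n", sep = "")
  invisible(x)
}
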