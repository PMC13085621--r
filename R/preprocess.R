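#' Baseline signal-to-noise ratio of an optical channel
#'
#' SNR is the temporal mean of the raw intensity over the baseline (resting)
#' window divided by its temporal standard deviation over the same window. A
#' noiseless constant channel has zero SD and is assigned `Inf` (retained by
#' any finite threshold).
#'
#' @param intensity Raw intensity series (arbitrary units).
#' @param fs Sampling rate (Hz).
#' @param window `(start_s, end_s)` baseline window (half-open), default the
#'   first 60 s.
#' @return Dimensionless SNR.
#' @export
compute_snr <- function(intensity, fs, window = c(0, 60)) {
  t <- (seq_along(intensity) - 1) / fs
  idx <- t >= window[1] & t < window[2]
  if (sum(idx) < 2) stop("baseline window must contain at least 2 samples")
  m <- mean(intensity[idx])
  s <- stats::sd(intensity[idx])
  if (s == 0) return(Inf)
  m / s
}

#' Screen channels by baseline SNR
#'
#' Removes channels whose baseline SNR falls below the threshold (strict
#' inequality: SNR exactly equal to the threshold is retained) and reports a
#' QC record for every channel. If the surviving channels span fewer than two
#' distinct wavelengths the recording is flagged unreconstructable rather than
#' raising an error.
#'
#' @param rec An `optical_recording`.
#' @param threshold SNR exclusion threshold (default 4).
#' @return List with `recording` (channels restricted to survivors), `qc`
#'   (data frame: detector, wavelength, snr, included, reason), and
#'   `reconstructable` (logical).
#' @export
apply_snr_filter <- function(rec, threshold = 4) {
  fs <- rec$protocol$sampling_rate_hz
  ph <- rec$protocol$phases[1, ]
  win <- c(ph$start_s, ph$start_s + ph$duration_s)
  snr <- vapply(rec$channels, function(ch)
    compute_snr(ch$intensity, fs, win), numeric(1))
  included <- snr >= threshold
  qc <- data.frame(
    detector = vapply(rec$channels, `[[`, numeric(1), "detector_id"),
    wavelength = vapply(rec$channels, `[[`, numeric(1), "wavelength"),
    snr = snr,
    included = included,
    reason = ifelse(included, "",
                    sprintf("baseline SNR %.3g < %.3g", snr, threshold)),
    stringsAsFactors = FALSE
  )
  rec$channels <- rec$channels[included]
  wl <- qc$wavelength[included]
  list(recording = rec, qc = qc,
       reconstructable = length(unique(wl)) >= 2)
}

# 2nd-order low-pass Butterworth design by bilinear transform.
# Returns list(b, a) of transfer-function coefficients (a[1] == 1).
butter_lowpass <- function(fs, cutoff, order = 2) {
  if (order != 2) stop("only the 2nd-order design is implemented")
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("cutoff must lie strictly between 0 and the Nyquist frequency")
  w <- tan(pi * cutoff / fs)
  a0 <- 1 + sqrt(2) * w + w^2
  list(b = c(w^2, 2 * w^2, w^2) / a0,
       a = c(1, 2 * (w^2 - 1) / a0, (1 - sqrt(2) * w + w^2) / a0))
}

# Single forward IIR pass with near-steady-state initial conditions; the
# signal is expected to be pre-padded so residual start-up transients decay
# inside the padding.
iir_pass <- function(x, b, a) {
  n <- length(x)
  xb <- b[1] * x +
    b[2] * c(x[1], x[-n]) +
    b[3] * c(x[1], x[1], x[-c(n - 1, n)])
  as.numeric(stats::filter(xb, -a[2:3], method = "recursive",
                           init = rep(x[1], 2)))
}

#' Zero-phase low-pass Butterworth filter
#'
#' Forward-backward application of a 2nd-order low-pass Butterworth filter
#' (default cutoff 0.51 Hz at 2.56 Hz sampling), with odd-reflection padding
#' at both ends so edge transients stay outside the data. The two passes
#' cancel phase exactly (zero group delay), which protects interval-slope
#' features from timing bias; the DC gain is exactly 1.
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz), default 2.56.
#' @param cutoff Cutoff frequency (Hz), default 0.51; must be below Nyquist.
#' @param order Filter order (2 only).
#' @return Filtered series, same length as `x`.
#' @export
lowpass_filter <- function(x, fs = 2.56, cutoff = 0.51, order = 2) {
  coef <- butter_lowpass(fs, cutoff, order)
  if (length(x) <= 3 * order)
    stop("series too short for filtering (need > ", 3 * order, " samples)")
  n <- length(x)
  p <- min(n - 1, 12L)
  ext <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- iir_pass(ext, coef$b, coef$a)
  y <- rev(iir_pass(rev(y), coef$b, coef$a))
  y[(p + 1):(p + n)]
}

# Apply the low-pass filter to every channel of a recording.
filter_recording <- function(rec, cutoff = 0.51, order = 2) {
  fs <- rec$protocol$sampling_rate_hz
  rec$channels <- lapply(rec$channels, function(ch) {
    ch$intensity <- lowpass_filter(ch$intensity, fs, cutoff, order)
    ch
  })
  rec
}

#' Flag motion artifacts in a series
#'
#' Robust spike detection (modified z-score against the median/MAD of the
#' first difference) combined with rolling-median step detection. The series
#' is flagged when the artifact fraction exceeds `max_fraction`.
#'
#' @param x Numeric series.
#' @param spike_z Modified z-score threshold on first differences (default 6).
#' @param step_threshold Step size threshold as a multiple of the robust
#'   difference scale (default 8).
#' @param window Rolling-median half-window in samples (default 5).
#' @param max_fraction Artifact fraction above which the series is flagged.
#' @return List with `flagged`, `fraction`, and `intervals` (data frame of
#'   artifact sample runs: start, end indices).
#' @export
flag_motion <- function(x, spike_z = 6, step_threshold = 8, window = 5,
                        max_fraction = 0.005) {
  stopifnot(length(x) >= 3)
  d <- diff(x)
  s <- stats::mad(d)
  if (s == 0) s <- stats::sd(d)
  if (is.na(s) || s == 0)
    return(list(flagged = FALSE, fraction = 0,
                intervals = data.frame(start = integer(), end = integer())))
  spike <- c(FALSE, abs(d - stats::median(d)) / s > spike_z)
  rmed <- stats::runmed(x, 2 * window + 1)
  step <- abs(diff(rmed)) > step_threshold * s
  art <- spike | c(FALSE, step)
  r <- rle(art)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- data.frame(start = starts[r$values], end = ends[r$values])
  frac <- mean(art)
  list(flagged = frac > max_fraction, fraction = frac, intervals = iv)
}

#' Quality control and reconstruction of one recording
#'
#' Chains the preprocessing and inversion steps used by the pipeline: SNR
#' screening, zero-phase low-pass filtering of the retained raw intensities,
#' and Beer-Lambert inversion with detector averaging.
#'
#' @param rec An `optical_recording`.
#' @param ext An [extinction_table()].
#' @param snr_threshold SNR exclusion threshold (default 4).
#' @param cutoff Low-pass cutoff in Hz (default 0.51); `NA` disables
#'   filtering.
#' @return List with `trace` (a [hemo_trace()], or `NULL` when
#'   unreconstructable) and `qc`.
#' @export
process_recording <- function(rec, ext = extinction_table(),
                              snr_threshold = 4, cutoff = 0.51) {
  scr <- apply_snr_filter(rec, snr_threshold)
  if (!scr$reconstructable)
    return(list(trace = NULL, qc = scr$qc))
  filtered <- if (is.na(cutoff)) scr$recording
              else filter_recording(scr$recording, cutoff)
  list(trace = invert_hemoglobin(filtered, ext), qc = scr$qc)
}
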