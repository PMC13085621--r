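#' Hemoglobin extinction coefficient table
#'
#' Reads a 3-column delimited table (`wavelength_nm`, `eps_hbo`, `eps_hbd`;
#' coefficients in L/(mmol cm), `#` comment header carrying the source
#' citation). The packaged default holds working values at the four device
#' wavelengths (670, 780, 808, 850 nm). At least two wavelengths are required
#' and the coefficient matrix must have full column rank so oxy- and
#' deoxyhemoglobin are distinguishable.
#'
#' @param path Path to an extinction file; default is the packaged table.
#' @return Data frame of class `extinction_table` with attribute `"source"`.
#' @export
extinction_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "extinction_v1.tsv", package = "dvos",
                        mustWork = TRUE)
  header <- grep("^#", readLines(path, n = 20), value = TRUE)
  tab <- utils::read.delim(path, comment.char = "#")
  need <- c("wavelength_nm", "eps_hbo", "eps_hbd")
  if (!all(need %in% names(tab)))
    stop("extinction table needs columns: ", paste(need, collapse = ", "))
  if (nrow(tab) < 2) stop("need at least 2 wavelengths")
  if (any(tab$eps_hbo <= 0) || any(tab$eps_hbd <= 0))
    stop("extinction coefficients must be positive")
  if (qr(as.matrix(tab[, c("eps_hbo", "eps_hbd")]))$rank < 2)
    stop("extinction matrix is column-rank deficient; wavelengths cannot ",
         "separate HbO from HbD")
  structure(tab, class = c("extinction_table", "data.frame"),
            source = paste(sub("^#\\s?", "", header), collapse = "\n"))
}

eps_at <- function(ext, wavelength) {
  i <- match(wavelength, ext$wavelength_nm)
  if (any(is.na(i)))
    stop("wavelength(s) missing from extinction table: ",
         paste(wavelength[is.na(i)], collapse = ", "), " nm")
  ext[i, c("eps_hbo", "eps_hbd"), drop = FALSE]
}

#' Forward optical model (modified Beer-Lambert law)
#'
#' Converts a hemoglobin concentration trace into per-channel optical
#' intensities. For each wavelength the optical-density change is
#' `dOD(t) = (eps_HbO * dHbO + eps_HbD * dHbD)/1000 * pathlength * DPF`
#' (concentrations converted from umol/L to mmol/L) and the intensity is
#' `I(t) = I0 * 10^(-dOD(t)) * gain`, with optional multiplicative noise,
#' per-channel linear drift, and injected motion artifacts.
#'
#' @param trace A [hemo_trace()].
#' @param protocol The [cuff_protocol()] the trace was recorded under.
#' @param ext An [extinction_table()] covering the requested wavelengths.
#' @param subject_id Identifier stored in the recording.
#' @param wavelengths Wavelengths (nm) to synthesise; default all in `ext`.
#' @param pathlength_cm Geometric source-detector distance (cm).
#' @param dpf Differential pathlength factor (dimensionless).
#' @param i0 Nominal source intensity (arbitrary units).
#' @param n_detectors Number of detectors per patch.
#' @param gains Optional numeric matrix (`n_detectors` x wavelengths) of
#'   channel gains; drawn uniformly in `[0.5, 2]` when `NULL`.
#' @param noise A [noise_config()].
#' @param log_base `"10"` (decadic, default) or `"e"`; the inversion must use
#'   the same convention.
#' @return Object of class `optical_recording`.
#' @export
forward_model <- function(trace, protocol, ext = extinction_table(),
                          subject_id = "subject", wavelengths = NULL,
                          pathlength_cm = 3, dpf = 4, i0 = 1000,
                          n_detectors = 2, gains = NULL,
                          noise = noise_config(), log_base = c("10", "e")) {
  log_base <- match.arg(log_base)
  if (is.null(wavelengths)) wavelengths <- ext$wavelength_nm
  eps <- eps_at(ext, wavelengths)
  times <- trace$time_s
  n <- length(times)
  if (is.null(gains))
    gains <- matrix(stats::runif(n_detectors * length(wavelengths), 0.5, 2),
                    n_detectors, length(wavelengths))
  pow <- function(x) if (log_base == "10") 10^(-x) else exp(-x)
  channels <- list()
  for (d in seq_len(n_detectors)) {
    for (k in seq_along(wavelengths)) {
      dod <- (eps$eps_hbo[k] * trace$hbo + eps$eps_hbd[k] * trace$hbd) /
        1000 * pathlength_cm * dpf
      intens <- i0 * pow(dod) * gains[d, k]
      sd_i <- noise$intensity_sd
      if (noise$low_snr_fraction > 0 &&
          stats::runif(1) < noise$low_snr_fraction)
        sd_i <- 0.4  # degraded channel: baseline SNR ~ 2.5, fails the screen
      if (sd_i > 0)
        intens <- intens * (1 + stats::rnorm(n, 0, sd_i))
      if (noise$drift_sd > 0)
        intens <- intens * (1 + stats::rnorm(1, 0, noise$drift_sd) * times / 60)
      if (noise$motion_rate > 0) {
        n_art <- stats::rpois(1, noise$motion_rate)
        for (j in seq_len(n_art)) {
          at <- sample.int(n - 8, 1)
          intens[at] <- intens[at] * (1 + noise$motion_amp * 10)  # spike
          intens[(at + 1):n] <- intens[(at + 1):n] *
            (1 + noise$motion_amp * sample(c(-1, 1), 1))          # step
        }
      }
      intens <- pmax(intens, i0 * 1e-9)
      channels[[length(channels) + 1L]] <-
        list(detector_id = d, wavelength = wavelengths[k],
             intensity = intens, gain = gains[d, k])
    }
  }
  structure(list(subject_id = subject_id, patch_id = "medial_plantar",
                 channels = channels, protocol = protocol,
                 pathlength_cm = pathlength_cm, dpf = dpf,
                 log_base = log_base),
            class = "optical_recording")
}

#' @export
print.optical_recording <- function(x, ...) {
  wl <- vapply(x$channels, `[[`, numeric(1), "wavelength")
  cat("<optical_recording> subject ", x$subject_id, ", patch ", x$patch_id,
      ", ", length(x$channels), " channels (",
      paste(sort(unique(wl)), collapse = "/"), " nm)\n", sep = "")
  invisible(x)
}

#' Reconstruct hemoglobin concentrations from an optical recording
#'
#' Modified Beer-Lambert inversion. For each detector, optical-density changes
#' referenced to the mean intensity over the baseline phase are solved
#' per time point as a least-squares system across available wavelengths,
#' `dOD(lambda, t) = eps(lambda, .) %*% dC(t) * L * DPF`, yielding dHbO and
#' dHbD in umol/L (the mmol/umol factor is handled internally). Detector
#' traces are averaged after inversion; HbT is HbO + HbD by construction.
#' Channel gains cancel in the baseline-referenced dOD, so the result is
#' gain-invariant.
#'
#' @param rec An `optical_recording` (after QC; at least two distinct
#'   wavelengths must remain).
#' @param ext An [extinction_table()].
#' @param baseline_window Two-element `(start_s, end_s)` window for the
#'   reference intensity; defaults to the protocol's baseline phase.
#' @return A [hemo_trace()].
#' @export
invert_hemoglobin <- function(rec, ext = extinction_table(),
                              baseline_window = NULL) {
  protocol <- rec$protocol
  times <- protocol_times(protocol)
  if (is.null(baseline_window)) {
    ph <- protocol$phases[1, ]
    baseline_window <- c(ph$start_s, ph$start_s + ph$duration_s)
  }
  base_idx <- times >= baseline_window[1] & times < baseline_window[2]
  if (sum(base_idx) < 2) stop("baseline window contains < 2 samples")
  wl_all <- vapply(rec$channels, `[[`, numeric(1), "wavelength")
  if (length(unique(wl_all)) < 2)
    stop("reconstruction refused: fewer than 2 distinct wavelengths ",
         "available after QC")
  logf <- if (identical(rec$log_base, "e")) log else log10
  dets <- sort(unique(vapply(rec$channels, `[[`, numeric(1), "detector_id")))
  used <- 0L
  acc_hbo <- acc_hbd <- 0
  for (d in dets) {
    chs <- rec$channels[vapply(rec$channels, `[[`, numeric(1),
                               "detector_id") == d]
    wl <- vapply(chs, `[[`, numeric(1), "wavelength")
    if (length(unique(wl)) < 2) next
    dod <- t(vapply(chs, function(ch) {
      -logf(ch$intensity / mean(ch$intensity[base_idx]))
    }, numeric(length(times))))
    a <- as.matrix(eps_at(ext, wl)) * rec$pathlength_cm * rec$dpf / 1000
    conc <- solve(crossprod(a), crossprod(a, dod))  # 2 x T, umol/L
    acc_hbo <- acc_hbo + conc[1, ]
    acc_hbd <- acc_hbd + conc[2, ]
    used <- used + 1L
  }
  if (used == 0L)
    stop("reconstruction refused: no detector retains 2 distinct wavelengths")
  hemo_trace(times, hbo = acc_hbo / used, hbd = acc_hbd / used)
}
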