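#' Sample subject covariates for one study group
#'
#' Draws clinical and demographic covariates from the calibration table's
#' group-specific moments: continuous covariates (age, BMI, diabetes and
#' hypertension duration, left/right ankle-brachial index) from truncated
#' normals re-standardised so the truncated moments match the printed ones, and
#' categorical covariates (sex, smoking, medications) as Bernoulli draws with
#' the printed proportions.
#'
#' @param n Number of subjects to draw.
#' @param group `"PAD"` or `"nonPAD"`.
#' @param calib A [load_calibration()] object.
#' @param sd_scale Multiplier on all SDs (0 gives every subject the group
#'   means; used for degenerate-world tests).
#' @return Data frame with one row per subject.
#' @export
sample_covariates <- function(n, group, calib = default_calibration(),
                              sd_scale = 1) {
  group <- match.arg(group, c("PAD", "nonPAD"))
  stopifnot(n >= 1)
  cont <- c("age", "bmi", "dm_duration", "abi_left", "abi_right")
  out <- list(group = rep(group, n))
  for (p in cont) {
    cal <- tn_for(calib, "covariates", group, p, sd_scale = sd_scale)
    out[[p]] <- if (isTRUE(cal$degenerate)) rep(cal$mu, n) else rtn(n, cal)
  }
  prop <- function(p)
    calibration_moments(calib, "proportions", group, p)$mean
  # Hypertension duration is zero-inflated: it is zero for subjects without
  # hypertension (prevalence = the antihypertensive proportion), and the
  # positive component's moments are solved so the overall mean/SD match the
  # calibration moments; a plain truncated normal cannot represent sd > mean.
  p_htn <- prop("antihypertensive")
  htn <- stats::runif(n) < p_htn
  hrow <- calibration_moments(calib, "covariates", group, "htn_duration")
  m1 <- hrow$mean / p_htn
  if (sd_scale == 0) {
    out$htn_duration <- ifelse(htn, m1, 0)
  } else {
    v1 <- ((hrow$sd * sd_scale)^2 + hrow$mean^2) / p_htn - m1^2
    if (v1 <= 0) stop("inconsistent zero-inflated htn_duration moments")
    out$htn_duration <- ifelse(htn, rtn(n, tn_calibrate(m1, sqrt(v1), 0, Inf)),
                               0)
  }
  out$sex <- ifelse(stats::runif(n) < prop("male"), "M", "F")
  for (p in c("smoking", "statin", "antiplatelet"))
    out[[p]] <- stats::runif(n) < prop(p)
  out$antihypertensive <- htn
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Ankle-brachial index screening rule
#'
#' Simple labelling utility implementing the ABI decision rule used for
#' participant classification: ABI at or below 0.9 indicates PAD; at or above
#' 1.3 suggests arterial calcification (imaging required); a normal ABI
#' (1-1.3) in an asymptomatic subject who is not high-risk is classified
#' non-PAD; every other case is referred to imaging.
#'
#' @param abi Ankle-brachial index (positive ratio); vectorised.
#' @param symptoms,high_risk Logical; presence of PAD symptoms / high-risk
#'   status (recycled).
#' @return Character vector in `{"PAD", "nonPAD", "needs_imaging"}`.
#' @examples
#' classify_abi(c(0.85, 1.10, 1.35))
#' @export
classify_abi <- function(abi, symptoms = FALSE, high_risk = FALSE) {
  if (any(!is.finite(abi)) || any(abi <= 0))
    stop("abi must be positive and finite")
  k <- pmax(length(abi), length(symptoms), length(high_risk))
  abi <- rep_len(abi, k)
  symptoms <- rep_len(symptoms, k)
  high_risk <- rep_len(high_risk, k)
  ifelse(abi <= 0.9, "PAD",
    ifelse(abi >= 1.3, "needs_imaging",
      ifelse(abi >= 1.0 & !symptoms & !high_risk, "nonPAD",
             "needs_imaging")))
}

#' Sample per-subject hemodynamic feature targets
#'
#' Draws ground-truth values of the four parameters (ΔHbO, HF, VO2, Tp) at
#' both occlusion pressures from truncated normals matching the calibration
#' moments of the requested group. A shared latent standard-normal severity
#' factor (Gaussian copula, configurable loading) induces positive
#' cross-parameter correlation while leaving every marginal exactly the
#' calibrated truncated normal.
#'
#' @param n Number of subjects.
#' @param group `"PAD"` or `"nonPAD"`.
#' @param calib A [load_calibration()] object.
#' @param loading Severity-factor loading in `[0, 1)` applied to each
#'   standardised feature (default 0.6).
#' @param sd_scale Multiplier on all SDs (0 = degenerate at group means).
#' @return Data frame with columns `delta_hbo_60`, `hf_60`, `vo2_60`, `tp_60`
#'   and the `_100` counterparts; the latent severity draw is attached as
#'   attribute `"severity"`.
#' @export
sample_feature_targets <- function(n, group, calib = default_calibration(),
                                   loading = 0.6, sd_scale = 1) {
  group <- match.arg(group, c("PAD", "nonPAD"))
  stopifnot(n >= 1, loading >= 0, loading < 1)
  z <- stats::rnorm(n)
  out <- list()
  for (pressure in c(60, 100)) {
    for (p in c("delta_hbo", "hf", "vo2", "tp")) {
      cal <- tn_for(calib, "features", group, p, pressure, sd_scale = sd_scale)
      w <- loading * z + sqrt(1 - loading^2) * stats::rnorm(n)
      val <- if (isTRUE(cal$degenerate)) rep(cal$mu, n)
             else tn_from_latent(w, cal)
      out[[paste0(p, "_", pressure)]] <- val
    }
  }
  out <- as.data.frame(out)
  attr(out, "severity") <- z
  out
}

# reshape one wide target row into the long form used by construct_trace
targets_long <- function(targets_row) {
  data.frame(
    pressure = c(60, 100),
    delta_hbo = c(targets_row$delta_hbo_60, targets_row$delta_hbo_100),
    hf = c(targets_row$hf_60, targets_row$hf_100),
    vo2 = c(targets_row$vo2_60, targets_row$vo2_100),
    tp = c(targets_row$tp_60, targets_row$tp_100)
  )
}

#' Options controlling synthetic trace morphology
#'
#' @param rise_s Duration of the initial HbT rise segment whose slope encodes
#'   the HF target; must exceed one 5-s slope interval so the first interval's
#'   least-squares slope equals the target rate.
#' @param hbd_rise_s Default duration of the early HbD rise encoding VO2
#'   (extended automatically when the target combination requires a larger
#'   end-occlusion HbD level).
#' @param hbd_decline_frac Fractional (of the VO2 slope) HbD decline rate after
#'   the early rise.
#' @param smooth_width Width (samples, odd) of the moving-average kernel
#'   applied to the piecewise-linear skeleton.
#' @return List of options for [construct_trace()].
#' @export
trace_options <- function(rise_s = 5.8, hbd_rise_s = 12,
                          hbd_decline_frac = 0.05, smooth_width = 3) {
  stopifnot(rise_s > 5, rise_s < 10, hbd_rise_s > 5.2,
            smooth_width %% 2 == 1)
  list(rise_s = rise_s, hbd_rise_s = hbd_rise_s,
       hbd_decline_frac = hbd_decline_frac, smooth_width = smooth_width)
}

# Build the knot sequence for one occlusion + recovery block.
#
# Geometry (concentrations relative to the block's entry level L):
#   HbT: slope h = HF/5 for rise_s seconds (encodes HF), then a slower linear
#        segment to alpha*M at 30 s, then to the peak M at deflation, then a
#        fall calibrated so the 90%-of-max plateau time equals the Tp target,
#        then washout to zero.
#   HbD: rise at the VO2-implied slope for hbd_rise_s seconds, slight decline,
#        linear adjustment over the second half-occlusion to the level
#        M - delta_hbo (which makes the end-occlusion HbO maximum equal the
#        ΔHbO target), then washout.
# All shape constraints (interval-slope ordering, monotone HbO, crossing
# placement) are checked explicitly; violations are reported as infeasible.
build_occlusion_knots <- function(D, Hp, V, Tp, L_hbt, L_hbd, t0,
                                  occ_s, rec_s, opts) {
  if (!all(is.finite(c(D, Hp, V, Tp))) || D <= 0 || Hp <= 0 || V <= 0 ||
      Tp <= 0)
    stop("infeasible targets: delta_hbo, hf, vo2, tp must all be positive")
  h <- Hp / HF_INTERVAL_S
  sdr <- V / vo2_conversion_factor()
  r1 <- opts$rise_s
  q <- opts$hbd_decline_frac * sdr
  p2max <- min(45, rec_s - 10)
  margin <- (r1 - HF_INTERVAL_S) / 2   # smoothing guard around the steep run
  shelf <- 1.6   # flat peak held before deflation so smoothing keeps the
                 # occlusion maximum (hence delta_hbo and the 90% level) exact

  hbd_geom <- function(dd, at) {
    # HbD relative level at time `at` for rise duration dd and decline q
    sdr * min(dd, at) - q * max(0, at - dd)
  }

  # Shape A ("concave"): steep HF-encoding rise at occlusion onset, then two
  # decelerating segments; requires the early HbO excursion to stay under the
  # delta_hbo target.
  solve_early <- function(dd) {
    if (max(0, h - sdr) * r1 > D) return(NULL)
    e <- hbd_geom(dd, occ_s)
    if (e < 0) return(NULL)
    hbd30 <- hbd_geom(dd, 30)
    M <- D + e
    if (M <= h * r1) return(NULL)
    lam <- L_hbt / M
    kfac <- (30 - shelf) * 0.1 * (1 + lam)   # p1 = kfac/(1-alpha) + shelf
    alpha_of_p1 <- function(p1) 1 - kfac / (p1 - shelf)
    alo <- 1.05 * h * r1 / M
    if (Tp - p2max > shelf + 0.1)
      alo <- max(alo, alpha_of_p1(Tp - p2max))
    aup <- min(h * (r1 + 0.85 * (30 - r1)) / M,
               0.9 - 0.1 * lam - 0.02,
               alpha_of_p1(Tp - 0.2),
               (D + hbd30) / M)
    if (alo > aup) return(NULL)
    alpha <- min(max(alpha_of_p1(max(Tp / 2, shelf + 0.3)), alo), aup)
    M_abs <- L_hbt + M
    p1 <- kfac / (1 - alpha) + shelf
    list(dd = dd, e = e, M = M, p1 = p1, mode = "early",
         knots_t = c(t0, t0 + r1, t0 + 30, t0 + occ_s - shelf, t0 + occ_s),
         knots_v = c(L_hbt, L_hbt + h * r1, L_hbt + alpha * M, M_abs, M_abs))
  }

  # Shape B ("late rise"): slow ramp, steep run spanning the last 5-s slope
  # window, then on to the peak. Used when the sampled delta_hbo is too small
  # for shape A: by 25 s enough HbD has pooled that the steep HbT run no
  # longer pushes HbO above its target.
  solve_late <- function(dd) {
    tA0 <- 25 - margin                       # steep run start (s into occ)
    tA1 <- tA0 + r1
    e <- hbd_geom(dd, occ_s)
    if (e < 0) return(NULL)
    M <- D + e
    M_abs <- L_hbt + M
    hbdA <- hbd_geom(dd, tA1)
    y_up <- min(0.85 * h * tA0 + r1 * h,      # pre-ramp slope <= 0.85 h
                D + hbdA,                     # HbO at ramp end <= target
                M / 1.02,                     # headroom below the peak
                0.9 * M - 0.1 * L_hbt)        # crossing after the ramp
    y_lo <- r1 * h                            # pre-ramp level >= 0
    p1_lo <- max(shelf + 0.3, Tp - p2max)
    p1_up <- Tp - 0.2
    if (p1_lo > p1_up) return(NULL)
    span <- occ_s - tA1
    kf2 <- (span - shelf) * 0.1 * M_abs
    ya_of_p1 <- function(p1) M - kf2 / (p1 - shelf)
    y_lo <- max(y_lo, ya_of_p1(p1_lo))
    y_up <- min(y_up, ya_of_p1(p1_up))
    if (y_lo > y_up) return(NULL)
    yA <- min(max(ya_of_p1(min(max(Tp / 2, p1_lo), p1_up)), y_lo), y_up)
    p1 <- kf2 / (M - yA) + shelf
    list(dd = dd, e = e, M = M, p1 = p1, mode = "late",
         knots_t = c(t0, t0 + tA0, t0 + tA1, t0 + occ_s - shelf, t0 + occ_s),
         knots_v = c(L_hbt, L_hbt + yA - r1 * h, L_hbt + yA, M_abs, M_abs))
  }

  # Shape C ("dip"): flat start, steep run over the last 5-s slope window,
  # shallow dip, then a late climb to the peak. The dip decouples the
  # climb-to-peak slope from the ramp height, which is the only way to honour
  # a short plateau time when the sampled HbT amplitude barely exceeds the
  # HF-mandated ramp (tail draws with small Tp and delta_hbo but large HF).
  solve_dip <- function(dd) {
    tA0 <- 25 - margin
    tA1 <- tA0 + r1
    t_dip <- 40
    e <- hbd_geom(dd, occ_s)
    if (e < 0) return(NULL)
    M <- D + e
    M_abs <- L_hbt + M
    hbdA <- hbd_geom(dd, tA1)
    # ramp top capped by the HbO target and by the 90% level; when smaller
    # than the mandatory ramp rise the ramp starts below the entry level
    yA <- min(r1 * h, D + hbdA, 0.88 * M - 0.12 * L_hbt)
    if (yA <= 0) return(NULL)
    p1_lo <- max(shelf + 0.3, Tp - p2max)
    p1_up <- Tp - 0.2
    if (p1_lo > p1_up) return(NULL)
    kf3 <- (occ_s - shelf - t_dip) * 0.1 * M_abs
    yb_of_p1 <- function(p1) M - kf3 / (p1 - shelf)
    yb_lo <- max(0, yb_of_p1(p1_lo))
    yb_up <- min(0.85 * M - 0.15 * L_hbt, yb_of_p1(p1_up))
    if (yb_lo > yb_up) return(NULL)
    yB <- min(max(yb_of_p1(min(max(Tp / 2, p1_lo), p1_up)), yb_lo), yb_up)
    p1 <- kf3 / (M - yB) + shelf
    list(dd = dd, e = e, M = M, p1 = p1, mode = "dip",
         knots_t = c(t0, t0 + tA0, t0 + tA1, t0 + t_dip,
                     t0 + occ_s - shelf, t0 + occ_s),
         knots_v = c(L_hbt, L_hbt + yA - r1 * h, L_hbt + yA, L_hbt + yB,
                     M_abs, M_abs))
  }

  # exact knot-level guard: HbO may not exceed its target anywhere in the
  # occlusion (the end-occlusion level IS the target)
  hbo_ok <- function(sol) {
    tt <- sort(unique(c(sol$knots_t, t0 + min(sol$dd, occ_s))))
    hbt_v <- stats::approx(sol$knots_t, sol$knots_v, xout = tt)$y
    hbd_v <- L_hbd + vapply(tt - t0, function(at) hbd_geom(sol$dd, at),
                            numeric(1))
    max(hbt_v - hbd_v) <= L_hbt - L_hbd + D * (1 + 1e-9) + 1e-12
  }

  sol <- NULL
  dd_grid <- unique(c(opts$hbd_rise_s, seq(15, 45, by = 5)))
  for (solver in list(solve_early, solve_late, solve_dip)) {
    for (dd in dd_grid) {
      sol <- solver(dd)
      if (!is.null(sol) && !hbo_ok(sol)) sol <- NULL
      if (!is.null(sol)) break
    }
    if (!is.null(sol)) break
  }
  if (is.null(sol))
    stop("infeasible targets: no admissible trace shape (HF/delta_hbo/tp ",
         "constraints cannot be met jointly)")

  M_abs <- L_hbt + sol$M
  p2 <- Tp - sol$p1
  f <- 0.1 * M_abs / p2
  wrate <- max(f, 0.9 * M_abs / (rec_s - p2 - 8))
  t_zero <- t0 + occ_s + p2 + 0.9 * M_abs / wrate
  hbt <- data.frame(
    t = c(sol$knots_t, t0 + occ_s + p2, t_zero, t0 + occ_s + rec_s),
    v = c(sol$knots_v, 0.9 * M_abs, 0, 0))
  e_abs <- L_hbd + sol$e
  hbd <- data.frame(
    t = c(t0, t0 + min(sol$dd, occ_s), t0 + occ_s,
          t0 + occ_s + min(20, rec_s - 10), t0 + occ_s + rec_s),
    v = c(L_hbd, L_hbd + sdr * min(sol$dd, occ_s), e_abs, 0, 0))
  list(hbt = hbt, hbd = hbd,
       params = c(dd = sol$dd, M = sol$M, p1 = sol$p1, p2 = p2,
                  fall_rate = f),
       mode = sol$mode)
}

#' Construct a noiseless hemoglobin trace realising feature targets
#'
#' Builds a piecewise-linear (moving-average-smoothed) HbT/HbD pair over the
#' full five-phase protocol such that running [extract_features()] on the
#' result (without noise or filtering) recovers the supplied targets: the
#' steepest 5-s HbT interval encodes HF, the early HbD rise rate encodes VO2,
#' the end-occlusion HbO level encodes ΔHbO, and the fall after deflation is
#' calibrated so the 90%-of-maximum plateau time equals Tp. HbO is defined as
#' HbT - HbD so the additive identity holds at every sample. Target
#' combinations that admit no such shape are rejected with the violated
#' constraint named.
#'
#' @param targets Data frame with columns `pressure`, `delta_hbo`, `hf`,
#'   `vo2`, `tp` (one row per occlusion phase of `protocol`); or a one-row
#'   wide data frame as returned by [sample_feature_targets()].
#' @param protocol A [cuff_protocol()].
#' @param opts A [trace_options()] list.
#' @return A [hemo_trace()]; shape parameters are attached as attribute
#'   `"shape"`.
#' @export
construct_trace <- function(targets, protocol = cuff_protocol(),
                            opts = trace_options()) {
  if (!is.null(targets$delta_hbo_60)) targets <- targets_long(targets[1, ])
  occ <- occlusion_phases(protocol)
  if (nrow(targets) != nrow(occ))
    stop("need one target row per occlusion phase")
  hbt_knots <- data.frame(t = c(0, occ$start_s[1]), v = c(0, 0))
  hbd_knots <- hbt_knots
  shape <- list()
  for (i in seq_len(nrow(occ))) {
    tr <- targets[targets$pressure == occ$pressure_mmHg[i], , drop = FALSE]
    if (nrow(tr) != 1)
      stop("no target row for ", occ$pressure_mmHg[i], " mmHg")
    rec_s <- protocol$phases$duration_s[match(occ$label[i],
                                              protocol$phases$label) + 1]
    blk <- build_occlusion_knots(tr$delta_hbo, tr$hf, tr$vo2, tr$tp,
                                 L_hbt = 0, L_hbd = 0, t0 = occ$start_s[i],
                                 occ_s = occ$duration_s[i], rec_s = rec_s,
                                 opts = opts)
    hbt_knots <- rbind(hbt_knots, blk$hbt)
    hbd_knots <- rbind(hbd_knots, blk$hbd)
    shape[[paste0("p", occ$pressure_mmHg[i])]] <- blk$params
  }
  times <- protocol_times(protocol)
  eval_knots <- function(k) {
    k <- k[!duplicated(k$t), ]
    stats::approx(k$t, k$v, xout = times, rule = 2)$y
  }
  w <- opts$smooth_width
  smooth <- function(x) {
    y <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
    bad <- is.na(y)
    y[bad] <- x[bad]
    y
  }
  hbt <- smooth(eval_knots(hbt_knots))
  hbd <- smooth(eval_knots(hbd_knots))
  out <- hemo_trace(times, hbo = hbt - hbd, hbd = hbd, hbt = hbt)
  attr(out, "shape") <- shape
  out
}

#' Measurement noise configuration for the optical forward model
#'
#' @param intensity_sd SD of multiplicative Gaussian intensity noise per
#'   sample (default 0.005, i.e. baseline SNR about 200, representative of
#'   channels retained by the SNR screen).
#' @param drift_sd SD of the per-channel linear drift rate, as fractional
#'   intensity change per minute (default 0.001).
#' @param low_snr_fraction Probability that a channel is degraded to a noise
#'   level failing the SNR < 4 screen (default 0; used to exercise QC).
#' @param motion_rate Expected number of injected motion artifacts (step +
#'   spike) per recording (default 0).
#' @param motion_amp Fractional intensity amplitude of injected artifacts.
#' @return List of class `noise_config`.
#' @export
noise_config <- function(intensity_sd = 0.005, drift_sd = 0.001,
                         low_snr_fraction = 0, motion_rate = 0,
                         motion_amp = 0.2) {
  stopifnot(intensity_sd >= 0, drift_sd >= 0,
            low_snr_fraction >= 0, low_snr_fraction <= 1, motion_rate >= 0)
  structure(list(intensity_sd = intensity_sd, drift_sd = drift_sd,
                 low_snr_fraction = low_snr_fraction,
                 motion_rate = motion_rate, motion_amp = motion_amp),
            class = "noise_config")
}

#' Generate a synthetic DVOS cohort
#'
#' Draws covariates and latent feature targets for each subject, constructs
#' the ground-truth hemoglobin trace realising those targets, and
#' forward-models it to a multi-wavelength optical recording. Deterministic
#' given `seed`. Subjects whose sampled target combination admits no feasible
#' trace (a tail event under the calibrated moments) have their targets
#' redrawn; the number of redraws is recorded in the metadata.
#'
#' @param n_pad,n_nonpad Group sizes (default 118 each, the study cohort).
#' @param protocol A [cuff_protocol()].
#' @param noise A [noise_config()].
#' @param seed Integer seed governing every random draw.
#' @param calib Calibration table.
#' @param loading Severity-factor loading (see [sample_feature_targets()]).
#' @param opts Trace morphology options.
#' @param optics Optical geometry, see [forward_model()] arguments; a list
#'   with `pathlength_cm`, `dpf`, `i0`, `n_detectors`.
#' @return List with `subjects` (covariate table, non-PAD rows first),
#'   `targets` (wide per-subject target table), `traces` (ground-truth
#'   [hemo_trace()] list), `recordings` (list of `optical_recording`), and
#'   `meta`.
#' @export
generate_cohort <- function(n_pad = 118, n_nonpad = 118,
                            protocol = cuff_protocol(),
                            noise = noise_config(), seed = 1,
                            calib = default_calibration(), loading = 0.6,
                            opts = trace_options(),
                            optics = list(pathlength_cm = 3, dpf = 4,
                                          i0 = 1000, n_detectors = 2)) {
  stopifnot(n_pad >= 1, n_nonpad >= 1)
  set.seed(as.integer(seed %% .Machine$integer.max))
  ext <- extinction_table()
  groups <- c(rep("nonPAD", n_nonpad), rep("PAD", n_pad))
  subjects <- rbind(sample_covariates(n_nonpad, "nonPAD", calib),
                    sample_covariates(n_pad, "PAD", calib))
  subjects <- cbind(id = sprintf("S%03d", seq_along(groups)), subjects,
                    stringsAsFactors = FALSE)
  targets <- NULL
  traces <- vector("list", length(groups))
  recordings <- vector("list", length(groups))
  redraws <- 0L
  for (i in seq_along(groups)) {
    for (attempt in seq_len(50L)) {
      tg <- sample_feature_targets(1, groups[i], calib, loading = loading)
      tr <- tryCatch(construct_trace(tg, protocol, opts),
                     error = function(e) e)
      if (!inherits(tr, "error")) break
      redraws <- redraws + 1L
      if (attempt == 50L)
        stop("could not draw feasible targets for subject ", i, ": ",
             conditionMessage(tr))
    }
    targets <- rbind(targets, tg)
    traces[[i]] <- tr
    recordings[[i]] <- forward_model(
      tr, protocol, ext, subject_id = subjects$id[i],
      pathlength_cm = optics$pathlength_cm, dpf = optics$dpf,
      i0 = optics$i0, n_detectors = optics$n_detectors, noise = noise)
  }
  targets <- cbind(id = subjects$id, targets, stringsAsFactors = FALSE)
  names(traces) <- names(recordings) <- subjects$id
  list(subjects = subjects, targets = targets, traces = traces,
       recordings = recordings,
       meta = list(seed = seed, calibration = calib$version,
                   loading = loading, target_redraws = redraws,
                   noise = unclass(noise), optics = optics))
}
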