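# shared fixtures, all built in code

default_protocol <- cuff_protocol()

# piecewise-linear hemoglobin pair on the default time base
knot_trace <- function(hbt_knots, hbd_knots = NULL,
                       protocol = default_protocol) {
  times <- protocol_times(protocol)
  ev <- function(k) stats::approx(k$t, k$v, xout = times, rule = 2)$y
  hbt <- ev(hbt_knots)
  hbd <- if (is.null(hbd_knots)) rep(0, length(times)) else ev(hbd_knots)
  hemo_trace(times, hbo = hbt - hbd, hbd = hbd, hbt = hbt)
}

kn <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(t = m[, 1], v = m[, 2])
}

# printed group-moment fixtures used as round-trip targets
table1_targets <- list(
  nonPAD = data.frame(pressure = c(60, 100),
                      delta_hbo = c(6.81, 9.44), hf = c(2.48, 2.90),
                      vo2 = c(0.066, 0.079), tp = c(23.44, 20.86)),
  PAD = data.frame(pressure = c(60, 100),
                   delta_hbo = c(2.01, 3.90), hf = c(0.86, 1.35),
                   vo2 = c(0.040, 0.052), tp = c(20.70, 17.12))
)

zero_noise <- noise_config(intensity_sd = 0, drift_sd = 0)

# one run of the full default pipeline, shared between acceptance checks
shared_run <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$run)) {
      cache$elapsed <- system.time(
        cache$run <- run_pipeline(run_config(seed = 42)))[["elapsed"]]
    }
    list(run = cache$run, elapsed = cache$elapsed)
  }
})
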