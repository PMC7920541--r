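# Shared fixtures, built once per test run and memoized. Everything is
# generated in code; no data files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# A small planted session with its preprocessed epochs and wavelet cube:
# 8 channels, go-delta burst in M1/ALM, wait-theta burst in vOFC/A32D,
# outcome-dependent theta coupling on M1-vOFC.
fx_session <- function() fixture("fx_session", function() {
  cfg <- session_config(
    n_channels = 8, n_trials = 30, seed = 7,
    burst_specs = list(
      planted_effect(c("M1", "ALM"), c(1, 4), c(0.3, 0.5), amplitude = 2,
                     condition = "go"),
      planted_effect(c("vOFC", "A32D"), c(4, 7), c(0.5, 2), amplitude = 2,
                     condition = "wait")),
    coupling_specs = list(
      planted_coupling(c("M1", "vOFC"), c(4, 7), c(0.5, 2), phase_lag = pi / 2,
                       kappa = 0.9, amplitude = 2,
                       condition = "wait-correct")))
  sess <- generate_session(cfg)
  ep <- epoch(sess$recording, sess$events, "stimulus", c(-1.5, 2.5))
  ep <- median_reference(reject_artifacts(ep)$epochs)
  cube <- wavelet_transform(ep, f_min = 2, f_max = 20, n_freqs = 19,
                            cycles = c(2, 0.7), n_times = 60)
  list(config = cfg, session = sess, epochs = ep, cube = cube)
})

# Paper-mimic multi-session world used by the effect-recovery acceptance
# criterion: 24 regions, go-delta in 5 motor channels (0.3-0.5 s), wait-theta
# in 8 channels (0.5-2 s), and outcome-dependent M1-vOFC theta coupling
# (kappa 0.9 on patient vs. 0 on impulsive wait trials). Scaled to 20
# sessions of 56 trials with a 2-30 Hz grid for test-budget reasons (the
# emulated world has ~272-trial sessions; per-session wPLI noise grows as
# 1/sqrt(trials), so the scale-down is kept as mild as the budget allows).
mimic_template <- function() {
  session_config(
    n_channels = 24, n_trials = 56, seed = 1, artifact_rate = 0.05,
    burst_specs = list(
      planted_effect(c("M1", "ALM", "A24a", "A24b", "A33"), c(1, 4),
                     c(0.3, 0.5), amplitude = 2, condition = "go"),
      planted_effect(c("A32D", "A32V", "vOFC", "lOFC", "NAcC", "VMS",
                       "DMS", "M2"), c(4, 7), c(0.5, 2), amplitude = 2,
                     condition = "wait")),
    coupling_specs = list(
      planted_coupling(c("M1", "vOFC"), c(4, 7), c(0.5, 2),
                       phase_lag = pi / 2, kappa = 0.9, amplitude = 2,
                       condition = "wait-correct"),
      planted_coupling(c("M1", "vOFC"), c(4, 7), c(0.5, 2),
                       phase_lag = pi / 2, kappa = 0, amplitude = 2,
                       condition = "wait-incorrect")))
}

mimic_config <- function(n_sessions = 20, seed = 101) {
  run_config(mimic_template(), n_sessions = n_sessions, seed = seed,
             epoch_window = c(-1.5, 2.6), f_max = 30, n_freqs = 29,
             n_times = 80)
}

fx_mimic_bundle <- function() fixture("fx_mimic_bundle", function() {
  run_all(mimic_config())
})

# Planted-bin bookkeeping for sensitivity scoring: core bins are frequency
# bins within 1 Hz of the planted carrier and times inside the central 80%
# of the planted window (the Hann taper and wavelet smoothing dilute edges).
core_bins <- function(times, freqs, band, window) {
  fc <- mean(band)
  pad <- 0.1 * diff(window)
  list(tidx = which(times >= window[1] + pad & times <= window[2] - pad),
       fidx = which(freqs >= fc - 1 & freqs <= fc + 1))
}

# Small recording with a single pure tone on one channel, for wavelet tests.
tone_recording <- function(freq, amplitude = 2, fs = 1000, dur = 20,
                           n_channels = 2) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  data <- matrix(stats::rnorm(n_channels * length(t), sd = 0), n_channels)
  data[1, ] <- amplitude * sin(2 * pi * freq * t)
  structure(list(data = data, fs = fs,
                 labels = paste0("ch", seq_len(n_channels))),
            class = "lfp_recording")
}

simple_events <- function(starts, rt = 0.6, type = "go", outcome = "correct") {
  data.frame(trial_id = seq_along(starts), start_time_s = starts,
             response_time_s = rep_len(rt, length(starts)),
             trial_type = rep_len(type, length(starts)),
             outcome = rep_len(outcome, length(starts)),
             stringsAsFactors = FALSE)
}

# Build an epoch_set directly (bypassing a recording) from a trials x
# channels x samples array.
make_epochs <- function(data, fs = 1000, window = NULL, events = NULL) {
  d <- dim(data)
  if (is.null(window)) window <- c(0, d[3] / fs)
  if (is.null(events)) events <- simple_events(seq_len(d[1]) * 10)
  structure(list(data = data, window = window, alignment = "stimulus",
                 fs = fs, labels = paste0("ch", seq_len(d[2])),
                 events = events, n_dropped = 0L),
            class = "epoch_set")
}

# Independent Monte-Carlo oracle for the wPLI implied by the von Mises
# coupling model: unit-amplitude trials with phase difference
# lag + jitter, jitter ~ VM(0, 2*kappa/(1-kappa)).
wpli_vm_oracle <- function(kappa, lag = pi / 2, n = 1e4) {
  conc <- if (kappa >= 1) Inf else 2 * kappa / (1 - kappa)
  ph <- lag + rvonmises(n, 0, conc)
  s <- sin(ph)
  abs(mean(s)) / mean(abs(s))
}
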