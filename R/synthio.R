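# Synthetic go/wait session generator. Produces a continuous multichannel
# recording with 1/f background noise, planted band-limited bursts, planted
# phase-coupled channel pairs, optional whole-trial artifacts and an optional
# zero-lag common source, together with the event table and the ground truth
# needed to score every downstream stage.

#' Default abstract region labels
#'
#' Labels for up to 32 recording channels. The pipeline treats channels as
#' labeled abstract regions; these defaults use conventional rodent region
#' acronyms (motor, prefrontal, striatal, thalamic, sensory and limbic sites)
#' purely as mnemonic names.
#'
#' @param n number of channels (<= 32).
#' @return character vector of length `n`.
#' @export
default_region_labels <- function(n = 32) {
  stopifnot(n >= 1, n <= 32)
  labs <- c("M1", "vOFC", "A32D", "A32V", "ALM", "M2", "A24a", "A24b",
            "A33", "lOFC", "NAcC", "NAcS", "VMS", "DMS", "DLS", "MDT",
            "CMT", "AI", "V1", "PPC", "RSC", "CA1", "CA3", "DG", "MS",
            "BLA", "CEA", "LFC", "S1", "A29c", "A30c", "SEPT")
  labs[seq_len(n)]
}

#' Describe a planted oscillatory burst
#'
#' @param channels character vector of channel labels receiving the burst.
#' @param band frequency band in Hz, `c(f_lo, f_hi)`; the burst is a tapered
#'   sinusoid at the band center.
#' @param window time window in seconds relative to the stimulus,
#'   `c(t0, t1)`.
#' @param amplitude burst amplitude as a multiple of the background noise SD.
#' @param condition trial condition receiving the burst: one of `"all"`,
#'   `"go"`, `"wait"`, `"go-correct"`, `"wait-correct"`, `"wait-incorrect"`.
#' @return an object of class `planted_effect`.
#' @export
planted_effect <- function(channels, band, window, amplitude = 1,
                           condition = "all") {
  stopifnot(length(band) == 2, band[1] < band[2],
            length(window) == 2, window[1] < window[2], amplitude >= 0)
  condition <- match.arg(condition, c("all", "go", "wait", "go-correct",
                                      "wait-correct", "wait-incorrect"))
  structure(list(channels = channels, band = band, window = window,
                 amplitude = amplitude, condition = condition),
            class = "planted_effect")
}

#' Describe a planted phase coupling between two channels
#'
#' Both channels of the pair receive a shared tapered sinusoid with a random
#' phase per trial; the second channel's copy is shifted by `phase_lag` plus
#' von Mises phase jitter whose concentration is a monotone map of `kappa`
#' (0 = no coupling, 1 = rigid lag). A non-zero lag gives the weighted
#' phase-lag index (wPLI) a well-defined target.
#'
#' @param pair character vector of two channel labels.
#' @param band frequency band in Hz; the shared component sits at its center.
#' @param window time window in seconds relative to the stimulus.
#' @param phase_lag fixed lag of the second channel in radians (non-zero).
#' @param kappa coupling strength in `[0, 1]`.
#' @param amplitude amplitude of the shared component, multiple of noise SD.
#' @param condition trial condition, as in [planted_effect()].
#' @return an object of class `planted_coupling`.
#' @export
planted_coupling <- function(pair, band, window, phase_lag = pi / 2,
                             kappa = 0.8, amplitude = 1, condition = "all") {
  stopifnot(length(pair) == 2, length(band) == 2, band[1] < band[2],
            length(window) == 2, window[1] < window[2],
            kappa >= 0, kappa <= 1, amplitude >= 0)
  condition <- match.arg(condition, c("all", "go", "wait", "go-correct",
                                      "wait-correct", "wait-incorrect"))
  structure(list(pair = pair, band = band, window = window,
                 phase_lag = phase_lag, kappa = kappa, amplitude = amplitude,
                 condition = condition),
            class = "planted_coupling")
}

#' Configure a synthetic go/wait session
#'
#' Defaults reproduce the task statistics the pipeline assumes: a 25%/75%
#' go/wait trial mix, sessions near 272 trials, go response times with a
#' median near 588 ms, and bimodal wait response times (impulsive component
#' near 1263 ms, patient component near 2513 ms, truncated at the 2 s
#' criterion). Trials are self-paced with inter-trial onset intervals drawn
#' uniformly from 8-12 s so that 7 s epochs never overlap.
#'
#' @param n_channels number of channels (default 32).
#' @param fs sampling rate in Hz (default 1000).
#' @param n_trials number of trials (default 272).
#' @param p_go probability of a go trial (default 0.25).
#' @param rt_go_meanlog,rt_go_sdlog lognormal parameters of go response
#'   times in seconds.
#' @param p_go_lapse probability that a go trial is a lapse (response after
#'   the 2 s deadline, scored incorrect).
#' @param rt_wait_impulsive_mean,rt_wait_impulsive_sd truncated-normal
#'   parameters (seconds) of the impulsive wait component (< 2 s).
#' @param rt_wait_patient_mean,rt_wait_patient_sd truncated-normal
#'   parameters (seconds) of the patient wait component (> 2 s).
#' @param p_patient probability a wait trial is patient (correct).
#' @param burst_specs list of [planted_effect()] objects.
#' @param coupling_specs list of [planted_coupling()] objects.
#' @param noise_exponent 1/f power-spectrum slope of the background noise.
#' @param noise_sd background noise standard deviation (arbitrary units).
#' @param artifact_rate proportion of trials receiving an artifact.
#' @param artifact_gain amplitude scaling applied to artifact trials.
#' @param common_source_gain gain of an optional zero-lag latent source
#'   mixed instantaneously into every channel (volume-conduction confound).
#' @param iti_range inter-trial onset interval range in seconds.
#' @param min_trial_spacing minimum onset spacing (seconds) compatible with
#'   the epoch window; smaller realized spacing is an error.
#' @param lead_in,tail padding (seconds) before the first and after the last
#'   trial onset.
#' @param channel_labels channel labels; defaults to
#'   [default_region_labels()].
#' @param seed integer seed; every draw in [generate_session()] flows from
#'   it.
#' @return a `session_config` list, validated.
#' @export
session_config <- function(n_channels = 32, fs = 1000, n_trials = 272,
                           p_go = 0.25,
                           rt_go_meanlog = log(0.588), rt_go_sdlog = 0.2,
                           p_go_lapse = 0.03,
                           rt_wait_impulsive_mean = 1.263,
                           rt_wait_impulsive_sd = 0.29,
                           rt_wait_patient_mean = 2.513,
                           rt_wait_patient_sd = 0.135,
                           p_patient = 0.54,
                           burst_specs = list(), coupling_specs = list(),
                           noise_exponent = 1, noise_sd = 1,
                           artifact_rate = 0, artifact_gain = 25,
                           common_source_gain = 0,
                           iti_range = c(8, 12), min_trial_spacing = 7,
                           lead_in = 10, tail = 10,
                           channel_labels = NULL, seed = 1) {
  if (is.null(channel_labels)) {
    channel_labels <- if (n_channels <= 32) default_region_labels(n_channels)
                      else paste0("ch", seq_len(n_channels))
  }
  cfg <- list(n_channels = n_channels, fs = fs, n_trials = n_trials,
              p_go = p_go, rt_go_meanlog = rt_go_meanlog,
              rt_go_sdlog = rt_go_sdlog, p_go_lapse = p_go_lapse,
              rt_wait_impulsive_mean = rt_wait_impulsive_mean,
              rt_wait_impulsive_sd = rt_wait_impulsive_sd,
              rt_wait_patient_mean = rt_wait_patient_mean,
              rt_wait_patient_sd = rt_wait_patient_sd,
              p_patient = p_patient, burst_specs = burst_specs,
              coupling_specs = coupling_specs,
              noise_exponent = noise_exponent, noise_sd = noise_sd,
              artifact_rate = artifact_rate, artifact_gain = artifact_gain,
              common_source_gain = common_source_gain,
              iti_range = iti_range, min_trial_spacing = min_trial_spacing,
              lead_in = lead_in, tail = tail,
              channel_labels = channel_labels, seed = seed)
  validate_session_config(cfg)
  class(cfg) <- "session_config"
  cfg
}

validate_session_config <- function(cfg) {
  stopifnot(cfg$n_channels >= 1, cfg$fs > 0, cfg$n_trials >= 1,
            cfg$p_go >= 0, cfg$p_go <= 1,
            cfg$p_patient >= 0, cfg$p_patient <= 1,
            cfg$p_go_lapse >= 0, cfg$p_go_lapse <= 1,
            cfg$artifact_rate >= 0, cfg$artifact_rate <= 1,
            cfg$noise_sd >= 0, cfg$iti_range[1] <= cfg$iti_range[2],
            length(cfg$channel_labels) == cfg$n_channels,
            !anyDuplicated(cfg$channel_labels))
  band_tops <- c(
    vapply(cfg$burst_specs, function(b) b$band[2], numeric(1)),
    vapply(cfg$coupling_specs, function(b) b$band[2], numeric(1)))
  if (length(band_tops) && cfg$fs <= 2 * max(band_tops))
    stop("sampling rate must exceed twice the highest planted frequency")
  invisible(cfg)
}

# Truncated normal draws by inverse-CDF (vectorized, deterministic in the
# RNG stream).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Which trials does a planted condition apply to?
condition_matches <- function(condition, trial_type, outcome) {
  switch(condition,
         "all" = rep(TRUE, length(trial_type)),
         "go" = trial_type == "go",
         "wait" = trial_type == "wait",
         "go-correct" = trial_type == "go" & outcome == "correct",
         "wait-correct" = trial_type == "wait" & outcome == "correct",
         "wait-incorrect" = trial_type == "wait" & outcome == "incorrect",
         stop("unknown condition: ", condition))
}

#' Generate a synthetic session
#'
#' Draws the event table (trial types, outcomes, response times), synthesizes
#' the continuous recording (1/f noise, planted bursts, planted couplings,
#' optional zero-lag common source and whole-trial artifacts), and returns
#' the full ground truth. Bit-reproducible given `config$seed`.
#'
#' @param config a [session_config()].
#' @return list with elements `recording` (class `lfp_recording`: `data`
#'   channels x samples, `fs`, `labels`), `events` (data frame with columns
#'   `trial_id, start_time_s, response_time_s, trial_type, outcome`) and
#'   `ground_truth` (per-trial labels incl. mixture component and artifact
#'   flag, realized bursts, realized couplings, recorded warnings).
#' @export
generate_session <- function(config) {
  validate_session_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_trials
  fs <- config$fs
  warnings <- character(0)

  ## --- events ---------------------------------------------------------
  gaps <- stats::runif(max(n - 1, 0), config$iti_range[1], config$iti_range[2])
  if (length(gaps) && min(gaps) < config$min_trial_spacing)
    stop("inter-trial spacing shorter than the epoch window")
  onsets <- config$lead_in + c(0, cumsum(gaps))
  is_go <- stats::rbinom(n, 1, config$p_go) == 1
  trial_type <- ifelse(is_go, "go", "wait")
  rt <- numeric(n)
  component <- character(n)
  n_go <- sum(is_go)
  if (n_go > 0) {
    lapse <- stats::rbinom(n_go, 1, config$p_go_lapse) == 1
    r <- stats::rlnorm(n_go, config$rt_go_meanlog, config$rt_go_sdlog)
    r[lapse] <- stats::runif(sum(lapse), 2.05, 3.5)
    r <- pmin(r, 1.99 + 1.51 * lapse)  # non-lapse go responses beat 2 s
    rt[is_go] <- r
    component[is_go] <- ifelse(lapse, "go-lapse", "go")
  }
  n_wait <- n - n_go
  if (n_wait > 0) {
    patient <- stats::rbinom(n_wait, 1, config$p_patient) == 1
    r <- numeric(n_wait)
    r[patient] <- rtruncnorm(sum(patient), config$rt_wait_patient_mean,
                             config$rt_wait_patient_sd, lower = 2.001)
    r[!patient] <- rtruncnorm(sum(!patient), config$rt_wait_impulsive_mean,
                              config$rt_wait_impulsive_sd,
                              lower = 0.15, upper = 1.999)
    rt[!is_go] <- r
    component[!is_go] <- ifelse(patient, "patient", "impulsive")
  }
  outcome <- ifelse(trial_type == "go", ifelse(rt <= 2, "correct", "incorrect"),
                    ifelse(rt > 2, "correct", "incorrect"))
  events <- data.frame(trial_id = seq_len(n), start_time_s = onsets,
                       response_time_s = rt, trial_type = trial_type,
                       outcome = outcome, stringsAsFactors = FALSE)

  ## --- continuous data ------------------------------------------------
  n_samples <- round((onsets[n] + config$tail) * fs)
  data <- matrix(0, config$n_channels, n_samples)
  for (c in seq_len(config$n_channels))
    data[c, ] <- one_over_f_noise(n_samples, fs, config$noise_exponent,
                                  config$noise_sd)
  if (config$common_source_gain != 0) {
    src <- one_over_f_noise(n_samples, fs, config$noise_exponent,
                            config$noise_sd)
    data <- data + config$common_source_gain *
      matrix(src, config$n_channels, n_samples, byrow = TRUE)
  }
  tvec <- (seq_len(n_samples) - 1) / fs

  window_idx <- function(t_on, window) {
    i0 <- round((t_on + window[1]) * fs) + 1L
    i1 <- round((t_on + window[2]) * fs)
    if (i0 < 1L || i1 > n_samples) return(NULL)
    i0:i1
  }

  bursts <- list()
  for (spec in config$burst_specs) {
    ch_idx <- match(spec$channels, config$channel_labels)
    if (anyNA(ch_idx)) stop("unknown channel label in burst spec")
    fc <- mean(spec$band)
    sel <- which(condition_matches(spec$condition, trial_type, outcome))
    for (tr in sel) {
      idx <- window_idx(onsets[tr], spec$window)
      if (is.null(idx)) next
      phase <- stats::runif(1, 0, 2 * pi)
      wavef <- spec$amplitude * config$noise_sd * tukey_taper(length(idx)) *
        sin(2 * pi * fc * tvec[idx] + phase)
      data[ch_idx, idx] <- data[ch_idx, idx] +
        matrix(wavef, length(ch_idx), length(idx), byrow = TRUE)
      bursts[[length(bursts) + 1L]] <- data.frame(
        trial_id = tr, channels = paste(spec$channels, collapse = ";"),
        f_center = fc, t0 = spec$window[1], t1 = spec$window[2],
        amplitude = spec$amplitude, condition = spec$condition)
    }
  }

  couplings <- list()
  for (spec in config$coupling_specs) {
    ch_idx <- match(spec$pair, config$channel_labels)
    if (anyNA(ch_idx)) stop("unknown channel label in coupling spec")
    if (spec$kappa > 0 && abs(wrap_angle(spec$phase_lag)) < 1e-12) {
      warnings <- c(warnings,
                    "coupling with kappa > 0 and zero phase lag: wPLI target undefined")
    }
    fc <- mean(spec$band)
    conc <- kappa_to_concentration(spec$kappa)
    sel <- which(condition_matches(spec$condition, trial_type, outcome))
    for (tr in sel) {
      idx <- window_idx(onsets[tr], spec$window)
      if (is.null(idx)) next
      phase <- stats::runif(1, 0, 2 * pi)
      jit <- rvonmises(1, 0, conc)
      tap <- spec$amplitude * config$noise_sd * tukey_taper(length(idx))
      arg <- 2 * pi * fc * tvec[idx] + phase
      data[ch_idx[1], idx] <- data[ch_idx[1], idx] + tap * sin(arg)
      data[ch_idx[2], idx] <- data[ch_idx[2], idx] +
        tap * sin(arg + spec$phase_lag + jit)
      couplings[[length(couplings) + 1L]] <- data.frame(
        trial_id = tr, pair = paste(spec$pair, collapse = ";"),
        f_center = fc, t0 = spec$window[1], t1 = spec$window[2],
        phase_lag = spec$phase_lag, jitter = jit, kappa = spec$kappa,
        condition = spec$condition)
    }
  }

  artifact <- rep(FALSE, n)
  if (config$artifact_rate > 0) {
    artifact <- stats::rbinom(n, 1, config$artifact_rate) == 1
    for (tr in which(artifact)) {
      idx <- window_idx(onsets[tr], c(-2, 5))
      if (is.null(idx)) idx <- window_idx(onsets[tr], c(0, 2))
      n_aff <- max(1L, stats::rbinom(1, config$n_channels, 0.5))
      chans <- sample(config$n_channels, n_aff)
      data[chans, idx] <- data[chans, idx] * config$artifact_gain
    }
  }

  recording <- structure(list(data = data, fs = fs,
                              labels = config$channel_labels),
                         class = "lfp_recording")
  ground_truth <- list(
    trials = data.frame(trial_id = seq_len(n), trial_type = trial_type,
                        outcome = outcome, rt = rt, component = component,
                        artifact = artifact, stringsAsFactors = FALSE),
    bursts = if (length(bursts)) do.call(rbind, bursts) else NULL,
    couplings = if (length(couplings)) do.call(rbind, couplings) else NULL,
    warnings = warnings)
  list(recording = recording, events = events, ground_truth = ground_truth)
}
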