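# Time-frequency decomposition and evoked-activity summaries.
#
# Morlet wavelets are applied in the frequency domain: the FFT of each
# trial/channel trace is multiplied by a Gaussian frequency window centered
# on each analysis frequency (negative frequencies zeroed, positive doubled),
# which yields the complex analytic coefficient whose modulus recovers the
# amplitude of a pure sinusoid at the center frequency with unit gain.

# Cycles grow with frequency as n_cycles(f) = c0 * (f / f_min)^(1 - c1):
# the lowest frequency gets c0 cycles; higher frequencies get more, but less
# than fully proportional (EEGLAB-style [c0, c1] expansion semantics).
n_cycles_at <- function(f, f_min, cycles) {
  cycles[1] * (f / f_min)^(1 - cycles[2])
}

#' Morlet wavelet transform of an epoch set
#'
#' @param epochs an `epoch_set` (see [epoch()]).
#' @param f_min,f_max frequency range in Hz (default 2-70).
#' @param n_freqs number of linearly spaced frequencies (default 139).
#' @param cycles `c(c0, c1)` cycle expansion parameters (default `c(2, 0.7)`).
#' @param n_times number of output time points (default 200), evenly spaced
#'   over the epoch interior where the longest (lowest-frequency) wavelet
#'   fits fully (three temporal SDs from each epoch edge).
#' @return a `tf_cube`: list with `coef` (complex, trials x channels x
#'   n_freqs x n_times), `freqs`, `times`, `labels`, `events`, `fs`,
#'   `cycles`, `f_min`.
#' @export
wavelet_transform <- function(epochs, f_min = 2, f_max = 70, n_freqs = 139,
                              cycles = c(2, 0.7), n_times = 200) {
  stopifnot(inherits(epochs, "epoch_set"), f_min > 0, f_min < f_max,
            n_freqs >= 1, n_times >= 1, length(cycles) == 2)
  fs <- epochs$fs
  if (f_max > fs / 2) stop("f_max exceeds the Nyquist frequency")
  d <- dim(epochs$data)
  n_trials <- d[1]; n_chan <- d[2]; n_samp <- d[3]
  sigma_t_max <- n_cycles_at(f_min, f_min, cycles) / (2 * pi * f_min)
  support <- 3 * sigma_t_max
  if (n_samp / fs <= 2 * support)
    stop("epoch shorter than the lowest-frequency wavelet support")
  tvec <- epoch_times(epochs)
  t_lo <- tvec[1] + support
  t_hi <- tvec[n_samp] - support
  times <- if (n_times == 1) mean(c(t_lo, t_hi))
           else seq(t_lo, t_hi, length.out = n_times)
  time_idx <- pmin(pmax(round((times - tvec[1]) * fs) + 1L, 1L), n_samp)
  freqs <- if (n_freqs == 1) f_min else seq(f_min, f_max, length.out = n_freqs)

  nfft <- stats::nextn(n_samp, c(2, 3, 5))
  fgrid <- (seq_len(nfft) - 1) * fs / nfft
  n_pos <- floor(nfft / 2) + 1L
  # columns = (trial, channel) traces
  mat <- matrix(0, nfft, n_trials * n_chan)
  mat[seq_len(n_samp), ] <- matrix(aperm(epochs$data, c(3, 1, 2)), n_samp)

  coef <- array(complex(real = 0), c(n_trials, n_chan, n_freqs, n_times))
  chunk <- max(64L, min(ncol(mat), floor(2^23 / nfft)))
  starts <- seq(1L, ncol(mat), by = chunk)
  for (s0 in starts) {
    cols <- s0:min(s0 + chunk - 1L, ncol(mat))
    spec <- stats::mvfft(mat[, cols, drop = FALSE])
    for (j in seq_len(n_freqs)) {
      sigma_f <- freqs[j] / n_cycles_at(freqs[j], f_min, cycles)
      gain <- numeric(nfft)
      gain[seq_len(n_pos)] <-
        2 * exp(-0.5 * ((fgrid[seq_len(n_pos)] - freqs[j]) / sigma_f)^2)
      gain[1] <- gain[1] / 2                        # DC is not doubled
      if (nfft %% 2 == 0) gain[n_pos] <- gain[n_pos] / 2
      x <- stats::mvfft(spec * gain, inverse = TRUE)[time_idx, ,
                                                     drop = FALSE] / nfft
      # unfold columns back to (trial, channel)
      ci <- arrayInd(cols, c(n_trials, n_chan))
      for (k in seq_along(cols))
        coef[ci[k, 1], ci[k, 2], j, ] <- x[, k]
    }
  }
  structure(list(coef = coef, freqs = freqs, times = times,
                 labels = epochs$labels, events = epochs$events, fs = fs,
                 cycles = cycles, f_min = f_min),
            class = "tf_cube")
}

# Temporal SD (seconds) of the wavelet at frequency f under a cube's cycles.
wavelet_sigma_t <- function(cube, f) {
  n_cycles_at(f, cube$f_min, cube$cycles) / (2 * pi * f)
}

# Indices of cube times falling inside a closed window.
time_indices <- function(times, window) {
  idx <- which(times >= window[1] & times <= window[2])
  if (!length(idx)) stop("no time points inside window [",
                         window[1], ", ", window[2], "]")
  idx
}

freq_indices <- function(freqs, band) {
  idx <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(idx)) stop("no frequencies inside band [",
                         band[1], ", ", band[2], "]")
  idx
}

#' Per-trial baseline-subtracted analytic amplitude
#'
#' Subtracts, per electrode and frequency, the mean amplitude over the
#' baseline window from every time point. With `groups = NULL` the baseline
#' is the mean over all supplied trials (baseline of the average); passing a
#' factor of trial conditions computes the baseline within each condition.
#'
#' @param cube a `tf_cube`.
#' @param baseline baseline window in seconds (default `c(-1, -0.75)`,
#'   i.e., 1000-750 ms before the stimulus).
#' @param groups optional factor (length = trials) of condition labels.
#' @return array of evoked amplitude, trials x channels x freqs x times.
#' @export
evoked_power <- function(cube, baseline = c(-1, -0.75), groups = NULL) {
  stopifnot(inherits(cube, "tf_cube"))
  if (baseline[1] < cube$times[1] || baseline[2] > max(cube$times))
    stop("baseline window outside the epoch time grid")
  amp <- Mod(cube$coef)
  bidx <- time_indices(cube$times, baseline)
  d <- dim(amp)
  split_groups <- if (is.null(groups)) list(seq_len(d[1]))
                  else split(seq_len(d[1]), groups)
  for (tr in split_groups) {
    if (!length(tr)) next
    bl <- apply(amp[tr, , , bidx, drop = FALSE], c(2, 3), mean)
    amp[tr, , , ] <- amp[tr, , , , drop = FALSE] -
      aperm(array(bl, c(d[2], d[3], length(tr), d[4])), c(3, 1, 2, 4))
  }
  amp
}

tfe_conditions <- function(events) {
  list("go-correct" = events$trial_type == "go" & events$outcome == "correct",
       "wait-correct" = events$trial_type == "wait" &
         events$outcome == "correct",
       "wait-incorrect" = events$trial_type == "wait" &
         events$outcome == "incorrect")
}

#' Session-level time-frequency-electrode (TFE) maps per condition
#'
#' For each requested trial condition: average the analytic amplitude over
#' the condition's trials, subtract the mean baseline amplitude (per
#' electrode and frequency), and z-score over the time dimension (per
#' electrode and frequency). Under the default analysis configuration the
#' result is the 200 x 139 x 32 times x freqs x electrodes session matrix.
#'
#' @param cube a `tf_cube` carrying trial metadata in `cube$events`.
#' @param conditions character vector of conditions (default the three task
#'   conditions `go-correct`, `wait-correct`, `wait-incorrect`).
#' @param baseline baseline window in seconds (default `c(-1, -0.75)`).
#' @param zscore z-score over time after baseline subtraction (default TRUE).
#' @return named list of `tfe_matrix` arrays (times x freqs x electrodes)
#'   with attributes `times`, `freqs`, `labels`, `condition`, `n_trials`.
#'   Conditions without trials are omitted with a warning.
#' @export
session_maps <- function(cube, conditions = c("go-correct", "wait-correct",
                                              "wait-incorrect"),
                         baseline = c(-1, -0.75), zscore = TRUE) {
  stopifnot(inherits(cube, "tf_cube"))
  if (baseline[1] < cube$times[1] || baseline[2] > max(cube$times))
    stop("baseline window outside the epoch time grid")
  sel <- tfe_conditions(cube$events)[conditions]
  amp <- Mod(cube$coef)
  bidx <- time_indices(cube$times, baseline)
  out <- list()
  for (cond in conditions) {
    keep <- sel[[cond]]
    if (is.null(keep) || !any(keep)) {
      warning("condition '", cond, "' has no trials; omitted")
      next
    }
    m <- colMeans(amp[keep, , , , drop = FALSE], dims = 1)       # ch x f x t
    bl <- rowMeans(m[, , bidx, drop = FALSE], dims = 2)
    m <- m - array(bl, dim(m))
    tfe <- aperm(m, c(3, 2, 1))                                  # t x f x ch
    if (zscore) {
      nt <- dim(tfe)[1]
      tm <- matrix(tfe, nt)
      mu <- colMeans(tm)
      sd <- sqrt(pmax(colMeans(tm^2) - mu^2, 0) * nt / (nt - 1))
      sd[sd == 0] <- 1
      tfe <- array(t((t(tm) - mu) / sd), dim(tfe))
    }
    attr(tfe, "times") <- cube$times
    attr(tfe, "freqs") <- cube$freqs
    attr(tfe, "labels") <- cube$labels
    attr(tfe, "condition") <- cond
    attr(tfe, "n_trials") <- sum(keep)
    class(tfe) <- "tfe_matrix"
    out[[cond]] <- tfe
  }
  out
}

#' Mean TFE value per electrode over a band and time window
#'
#' Arithmetic mean over all (time, frequency) bins whose centers fall inside
#' the closed band x window selection, reported per electrode.
#'
#' @param tfe a `tfe_matrix` (or plain times x freqs x electrodes array with
#'   `times`/`freqs`/`labels` attributes).
#' @param band frequency band in Hz, `c(f_lo, f_hi)`.
#' @param window time window in seconds, `c(t0, t1)`.
#' @return named numeric vector, one value per electrode.
#' @export
band_window_mean <- function(tfe, band, window) {
  times <- attr(tfe, "times"); freqs <- attr(tfe, "freqs")
  tidx <- time_indices(times, window)
  fidx <- freq_indices(freqs, band)
  vals <- apply(unclass(tfe)[tidx, fidx, , drop = FALSE], 3, mean)
  names(vals) <- attr(tfe, "labels")
  vals
}

#' Event-related potentials per condition
#'
#' Optional broad-band FFT band-pass (upper edge capped at Nyquist with a
#' warning), per-trial baseline mean subtraction, then trial mean and SEM per
#' condition and electrode.
#'
#' @param epochs an `epoch_set`.
#' @param conditions conditions to average (default the three task
#'   conditions).
#' @param band band-pass edges in Hz (default `c(0.3, 500)`); `NULL` skips
#'   filtering.
#' @param baseline baseline window in seconds for mean subtraction.
#' @return named list per condition: `mean` and `sem` (channels x samples),
#'   `n_trials`; plus `times` and `labels` at the top level.
#' @export
compute_erp <- function(epochs, conditions = c("go-correct", "wait-correct",
                                               "wait-incorrect"),
                        band = c(0.3, 500), baseline = c(-1, -0.75)) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  data <- epochs$data
  fs <- epochs$fs
  if (!is.null(band)) {
    if (band[2] > fs / 2) {
      warning("band upper edge exceeds Nyquist; clipped to fs/2")
      band[2] <- fs / 2
    }
    n_samp <- d[3]
    mat <- matrix(aperm(data, c(3, 1, 2)), n_samp)
    nfft <- stats::nextn(n_samp, c(2, 3, 5))
    padded <- rbind(mat, matrix(0, nfft - n_samp, ncol(mat)))
    fgrid <- (seq_len(nfft) - 1) * fs / nfft
    fpos <- pmin(fgrid, fs - fgrid)
    keep <- fpos >= band[1] & fpos <= band[2]
    spec <- stats::mvfft(padded)
    spec[!keep, ] <- 0
    filt <- Re(stats::mvfft(spec, inverse = TRUE)[seq_len(n_samp), ,
                                                  drop = FALSE]) / nfft
    data <- aperm(array(filt, c(n_samp, d[1], d[2])), c(2, 3, 1))
  }
  tvec <- epoch_times(epochs)
  bidx <- which(tvec >= baseline[1] & tvec <= baseline[2])
  if (!length(bidx)) stop("baseline window outside epoch")
  bl <- apply(data[, , bidx, drop = FALSE], c(1, 2), mean)
  data <- data - array(bl, dim(data))
  sel <- tfe_conditions(epochs$events)[conditions]
  out <- list(times = tvec, labels = epochs$labels)
  for (cond in conditions) {
    keep <- sel[[cond]]
    if (is.null(keep) || sum(keep) < 2) {
      warning("condition '", cond, "' has fewer than 2 trials; omitted")
      next
    }
    x <- data[keep, , , drop = FALSE]
    m <- apply(x, c(2, 3), mean)
    s <- apply(x, c(2, 3), stats::sd) / sqrt(sum(keep))
    out[[cond]] <- list(mean = m, sem = s, n_trials = sum(keep))
  }
  out
}
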