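# Preprocessing: event-locked epoching, single-pass amplitude-based artifact
# rejection, and cross-channel median referencing.

#' Extract event-locked epochs
#'
#' Cuts the continuous recording into trials x channels x samples epochs
#' aligned to the stimulus (trial start) or to the response. Windows are
#' half-open `[t_pre, t_post)`: with `fs = 1000` and the default window
#' `c(-2, 5)` each epoch has exactly 7000 samples. The event sample is
#' `round(t_event * fs)` on the zero-based sample grid (sample k sits at
#' time k/fs). Trials whose window falls outside the recording are dropped
#' with a warning.
#'
#' @param recording an `lfp_recording`.
#' @param events event table (see [read_events()]).
#' @param alignment `"stimulus"` or `"response"`.
#' @param window `c(t_pre, t_post)` in seconds relative to the event.
#' @return an `epoch_set`: list with `data` (trials x channels x samples),
#'   `window`, `alignment`, `fs`, `labels`, `events` (retained rows),
#'   `n_dropped`.
#' @export
epoch <- function(recording, events, alignment = c("stimulus", "response"),
                  window = c(-2, 5)) {
  alignment <- match.arg(alignment)
  stopifnot(inherits(recording, "lfp_recording"),
            length(window) == 2, window[1] < window[2])
  fs <- recording$fs
  n_samp <- round((window[2] - window[1]) * fs)
  t_event <- events$start_time_s
  if (alignment == "response") t_event <- t_event + events$response_time_s
  start0 <- round(t_event * fs) + round(window[1] * fs)  # zero-based
  keep <- start0 >= 0 & (start0 + n_samp) <= ncol(recording$data)
  if (any(!keep))
    warning(sum(!keep), " trial(s) dropped: epoch window outside recording")
  idx <- which(keep)
  if (!length(idx)) stop("no trial fits inside the recording")
  data <- array(0, c(length(idx), nrow(recording$data), n_samp))
  for (i in seq_along(idx)) {
    s <- start0[idx[i]]
    data[i, , ] <- recording$data[, (s + 1L):(s + n_samp)]
  }
  structure(list(data = data, window = window, alignment = alignment,
                 fs = fs, labels = recording$labels,
                 events = events[idx, , drop = FALSE],
                 n_dropped = sum(!keep)),
            class = "epoch_set")
}

# Time axis of an epoch_set (seconds relative to the alignment event).
epoch_times <- function(epochs) {
  n_samp <- dim(epochs$data)[3]
  epochs$window[1] + (seq_len(n_samp) - 1) / epochs$fs
}

#' Reject high-amplitude trials
#'
#' Single-pass rule: a scalar activity score is computed per trial and trials
#' whose score exceeds `mean(scores) + k * sd(scores)` are discarded. The
#' default score (`"max_abs"`) is the maximum absolute amplitude across time
#' and channels after per-channel mean centering; `"pooled_sd"` uses the
#' per-trial standard deviation pooled over channels. If the score SD across
#' trials is zero (e.g., identical trials) no trial is rejected.
#'
#' @param epochs an `epoch_set`.
#' @param k rejection threshold in score standard deviations (default 4).
#' @param score scoring rule, `"max_abs"` (default) or `"pooled_sd"`.
#' @return list with `epochs` (survivors), `mask` (TRUE = rejected),
#'   `scores`, `threshold`, `n_rejected`.
#' @export
reject_artifacts <- function(epochs, k = 4, score = c("max_abs",
                                                      "pooled_sd")) {
  score <- match.arg(score)
  stopifnot(inherits(epochs, "epoch_set"), k > 0)
  d <- dim(epochs$data)
  if (d[1] < 2) stop("artifact rejection needs at least 2 trials")
  scores <- vapply(seq_len(d[1]), function(tr) {
    x <- epochs$data[tr, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    centered <- x - rowMeans(x)
    if (score == "max_abs") max(abs(centered)) else stats::sd(centered)
  }, numeric(1))
  s <- stats::sd(scores)
  threshold <- if (is.finite(k)) mean(scores) + k * s else Inf
  mask <- if (s == 0) rep(FALSE, d[1]) else scores > threshold
  if (all(mask)) stop("all trials rejected")
  out <- epochs
  out$data <- epochs$data[!mask, , , drop = FALSE]
  out$events <- epochs$events[!mask, , drop = FALSE]
  list(epochs = out, mask = mask, scores = scores, threshold = threshold,
       n_rejected = sum(mask))
}

#' Median-reference epochs
#'
#' At every (trial, sample) the median across channels is subtracted from
#' each channel, so the cross-channel median is exactly zero everywhere.
#' Pairwise channel differences are preserved exactly.
#'
#' @param epochs an `epoch_set` with at least 2 channels.
#' @return the referenced `epoch_set`.
#' @export
median_reference <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  if (d[2] < 2) stop("median referencing needs at least 2 channels")
  out <- epochs
  ref <- cpp_median_reference(as.vector(epochs$data), d[1], d[2], d[3])
  out$data <- array(ref, d)
  out
}
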