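# Weighted phase-lag index (wPLI) connectivity.
#
# For channels x and y with wavelet coefficients X, Y the cross-spectrum is
# Z = X * Conj(Y); at each (pair, frequency, time),
#   wPLI = |E[Im(Z)]| / E[|Im(Z)|],
# with E the mean over trials. Because only the imaginary part of the
# cross-spectrum enters, zero-lag (volume-conducted) coupling is suppressed;
# where E[|Im(Z)|] is numerically zero the estimate is undefined and masked.

#' Raw wPLI stack from wavelet coefficients
#'
#' @param cube a `tf_cube` (see [wavelet_transform()]).
#' @param trials optional integer/logical index of trials to use (e.g., one
#'   trial condition); default all.
#' @return a `wpli_stack`: list with `wpli` (electrodes x electrodes x
#'   freqs x times, symmetric, `NA` on the diagonal and at masked bins),
#'   `n_masked` per pair, `n_trials`, `freqs`, `times`, `labels`.
#' @export
wpli <- function(cube, trials = NULL) {
  stopifnot(inherits(cube, "tf_cube"))
  coef <- cube$coef
  if (!is.null(trials)) coef <- coef[trials, , , , drop = FALSE]
  d <- dim(coef)
  if (d[1] < 2) stop("wPLI needs at least 2 trials")
  n_ch <- d[2]
  w <- array(NA_real_, c(n_ch, n_ch, d[3], d[4]))
  n_masked <- matrix(0L, n_ch, n_ch)
  eps_scale <- sqrt(.Machine$double.eps)
  for (a in seq_len(n_ch - 1)) {
    xa <- coef[, a, , , drop = FALSE]
    for (b in (a + 1):n_ch) {
      z <- xa * Conj(coef[, b, , , drop = FALSE])
      imz <- Im(z)
      num <- abs(colMeans(imz, dims = 1))[1, , ]     # freq x time
      den <- colMeans(abs(imz), dims = 1)[1, , ]
      eps <- eps_scale * mean(Mod(z))
      v <- num / den
      bad <- den < eps
      v[bad] <- NA_real_
      n_masked[a, b] <- n_masked[b, a] <- sum(bad)
      w[a, b, , ] <- v
      w[b, a, , ] <- v
    }
  }
  structure(list(wpli = w, n_masked = n_masked, n_trials = d[1],
                 freqs = cube$freqs, times = cube$times,
                 labels = cube$labels),
            class = "wpli_stack")
}

#' Baseline-corrected ("evoked") wPLI
#'
#' Subtracts, per pair and frequency, the mean wPLI over a pre-stimulus
#' baseline window; values may be negative. Pairs whose baseline is fully
#' masked are flagged and left `NA`.
#'
#' @param stack a `wpli_stack`.
#' @param baseline baseline window in seconds (default `c(-0.7, -0.5)`,
#'   i.e., 700-500 ms before trial onset).
#' @return the stack with `wpli` baseline-corrected, plus
#'   `baseline_flagged` (logical pair matrix) and `baseline` recorded.
#' @export
evoked_wpli <- function(stack, baseline = c(-0.7, -0.5)) {
  stopifnot(inherits(stack, "wpli_stack"))
  bidx <- time_indices(stack$times, baseline)
  d <- dim(stack$wpli)
  flagged <- matrix(FALSE, d[1], d[2])
  out <- stack
  for (a in seq_len(d[1] - 1)) {
    for (b in (a + 1):d[2]) {
      bl <- apply(stack$wpli[a, b, , bidx, drop = FALSE], 3, mean,
                  na.rm = TRUE)
      if (all(!is.finite(bl))) {
        flagged[a, b] <- flagged[b, a] <- TRUE
        next
      }
      v <- stack$wpli[a, b, , ] - bl
      out$wpli[a, b, , ] <- v
      out$wpli[b, a, , ] <- v
    }
  }
  out$baseline_flagged <- flagged
  out$baseline <- baseline
  out
}

#' Mean wPLI per pair over a band and time window
#'
#' @param stack a `wpli_stack` (raw or baseline-corrected).
#' @param band frequency band in Hz.
#' @param window time window in seconds.
#' @return symmetric electrodes x electrodes matrix of means (`NA`
#'   diagonal); masked bins are excluded from the average.
#' @export
wpli_band_window <- function(stack, band, window) {
  stopifnot(inherits(stack, "wpli_stack"))
  fidx <- freq_indices(stack$freqs, band)
  tidx <- time_indices(stack$times, window)
  m <- apply(stack$wpli[, , fidx, tidx, drop = FALSE], c(1, 2), mean,
             na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  dimnames(m) <- list(stack$labels, stack$labels)
  m
}

#' Condition contrast of wPLI across sessions
#'
#' Per session, the pairwise wPLI difference between two conditions is
#' averaged over a band x window; the per-pair session means are tested
#' against 0 (two-sided one-sample t) and BH-FDR corrected over the upper
#' triangle of the pair matrix.
#'
#' @param stacks_a,stacks_b lists (one element per session) of `wpli_stack`
#'   objects — or of precomputed symmetric pair-mean matrices, in which case
#'   `band`/`window` are ignored — for the two conditions, same session
#'   order.
#' @param band frequency band in Hz.
#' @param window time window in seconds.
#' @param alpha FDR level (default 0.05).
#' @return list with symmetric pair matrices `mean`, `sem`, `p`, `adj_p`,
#'   logical `mask`, plus `labels` and `session_diffs` (sessions x pairs).
#' @export
wpli_condition_contrast <- function(stacks_a, stacks_b, band, window,
                                    alpha = 0.05) {
  if (length(stacks_a) != length(stacks_b))
    stop("condition stacks must pair up across sessions")
  n_sess <- length(stacks_a)
  if (n_sess < 3) stop("need at least 3 sessions")
  as_pairs <- function(x) {
    if (inherits(x, "wpli_stack")) wpli_band_window(x, band, window) else x
  }
  first <- stacks_a[[1]]
  labels <- if (inherits(first, "wpli_stack")) first$labels
            else rownames(as_pairs(first)) %||%
              paste0("ch", seq_len(nrow(first)))
  n_ch <- length(labels)
  ut <- upper.tri(matrix(0, n_ch, n_ch))
  diffs <- matrix(NA_real_, n_sess, sum(ut))
  for (s in seq_len(n_sess)) {
    da <- as_pairs(stacks_a[[s]])
    db <- as_pairs(stacks_b[[s]])
    diffs[s, ] <- (da - db)[ut]
  }
  if (anyNA(diffs)) diffs[is.na(diffs)] <- 0
  sm <- one_sample_tmap(diffs)
  fd <- fdr_correct(sm$p, q = alpha)
  unfold <- function(v) {
    m <- matrix(NA_real_, n_ch, n_ch, dimnames = list(labels, labels))
    m[ut] <- v
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  mask <- unfold(as.numeric(fd$mask)) == 1
  list(mean = unfold(sm$mean), sem = unfold(sm$sem), p = unfold(sm$p),
       adj_p = unfold(fd$adj_p), mask = mask, labels = labels,
       session_diffs = diffs)
}

#' Threshold a connectivity matrix into network edge lists
#'
#' Edges are pairs whose value meets the threshold AND are significant under
#' the supplied mask; returned per threshold as a weighted edge list (only
#' nodes with degree >= 1 appear). An empty edge list is allowed.
#'
#' @param values symmetric pair matrix (e.g., mean wPLI contrast).
#' @param mask logical significance matrix of the same shape (default: all
#'   significant).
#' @param thresholds numeric vector of thresholds (default `c(0.1, 0.15)`).
#' @param adj_p optional matrix of adjusted p values carried into the edge
#'   list.
#' @return named list (one per threshold) of data frames with columns
#'   `node_a`, `node_b`, `weight` and (if given) `adj_p`.
#' @export
threshold_graph <- function(values, mask = NULL, thresholds = c(0.1, 0.15),
                            adj_p = NULL) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  labels <- rownames(values) %||% paste0("ch", seq_len(nrow(values)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  ut <- which(upper.tri(values), arr.ind = TRUE)
  out <- list()
  for (th in thresholds) {
    keep <- !is.na(values[ut]) & values[ut] >= th & mask[ut]
    sel <- ut[keep, , drop = FALSE]
    edges <- data.frame(node_a = labels[sel[, 1]], node_b = labels[sel[, 2]],
                        weight = values[sel], stringsAsFactors = FALSE)
    if (!is.null(adj_p)) edges$adj_p <- adj_p[sel]
    out[[as.character(th)]] <- edges
  }
  out
}
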