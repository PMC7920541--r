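# Group-level statistics over sessions: one-sample and paired t maps,
# Benjamini-Hochberg FDR over the whole matrix, Bonferroni band summaries,
# and the dual-masked contrast procedure.

# Reshape an array whose first margin is sessions into sessions x bins.
as_session_matrix <- function(stack) {
  d <- dim(stack)
  if (is.null(d)) d <- c(length(stack), 1L)
  list(mat = matrix(stack, d[1]), dim = d[-1])
}

reshape_to <- function(x, dims) {
  if (length(dims) <= 1) as.vector(x) else array(x, dims)
}

#' One-sample t map over sessions
#'
#' Per-bin two-sided one-sample t test of a sessions x bins stack against a
#' null value (default 0, the z-scored no-change null). Zero-variance bins
#' get the smallest representable p value (if their mean differs from the
#' null) and are flagged rather than propagating NaN.
#'
#' @param stack array with sessions as the first margin (e.g., sessions x
#'   times x freqs x electrodes).
#' @param null null-hypothesis value (default 0).
#' @return a `stat_map`: list with `mean`, `sem`, `t`, `p`, `df`,
#'   `n_sessions`, `zero_variance` flags; each field shaped like one session.
#' @export
one_sample_tmap <- function(stack, null = 0) {
  sm <- as_session_matrix(stack)
  n <- nrow(sm$mat)
  if (n < 3) stop("need at least 3 sessions")
  if (any(!is.finite(sm$mat))) stop("stack contains non-finite values")
  m <- colMeans(sm$mat)
  sdv <- apply(sm$mat, 2, stats::sd)
  sem <- sdv / sqrt(n)
  tt <- (m - null) / sem
  p <- 2 * stats::pt(-abs(tt), df = n - 1)
  zv <- sdv == 0
  if (any(zv)) {
    p[zv] <- ifelse(m[zv] == null, 1, .Machine$double.xmin)
    tt[zv] <- ifelse(m[zv] == null, 0, Inf * sign(m[zv] - null))
  }
  structure(list(mean = reshape_to(m, sm$dim), sem = reshape_to(sem, sm$dim),
                 t = reshape_to(tt, sm$dim), p = reshape_to(p, sm$dim),
                 df = n - 1, n_sessions = n,
                 zero_variance = reshape_to(zv, sm$dim)),
            class = "stat_map")
}

#' Paired t map over sessions
#'
#' Two-sided paired t test per bin between two session stacks (e.g., per-
#' session condition-mean ERPs, sessions x times x electrodes), followed by
#' BH-FDR over the whole matrix.
#'
#' @param a,b arrays of equal shape, sessions first.
#' @param q FDR level (default 0.05).
#' @return a `stat_map` with `adj_p` and `mask` fields added.
#' @export
paired_tmap <- function(a, b, q = 0.05) {
  if (!identical(dim(a), dim(b))) stop("paired stacks must share a shape")
  sm <- one_sample_tmap(a - b, null = 0)
  fd <- fdr_correct(sm$p, q = q)
  sm$adj_p <- fd$adj_p
  sm$mask <- fd$mask
  sm
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up BH adjusted p values computed jointly over all supplied bins
#' (whole-matrix correction), independence variant:
#' `adj_p[(i)] = min_{j >= i} ( p[(j)] * m / j )`, capped at 1.
#'
#' @param p numeric vector/array of p values in `[0, 1]`.
#' @param q FDR level for the significance mask (default 0.05).
#' @return list with `adj_p` and logical `mask` (`adj_p < q`), shaped like
#'   `p`.
#' @export
fdr_correct <- function(p, q = 0.05) {
  if (!length(p)) stop("empty p-value input")
  pv <- as.vector(p)
  if (any(!is.finite(pv)) || any(pv < 0 | pv > 1))
    stop("p values must lie in [0, 1]")
  m <- length(pv)
  o <- order(pv)
  ranked <- pv[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  dims <- dim(p)
  adj_p <- if (is.null(dims)) out else array(out, dims)
  list(adj_p = adj_p, mask = adj_p < q)
}

#' Bonferroni adjustment
#'
#' `adj_p = min(1, p * m)`; adjusted values above 1 are set to 1.
#'
#' @param p p values.
#' @param m number of comparisons (default `length(p)`).
#' @return adjusted p values, same shape as `p`.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  stopifnot(m >= 1)
  out <- pmin(1, p * m)
  if (!is.null(dim(p))) dim(out) <- dim(p)
  out
}

#' Dual-masked condition contrast
#'
#' The contrast map `A - B` is reported only at bins that survive
#' whole-matrix FDR correction in BOTH the condition-A-alone test (vs. 0) and
#' the contrast test (vs. 0); all other bins are set to 0.
#'
#' @param maps_a,maps_b session stacks (sessions x times x freqs x
#'   electrodes) for the two conditions, same sessions in the same order.
#' @param alpha FDR level for both masks (default 0.05).
#' @return list with `values` (masked mean contrast), `mask` (joint),
#'   `stat_a`, `stat_contrast` (each a `stat_map` with `adj_p`/`mask`).
#' @export
dual_masked_contrast <- function(maps_a, maps_b, alpha = 0.05) {
  if (!identical(dim(maps_a), dim(maps_b)))
    stop("condition stacks must share a shape")
  contrast <- maps_a - maps_b
  stat_a <- one_sample_tmap(maps_a)
  stat_c <- one_sample_tmap(contrast)
  fa <- fdr_correct(stat_a$p, q = alpha)
  fc <- fdr_correct(stat_c$p, q = alpha)
  stat_a$adj_p <- fa$adj_p; stat_a$mask <- fa$mask
  stat_c$adj_p <- fc$adj_p; stat_c$mask <- fc$mask
  mask <- fa$mask & fc$mask
  values <- stat_c$mean
  values[!mask] <- 0
  list(values = values, mask = mask, stat_a = stat_a, stat_contrast = stat_c)
}

#' Band/window summary table with Bonferroni correction
#'
#' Per-electrode mean, SEM and Bonferroni-adjusted one-sample p value of a
#' sessions x electrodes matrix of band/window means (the layout used for
#' per-region summary tables).
#'
#' @param session_values sessions x electrodes matrix (column names = region
#'   labels).
#' @param m number of comparisons for the Bonferroni adjustment (default the
#'   number of electrodes).
#' @return data frame with columns `region`, `mean`, `sem`, `p`, `adj_p`.
#' @export
band_summary_table <- function(session_values, m = ncol(session_values)) {
  sm <- one_sample_tmap(session_values)
  data.frame(region = colnames(session_values) %||%
               paste0("ch", seq_along(sm$mean)),
             mean = as.vector(sm$mean), sem = as.vector(sm$sem),
             p = as.vector(sm$p),
             adj_p = as.vector(bonferroni_adjust(sm$p, m)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
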