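# Linear support-vector machine, trained by deterministic full-batch
# subgradient descent on the L2-regularized hinge loss (Pegasos-style step
# sizes). Feature counts and sample sizes in this package are small (tens of
# features, ~100 rows), so a dependency-free solver is adequate and keeps
# every split reproducible.

svm_train <- function(X, y, lambda = 0.01, n_iter = 400L) {
  X <- as.matrix(X)
  yy <- ifelse(y > 0, 1, -1)
  n <- nrow(X); k <- ncol(X)
  w <- rep(0, k); b <- 0
  for (t in seq_len(n_iter)) {
    eta <- 1 / (lambda * t)
    margin <- yy * (drop(X %*% w) + b)
    viol <- margin < 1
    gw <- lambda * w
    gb <- 0
    if (any(viol)) {
      gw <- gw - colMeans(X[viol, , drop = FALSE] * yy[viol])
      gb <- -mean(yy[viol])
    }
    w <- w - eta * gw
    b <- b - eta * gb
  }
  list(w = w, b = b, lambda = lambda)
}

svm_predict <- function(model, X) {
  as.numeric(drop(as.matrix(X) %*% model$w + model$b) > 0)
}

# Standardize columns using training statistics only (no test leakage).
standardize_train <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sd <- apply(Xtr, 2, stats::sd)
  sd[sd == 0] <- 1
  list(train = sweep(sweep(Xtr, 2, mu), 2, sd, "/"),
       test = sweep(sweep(Xte, 2, mu), 2, sd, "/"))
}

# k-fold CV accuracy of the SVM on (X, y) for one lambda.
svm_cv_accuracy <- function(X, y, lambda, folds = 10L) {
  n <- nrow(X)
  folds <- min(folds, n)
  fold_id <- rep_len(seq_len(folds), n)[sample.int(n)]
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    te <- fold_id == f
    if (length(unique(y[!te])) < 2) { acc[f] <- NA; next }
    st <- standardize_train(X[!te, , drop = FALSE], X[te, , drop = FALSE])
    m <- svm_train(st$train, y[!te], lambda)
    acc[f] <- mean(svm_predict(m, st$test) == y[te])
  }
  mean(acc, na.rm = TRUE)
}

#' Time-resolved linear SVM decoding
#'
#' At each time point, the rows are split 75/25 into training and test sets;
#' the regularization strength is chosen by 10-fold cross-validation on the
#' training split, the SVM is refit on the full training split, and accuracy
#' is measured on the held-out 25%. The split is redrawn `repeats` times
#' (seeded `seed + repeat`) to give a mean and SEM per time point. Factor
#' importance is the mean absolute weight per feature over the requested
#' window, normalized to sum to 1 (features are standardized within training
#' folds, so importance is invariant to feature scaling).
#'
#' @param x rows x features x times feature array.
#' @param y binary labels.
#' @param times time axis (seconds), length = `dim(x)[3]`.
#' @param split training fraction (default 0.75).
#' @param folds folds for internal cross-validation (default 10).
#' @param repeats number of random splits (default 10).
#' @param lambda_grid candidate regularization strengths.
#' @param importance_window time window (seconds) over which factor
#'   importance is aggregated (default `c(0.5, 0.9)`).
#' @param seed integer seed for the splits.
#' @return list with `accuracy` (mean per time point), `sem`, `times`,
#'   `importance` (per feature, sums to 1), `imbalance` (label imbalance
#'   fraction).
#' @export
svm_timecourse <- function(x, y, times, split = 0.75, folds = 10L,
                           repeats = 10L,
                           lambda_grid = c(0.001, 0.01, 0.1),
                           importance_window = c(0.5, 0.9), seed = 1) {
  d <- dim(x)
  stopifnot(length(d) == 3, d[1] == length(y), d[3] == length(times))
  if (min(table(y)) < 4) stop("need at least 4 rows per class")
  imbalance <- abs(mean(y) - 0.5)
  if (imbalance > 0.15)
    warning("labels are imbalanced (", round(mean(y), 2), " positive)")
  n <- d[1]
  acc <- matrix(NA_real_, repeats, d[3])
  wsum <- matrix(0, d[2], d[3])
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    tr <- sort(sample.int(n, round(split * n)))
    te <- setdiff(seq_len(n), tr)
    for (ti in seq_len(d[3])) {
      Xtr <- x[tr, , ti, drop = TRUE]
      Xte <- x[te, , ti, drop = TRUE]
      if (is.null(dim(Xtr))) { Xtr <- matrix(Xtr, ncol = d[2])
                               Xte <- matrix(Xte, ncol = d[2]) }
      cvacc <- vapply(lambda_grid, function(l)
        svm_cv_accuracy(Xtr, y[tr], l, folds), numeric(1))
      lambda <- lambda_grid[which.max(cvacc)]
      st <- standardize_train(Xtr, Xte)
      m <- svm_train(st$train, y[tr], lambda)
      acc[r, ti] <- mean(svm_predict(m, st$test) == y[te])
      wsum[, ti] <- wsum[, ti] + abs(m$w)
    }
  }
  in_win <- times >= importance_window[1] & times <= importance_window[2]
  if (!any(in_win)) in_win <- rep(TRUE, length(times))
  imp <- rowMeans(wsum[, in_win, drop = FALSE]) / repeats
  if (sum(imp) > 0) imp <- imp / sum(imp)
  list(accuracy = colMeans(acc), sem = apply(acc, 2, stats::sd) / sqrt(repeats),
       times = times, importance = imp, imbalance = imbalance)
}
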