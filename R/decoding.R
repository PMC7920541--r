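# Decoding of wait-trial outcome (patient vs. impulsive) from theta power
# and theta wPLI: behavioral d-prime, univariate and multivariate logistic
# regression, and a time-resolved linear SVM.

#' Signal-detection sensitivity d-prime
#'
#' `d' = qnorm(hit_rate) - qnorm(fa_rate)`, plus the scaled variant
#' `d' / scale` (default scale 4.65, the theoretical maximum, mapping d' to
#' the 0-1 range). Rates of exactly 0 or 1 are clipped to `1/(2n)` /
#' `1 - 1/(2n)` with a warning; `n` is then required.
#'
#' @param hit_rate,fa_rate hit and false-alarm rates in `[0, 1]`.
#' @param scale divisor for the scaled d-prime (default 4.65).
#' @param n number of trials underlying each rate, used only for clipping.
#' @return list with `dprime` and `scaled`.
#' @export
dprime <- function(hit_rate, fa_rate, scale = 4.65, n = NULL) {
  clip <- function(r) {
    if (r <= 0 || r >= 1) {
      if (is.null(n)) stop("rate of 0 or 1 requires n for the 1/(2n) clip")
      warning("rate clipped to the 1/(2n) convention")
      r <- min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))
    }
    r
  }
  hit_rate <- clip(hit_rate); fa_rate <- clip(fa_rate)
  d <- stats::qnorm(hit_rate) - stats::qnorm(fa_rate)
  list(dprime = d, scaled = d / scale)
}

# Logistic fit of a binary outcome on a design matrix, with a ridge-penalized
# IRLS fallback when the fit (quasi-)separates. The fallback standardizes the
# features and applies a unit ridge to the slopes (a weakly informative
# Gaussian prior), which keeps Wald inference usable where the unpenalized
# MLE diverges; coefficients are reported on the original feature scale.
# Returns per-feature coefficients, SEs, Wald p values and a separation flag.
logistic_fit <- function(X, y, ridge = 1) {
  X <- as.matrix(X)
  df <- data.frame(y = y, X)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear feature(s): ",
         paste(bad, collapse = ", "))
  }
  # quasi-separation: glm only warns in the most extreme cases, but Wald
  # inference already degrades (Hauck-Donner) once fitted probabilities pin
  # to 0/1; fall back to the ridge fit when the linear predictor explodes,
  # or (single-feature fits) when the Wald p has collapsed relative to the
  # likelihood-ratio p - the Hauck-Donner signature
  if (max(abs(stats::predict(fit, type = "link"))) > 10) separated <- TRUE
  if (!separated && ncol(X) == 1) {
    lrt_p <- stats::pchisq(fit$null.deviance - fit$deviance, df = 1,
                           lower.tail = FALSE)
    wald_p <- summary(fit)$coefficients[2, 4]
    if (lrt_p * 10 < wald_p) separated <- TRUE
  }
  if (!separated) {
    sm <- summary(fit)$coefficients
    ll0 <- stats::logLik(stats::glm(y ~ 1, data = df,
                                    family = stats::binomial()))
    r2 <- 1 - as.numeric(stats::logLik(fit)) / as.numeric(ll0)
    return(list(beta = sm[-1, 1], se = sm[-1, 2], p = sm[-1, 4],
                intercept = sm[1, 1], pseudo_r2 = r2, separated = FALSE))
  }
  # ridge-penalized IRLS on standardized features (penalty on slopes only)
  mu_x <- colMeans(X)
  sd_x <- apply(X, 2, stats::sd)
  sd_x[sd_x == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu_x), 2, sd_x, "/")
  Xd <- cbind(1, Xs)
  k <- ncol(Xd)
  pen <- diag(c(0, rep(ridge, k - 1)))
  beta <- rep(0, k)
  for (it in 1:200) {
    eta <- drop(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xd, Xd * w) + pen
    g <- crossprod(Xd, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  se <- sqrt(diag(solve(H)))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  mu <- 1 / (1 + exp(-drop(Xd %*% beta)))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  r2 <- 1 - ll / ll0
  # map slopes and SEs back to the original feature scale
  list(beta = beta[-1] / sd_x, se = se[-1] / sd_x, p = p[-1],
       intercept = beta[1] - sum(beta[-1] * mu_x / sd_x),
       pseudo_r2 = r2, separated = TRUE)
}

#' Build an outcome dataset from per-session condition summaries
#'
#' Stacks per-session feature summaries for the two wait-trial outcome
#' conditions into the two-rows-per-session design used by all decoding
#' models (label 1 = patient/correct, 0 = impulsive/incorrect).
#'
#' @param correct,incorrect matrices or arrays with sessions as the first
#'   margin (features in the remaining margins), one per outcome condition.
#' @return list with `x` (rows = 2 x sessions, remaining margins =
#'   features), `y` (binary labels) and `session` ids.
#' @export
outcome_dataset <- function(correct, incorrect) {
  if (!identical(dim(correct), dim(incorrect)))
    stop("condition summaries must share a shape")
  dc <- dim(correct)
  n <- dc[1]
  x <- abind_first(correct, incorrect)
  list(x = x, y = c(rep(1, n), rep(0, n)), session = rep(seq_len(n), 2))
}

# Bind two arrays along the first margin.
abind_first <- function(a, b) {
  da <- dim(a)
  ma <- matrix(a, da[1]); mb <- matrix(b, da[1])
  out <- rbind(ma, mb)
  array(out, c(2 * da[1], da[-1]))
}

#' Univariate outcome regression per electrode and time
#'
#' Logistic regression of wait-trial outcome on a single band-power feature,
#' fitted independently at every electrode x time point, with BH-FDR over
#' the full electrode x time matrix. Constant features get beta = 0, p = 1.
#'
#' @param x rows x electrodes x times feature array (rows = session x
#'   condition, see [outcome_dataset()]).
#' @param y binary outcome labels (1 = patient/correct).
#' @param q FDR level (default 0.05).
#' @return list of electrode x time matrices `beta`, `p`, `adj_p`, `mask`,
#'   `separated`.
#' @export
univariate_outcome_regression <- function(x, y, q = 0.05) {
  d <- dim(x)
  stopifnot(length(d) == 3, d[1] == length(y))
  if (length(unique(y)) < 2) stop("outcome labels are constant")
  if (d[1] < 10) warning("fewer than 10 rows; estimates will be unstable")
  beta <- p <- matrix(NA_real_, d[2], d[3])
  sep <- matrix(FALSE, d[2], d[3])
  for (e in seq_len(d[2])) {
    for (t in seq_len(d[3])) {
      f <- x[, e, t]
      if (stats::sd(f) == 0) {
        beta[e, t] <- 0; p[e, t] <- 1
        next
      }
      fit <- logistic_fit(matrix(f, ncol = 1), y)
      beta[e, t] <- fit$beta
      p[e, t] <- fit$p
      sep[e, t] <- fit$separated
    }
  }
  fd <- fdr_correct(p, q = q)
  list(beta = beta, p = p, adj_p = fd$adj_p, mask = fd$mask, separated = sep)
}

#' Pairwise wPLI outcome regression
#'
#' Logistic regression of wait-trial outcome on window-averaged evoked wPLI,
#' fitted per channel pair, BH-FDR corrected over the upper triangle of the
#' pair matrix.
#'
#' @param x rows x electrodes x electrodes array of pair features (rows =
#'   session x condition).
#' @param y binary outcome labels.
#' @param q FDR level (default 0.05).
#' @param labels optional channel labels.
#' @return list of symmetric pair matrices `beta`, `p`, `adj_p`, `mask`,
#'   `separated`.
#' @export
wpli_outcome_regression <- function(x, y, q = 0.05, labels = NULL) {
  d <- dim(x)
  stopifnot(length(d) == 3, d[2] == d[3], d[1] == length(y))
  n_ch <- d[2]
  labels <- labels %||% paste0("ch", seq_len(n_ch))
  ut <- which(upper.tri(matrix(0, n_ch, n_ch)), arr.ind = TRUE)
  beta_v <- p_v <- rep(NA_real_, nrow(ut))
  sep_v <- logical(nrow(ut))
  for (k in seq_len(nrow(ut))) {
    f <- x[, ut[k, 1], ut[k, 2]]
    if (anyNA(f) || stats::sd(f) == 0) {
      beta_v[k] <- 0; p_v[k] <- 1
      next
    }
    fit <- logistic_fit(matrix(f, ncol = 1), y)
    beta_v[k] <- fit$beta; p_v[k] <- fit$p; sep_v[k] <- fit$separated
  }
  fd <- fdr_correct(p_v, q = q)
  unfold <- function(v, fill = NA) {
    m <- matrix(fill, n_ch, n_ch, dimnames = list(labels, labels))
    m[cbind(ut[, 1], ut[, 2])] <- v
    m[cbind(ut[, 2], ut[, 1])] <- v
    m
  }
  list(beta = unfold(beta_v), p = unfold(p_v), adj_p = unfold(fd$adj_p),
       mask = unfold(fd$mask, FALSE), separated = unfold(sep_v, FALSE))
}

#' Multivariate seed-connectivity outcome model
#'
#' Multivariate logistic regression of wait-trial outcome on the wPLI from a
#' seed region to every other region. Positive coefficients mean higher
#' connectivity predicts the patient (correct) outcome. Reports McFadden's
#' pseudo-R-squared.
#'
#' @param x rows x features matrix (seed-to-other connectivity values).
#' @param y binary outcome labels.
#' @return list with `beta`, `se`, `p`, `pseudo_r2`, `separated`.
#' @export
multivariate_connectivity_model <- function(x, y) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y))
  if (nrow(x) < 3 * ncol(x))
    warning("fewer than 3 rows per feature; coefficients will be unstable")
  fit <- logistic_fit(x, y)
  nm <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  names(fit$beta) <- names(fit$se) <- names(fit$p) <- nm
  fit
}
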