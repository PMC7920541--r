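# wPLI estimation, baseline correction, condition contrasts, graphs.

test_that("constant non-zero lag gives wPLI exactly 1, any amplitudes", {
  set.seed(20)
  ph <- stats::runif(50, 0, 2 * pi)
  amps_a <- stats::runif(50, 0.5, 4)
  amps_b <- stats::runif(50, 0.5, 4)
  w <- wpli(phase_cube(ph, ph - pi / 2, amps_a, amps_b))
  expect_equal(w$wpli[1, 2, 1, 1], 1)
  expect_identical(w$wpli[1, 2, 1, 1], w$wpli[2, 1, 1, 1])
  expect_true(is.na(w$wpli[1, 1, 1, 1]))   # diagonal undefined
})

test_that("independent random phases give near-zero wPLI", {
  set.seed(21)
  w <- wpli(phase_cube(stats::runif(1e4, 0, 2 * pi),
                       stats::runif(1e4, 0, 2 * pi)))
  expect_lt(w$wpli[1, 2, 1, 1], 0.05)
})

test_that("identical channels (zero lag) are masked as undefined", {
  set.seed(22)
  ph <- stats::runif(100, 0, 2 * pi)
  w <- wpli(phase_cube(ph, ph))
  expect_true(is.na(w$wpli[1, 2, 1, 1]))
  expect_gt(w$n_masked[1, 2], 0)
  expect_error(wpli(phase_cube(1, 2)), "2 trials")
})

test_that("wPLI estimates tighten with trial count (consistency)", {
  set.seed(23)
  est <- function(n) {
    jit <- rvonmises(n, 0, 2)
    ph <- stats::runif(n, 0, 2 * pi)
    w <- wpli(phase_cube(ph, ph - pi / 2 - jit))
    w$wpli[1, 2, 1, 1]
  }
  sd_small <- stats::sd(replicate(30, est(50)))
  sd_big <- stats::sd(replicate(30, est(400)))
  expect_lt(sd_big, sd_small)
})

test_that("baseline correction zeroes stationary coupling and keeps
           post-stimulus-only coupling positive", {
  fx <- fx_session()
  keep <- fx$cube$events$trial_type == "wait" &
    fx$cube$events$outcome == "correct"
  st <- wpli(fx$cube, trials = keep)
  ev <- evoked_wpli(st, baseline = c(-0.7, -0.5))
  i <- match("M1", st$labels); j <- match("vOFC", st$labels)
  coupled <- wpli_band_window(ev, c(4, 7), c(0.8, 1.7))[i, j]
  expect_gt(coupled, 0.15)
  # uncoupled noise-only pairs: evoked wPLI fluctuates around zero with
  # ~1/sqrt(n_trials) spread (about 0.3 at a dozen trials), so the sharp
  # statement is relative: each stays well below the planted pair
  un <- rbind(c("M2", "A24b"), c("ALM", "M2"), c("ALM", "A24b"))
  bw <- wpli_band_window(ev, c(4, 7), c(0.8, 1.7))
  uncoupled <- mapply(function(a, b) bw[match(a, st$labels),
                                        match(b, st$labels)],
                      un[, 1], un[, 2])
  expect_lt(max(abs(uncoupled)), coupled)
  expect_lt(mean(abs(uncoupled)), 0.15)
  expect_error(evoked_wpli(st, baseline = c(-5, -4)), "window")
})

test_that("condition contrast is null when conditions are identical and
           FDR runs over the upper triangle", {
  fx <- fx_session()
  st <- wpli(fx$cube)
  ms <- lapply(1:4, function(i) wpli_band_window(st, c(4, 7), c(0.5, 2)))
  res <- wpli_condition_contrast(ms, ms, c(4, 7), c(0.5, 2))
  expect_true(all(res$mean[upper.tri(res$mean)] == 0))
  expect_false(any(res$mask, na.rm = TRUE))
  expect_error(wpli_condition_contrast(ms[1:2], ms[1:2], c(4, 7), c(0.5, 2)),
               "3 sessions")
})

test_that("submatrix FDR keeps the pairs found by whole-matrix FDR when the
           selected regions carry all the signal", {
  # the selected-subset use case: all small p values live inside the subset
  set.seed(24)
  p_full <- matrix(stats::runif(32 * 32, 0.2, 1), 32)
  sig <- cbind(sample(11, 6), sample(11, 6))
  p_full[sig] <- stats::runif(6, 1e-6, 1e-3)
  ut <- upper.tri(p_full)
  full_mask <- fdr_correct(p_full[ut])$mask
  sub <- p_full[1:11, 1:11]
  sub_mask <- fdr_correct(sub[upper.tri(sub)])$mask
  # map: every full-matrix discovery inside the subset is a subset discovery
  full_m <- matrix(FALSE, 32, 32); full_m[ut] <- full_mask
  sub_m <- matrix(FALSE, 11, 11); sub_m[upper.tri(sub_m)] <- sub_mask
  inside <- full_m[1:11, 1:11] & upper.tri(sub_m)
  expect_true(all(sub_m[inside]))
})

test_that("graph thresholding nests, matches brute force and allows empty", {
  vals <- matrix(c(NA, 0.2, 0.05, 0.12,
                   0.2, NA, 0.3, 0.08,
                   0.05, 0.3, NA, 0.16,
                   0.12, 0.08, 0.16, NA), 4,
                 dimnames = list(letters[1:4], letters[1:4]))
  mask <- matrix(TRUE, 4, 4); mask[1, 4] <- mask[4, 1] <- FALSE
  g <- threshold_graph(vals, mask, thresholds = c(0.1, 0.15))
  # brute force at 0.1: pairs (a,b)=.2, (b,c)=.3, (c,d)=.16; (a,d) masked out
  e1 <- g[["0.1"]]
  expect_setequal(paste(e1$node_a, e1$node_b),
                  c("a b", "b c", "c d"))
  e2 <- g[["0.15"]]
  expect_true(all(paste(e2$node_a, e2$node_b) %in%
                    paste(e1$node_a, e1$node_b)))
  empty <- threshold_graph(vals, mask, thresholds = 0.9)
  expect_equal(nrow(empty[["0.9"]]), 0)
})

test_that("a zero-lag common source raises amplitude correlation but barely
           moves wPLI of uncoupled pairs", {
  # Monte-Carlo at the coefficient level: X = N1 + g*S, Y = N2 + g*S with
  # S, N1, N2 independent complex Gaussians (S shared with zero lag)
  set.seed(25)
  n <- 5000
  cgauss <- function(n) complex(real = stats::rnorm(n),
                                imaginary = stats::rnorm(n))
  n1 <- cgauss(n); n2 <- cgauss(n); s <- cgauss(n)
  w0 <- wpli(phase_cube(Arg(n1), Arg(n2), Mod(n1), Mod(n2)))
  x <- n1 + 2 * s; y <- n2 + 2 * s
  expect_gt(stats::cor(Mod(x), Mod(y)), 0.5)
  w1 <- wpli(phase_cube(Arg(x), Arg(y), Mod(x), Mod(y)))
  expect_lt(abs(w1$wpli[1, 2, 1, 1] - w0$wpli[1, 2, 1, 1]), 0.05)
})
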