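# Morlet decomposition, evoked power, session maps, band means, ERPs.

test_that("pure tones are recovered with unit gain at the nearest bin", {
  rec <- tone_recording(10, amplitude = 2)
  ep <- epoch(rec, simple_events(c(5, 10, 15)), "stimulus", c(-2, 2))
  cube <- wavelet_transform(ep, f_min = 2, f_max = 40, n_freqs = 39,
                            n_times = 50)
  amp <- Mod(cube$coef)
  bin <- which.min(abs(cube$freqs - 10))
  peak <- mean(amp[1, 1, bin, ])
  expect_lt(abs(peak - 2) / 2, 0.05)
  # the peak frequency is the tone's bin
  prof <- apply(amp[, 1, , , drop = FALSE], 3, mean)
  expect_equal(which.max(prof), bin)
  # other channel carries nothing
  expect_lt(max(amp[, 2, , ]), 1e-8)
})

test_that("the transform is linear in signal amplitude", {
  set.seed(2)
  data <- array(stats::rnorm(2 * 1 * 3000), c(2, 1, 3000))
  ep1 <- make_epochs(data)
  ep3 <- make_epochs(3 * data)
  c1 <- wavelet_transform(ep1, 2, 30, 8, n_times = 20)
  c3 <- wavelet_transform(ep3, 2, 30, 8, n_times = 20)
  expect_equal(Mod(c3$coef), 3 * Mod(c1$coef), tolerance = 1e-10)
})

test_that("default configuration yields the 200 x 139 grid", {
  data <- array(stats::rnorm(2 * 1 * 7000), c(2, 1, 7000))
  ep <- make_epochs(data, window = c(-2, 5))
  cube <- wavelet_transform(ep)            # defaults: 2-70 Hz, 139, 200
  expect_equal(dim(cube$coef), c(2, 1, 139, 200))
  expect_equal(length(cube$freqs), 139)
  expect_equal(range(cube$freqs), c(2, 70))
  expect_equal(length(cube$times), 200)
  # grids strictly increasing, interior excludes the wavelet support
  expect_true(all(diff(cube$times) > 0) && all(diff(cube$freqs) > 0))
  expect_gte(cube$times[1], -2 + 3 * 2 / (2 * pi * 2))
})

test_that("frequency above Nyquist and too-short epochs are errors", {
  data <- array(0, c(2, 1, 3000))
  ep <- make_epochs(data)
  expect_error(wavelet_transform(ep, f_max = 600), "Nyquist")
  short <- make_epochs(array(0, c(2, 1, 500)))
  expect_error(wavelet_transform(short, f_min = 2, f_max = 30, n_freqs = 5),
               "support")
})

test_that("a planted burst is localized within one wavelet temporal SD", {
  fs <- 1000
  t <- seq(0, 3.999, by = 1 / fs)
  center <- 2.0
  sig <- exp(-0.5 * ((t - center) / 0.15)^2) * sin(2 * pi * 10 * t)
  data <- array(0, c(2, 1, length(t)))
  data[1, 1, ] <- sig; data[2, 1, ] <- sig
  ep <- make_epochs(data, window = c(0, 4))
  cube <- wavelet_transform(ep, 2, 30, 15, n_times = 150)
  bin <- which.min(abs(cube$freqs - 10))
  prof <- Mod(cube$coef[1, 1, bin, ])
  t_peak <- cube$times[which.max(prof)]
  sigma_t <- oscnet:::wavelet_sigma_t(cube, cube$freqs[bin])
  expect_lt(abs(t_peak - center), sigma_t + 0.15)
})

test_that("zero signal gives zero amplitude everywhere", {
  ep <- make_epochs(array(0, c(2, 2, 3000)))
  cube <- wavelet_transform(ep, 2, 30, 8, n_times = 20)
  expect_equal(max(Mod(cube$coef)), 0)
})

test_that("evoked power is near zero for stationary signals and positive
           inside a planted burst", {
  fx <- fx_session()
  cube <- fx$cube
  ev <- evoked_power(cube, baseline = c(-1, -0.75))
  go <- cube$events$trial_type == "go"
  bin_d <- which(cube$freqs >= 2 & cube$freqs <= 4)
  tin <- which(cube$times >= 0.33 & cube$times <= 0.47)
  tout <- which(cube$times <= -0.5)
  m1 <- match("M1", cube$labels)
  # the 0.2 s Hann burst of amplitude 2 is diluted by the taper, wavelet
  # smoothing and median referencing; what must hold is a clear positive
  # evoked response inside the planted window and near-zero outside
  inside <- mean(ev[go, m1, bin_d, tin])
  outside <- mean(ev[go, m1, bin_d, tout])
  expect_gt(inside, 0.1)
  expect_lt(abs(outside), inside / 3)
  expect_error(evoked_power(cube, baseline = c(-3, -2.5)), "baseline")
})

test_that("per-condition baseline grouping reduces to the pooled baseline
           when groups are statistically identical", {
  fx <- fx_session()
  cube <- fx$cube
  pooled <- evoked_power(cube, baseline = c(-1, -0.75))
  # one group: identical to pooled by definition
  one <- evoked_power(cube, baseline = c(-1, -0.75),
                      groups = factor(rep("a", dim(cube$coef)[1])))
  expect_equal(one, pooled)
  # distinct groups shift each trial by its own condition baseline
  grp <- factor(cube$events$trial_type)
  split <- evoked_power(cube, baseline = c(-1, -0.75), groups = grp)
  expect_false(identical(split, pooled))
})

test_that("conditions without trials are omitted with a warning", {
  set.seed(7)
  data <- array(stats::rnorm(4 * 2 * 3000), c(4, 2, 3000))
  ev <- simple_events(seq_len(4) * 10, type = "go", outcome = "correct")
  ep <- make_epochs(data, window = c(-1.5, 1.5), events = ev)
  cube <- wavelet_transform(ep, 2, 20, 10, n_times = 40)
  expect_warning(maps <- session_maps(cube, baseline = c(-1, -0.75)),
                 "wait-correct")
  expect_named(maps, "go-correct")
})

test_that("session maps are z-scored per electrode and frequency", {
  maps <- session_maps(fx_session()$cube, baseline = c(-1, -0.75))
  expect_named(maps, c("go-correct", "wait-correct", "wait-incorrect"))
  m <- maps[["go-correct"]]
  mu <- apply(unclass(m), c(2, 3), mean)
  sd <- apply(unclass(m), c(2, 3), stats::sd)
  expect_lt(max(abs(mu)), 1e-10)
  expect_lt(max(abs(sd - 1)), 1e-10)
})

test_that("planted go-delta activity separates conditions in the maps", {
  fx <- fx_session()
  maps <- session_maps(fx$cube, baseline = c(-1, -0.75))
  ci <- core_bins(fx$cube$times, fx$cube$freqs, c(1, 4), c(0.3, 0.5))
  m1 <- match("M1", fx$cube$labels)
  go_val <- mean(maps[["go-correct"]][ci$tidx, ci$fidx, m1])
  wait_val <- mean(maps[["wait-correct"]][ci$tidx, ci$fidx, m1])
  expect_gt(go_val, wait_val)
  expect_gt(go_val, 1)
})

test_that("identical trials in two conditions give identical maps", {
  set.seed(6)
  data <- array(stats::rnorm(4 * 2 * 3000), c(4, 2, 3000))
  data[3:4, , ] <- data[1:2, , ]
  ev <- simple_events(seq_len(4) * 10, type = c("go", "go", "wait", "wait"),
                      outcome = "correct")
  ev$response_time_s <- c(0.6, 0.6, 2.5, 2.5)
  ep <- make_epochs(data, window = c(-1.5, 1.5), events = ev)
  cube <- wavelet_transform(ep, 2, 20, 10, n_times = 40)
  maps <- session_maps(cube, c("go-correct", "wait-correct"),
                       baseline = c(-1, -0.75))
  expect_equal(unclass(maps[[1]]), unclass(maps[[2]]), ignore_attr = TRUE)
})

test_that("band/window means reduce to brute-force bin averages", {
  tfe <- array(5, c(10, 6, 3))
  attr(tfe, "times") <- seq(0, 0.9, by = 0.1)
  attr(tfe, "freqs") <- seq(2, 12, by = 2)
  attr(tfe, "labels") <- c("a", "b", "c")
  expect_equal(unname(band_window_mean(tfe, c(4, 7), c(0.3, 0.5))),
               rep(5, 3))
  # checkerboard
  chk <- array(0, c(10, 6, 3))
  chk[] <- (slice.index(chk, 1) + slice.index(chk, 2)) %% 2
  attributes(chk)[c("times", "freqs", "labels")] <-
    attributes(tfe)[c("times", "freqs", "labels")]
  tidx <- which(attr(tfe, "times") >= 0.2 & attr(tfe, "times") <= 0.61)
  fidx <- which(attr(tfe, "freqs") >= 4 & attr(tfe, "freqs") <= 7)
  brute <- apply(chk[tidx, fidx, , drop = FALSE], 3, mean)
  expect_equal(unname(band_window_mean(chk, c(4, 7), c(0.2, 0.61))), brute)
  expect_error(band_window_mean(tfe, c(40, 50), c(0, 1)), "band|frequencies")
})

test_that("ERPs: identical trials give zero SEM and DC offsets are removed", {
  data <- array(stats::rnorm(1 * 2 * 2000), c(1, 2, 2000))
  data <- data[rep(1, 4), , , drop = FALSE] + 10   # 4 identical trials + DC
  ev <- simple_events(seq_len(4) * 10)
  ep <- make_epochs(data, window = c(-1.5, 0.5), events = ev)
  expect_warning(erp <- compute_erp(ep, "go-correct", band = c(0.3, 900),
                                    baseline = c(-1.4, -1)),
                 "Nyquist")
  expect_lt(max(abs(erp[["go-correct"]]$sem)), 1e-10)
  expect_lt(abs(mean(erp[["go-correct"]]$mean)), 0.5)  # DC gone
})
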