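# Independent oracles shared across test files. These deliberately avoid the
# package's own code paths (apart from trivial constructors) so that
# implementation and oracle stay decoupled.

# Brute-force Benjamini-Hochberg oracle: adjusted p from the step-up
# definition, adj_p[(i)] = min_{j >= i} p[(j)] * m / j, via explicit loops.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    adj[o[i]] <- min(1, min(vals))
  }
  adj
}

# Build a tf_cube directly from per-trial phases/amplitudes on two channels,
# for analytic wPLI cases (unit grids unless stated).
phase_cube <- function(phase_a, phase_b, amp_a = 1, amp_b = 1,
                       n_freqs = 1, n_times = 1) {
  n <- length(phase_a)
  coef <- array(complex(real = 0), c(n, 2, n_freqs, n_times))
  coef[, 1, , ] <- amp_a * exp(1i * phase_a)
  coef[, 2, , ] <- amp_b * exp(1i * phase_b)
  structure(list(coef = coef, freqs = seq(4, length.out = n_freqs),
                 times = seq(0, length.out = n_times, by = 0.1),
                 labels = c("x", "y"),
                 events = simple_events(seq_len(n) * 10), fs = 1000,
                 cycles = c(2, 0.7), f_min = 2),
            class = "tf_cube")
}
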