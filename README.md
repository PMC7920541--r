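# oscnet

Mapping action- and inhibition-related brain networks from multisite local
field potentials (LFPs) recorded during a go/wait (action-postponement)
task — as a tested, reusable R pipeline.

## Who this is for

Systems-neuroscience labs recording LFP from many sites at once (or anyone
with multichannel time series plus a trial event table) who want the
standard analysis chain for task-evoked oscillations and functional
connectivity:

1. **Preprocessing** — event-locked epoching (`[-2, 5)` s windows),
   single-pass `mean + 4·SD` artifact rejection, cross-channel median
   referencing.
2. **Spectral analysis** — Morlet wavelet decomposition (2–70 Hz, 139
   frequencies, cycles `(2, 0.7)`), baseline-normalized evoked amplitude,
   per-condition session maps z-scored over time (the
   `200 × 139 × 32` time × frequency × electrode session matrix under
   defaults), event-related potentials.
3. **Statistics** — one-sample and paired t maps across sessions with
   Benjamini–Hochberg FDR over the whole matrix, Bonferroni band summaries,
   and the *dual-masked contrast*: a condition difference reported only at
   bins significant both for the contrast and for the single condition
   alone.
4. **Connectivity** — weighted phase-lag index per channel pair,

   wPLI = |E[Im Z]| / E[|Im Z|],  Z = X·conj(Y) per trial,

   which suppresses zero-lag (volume-conducted) coupling; baseline-corrected
   ("evoked") wPLI, condition contrasts with FDR over the pair matrix, and
   thresholded network graphs (edges at wPLI ≥ 0.1 / 0.15 and significant).
5. **Decoding** — behavioral d′ = z(hits) − z(false alarms) (scaled by the
   4.65 theoretical maximum); logistic regression of wait-trial outcome
   (patient vs. impulsive) on theta power per electrode and on pairwise
   theta wPLI; a multivariate seed-region connectivity model (McFadden
   pseudo-R²); and a time-resolved linear SVM (75/25 split, 10-fold CV,
   10 repeats) with factor importance, run at theta with a matched
   beta-band control.
6. **Synthetic sessions** — a first-class generator
   (`session_config()` / `generate_session()`) that emulates the task's
   event statistics (25/75 go–wait mix, ~272 trials, lognormal go RTs with
   588 ms median, bimodal wait RTs at 1263/2513 ms), 1/f background noise,
   planted band-limited bursts, planted von Mises phase-coupled pairs with
   controllable wPLI, whole-trial artifacts and a zero-lag common-source
   confound — so the entire pipeline is testable without any recording.

## Worked example

Simulate a small multi-session world with a planted go-delta motor network,
a wait-theta inhibition network and outcome-dependent M1–vOFC theta
coupling, then run the full pipeline:

```r
library(oscnet)

tmpl <- session_config(
  n_channels = 16, n_trials = 40, seed = 1,
  burst_specs = list(
    planted_effect(c("M1", "ALM", "A33"), band = c(1, 4),
                   window = c(0.3, 0.5), amplitude = 2, condition = "go"),
    planted_effect(c("A32D", "vOFC", "NAcC"), band = c(4, 7),
                   window = c(0.5, 2), amplitude = 2, condition = "wait")),
  coupling_specs = list(
    planted_coupling(c("M1", "vOFC"), band = c(4, 7), window = c(0.5, 2),
                     kappa = 0.9, amplitude = 2,
                     condition = "wait-correct"),
    planted_coupling(c("M1", "vOFC"), band = c(4, 7), window = c(0.5, 2),
                     kappa = 0, amplitude = 2,
                     condition = "wait-incorrect")))

cfg <- run_config(tmpl, n_sessions = 8, seed = 11,
                  epoch_window = c(-1.5, 2.6),   # scaled-down analysis grid
                  f_max = 30, n_freqs = 29, n_times = 80)
bundle <- run_all(cfg)
report <- make_report(bundle)
head(report$delta_table, 3)
#>   region      mean       sem            p        adj_p
#> 1     M1 3.5176296 0.1494849 6.356681e-08 1.017069e-06
#> 2   vOFC 0.7177033 0.3235292 6.202745e-02 9.924391e-01
#> 3   A32D 1.2907384 0.1302283 2.268695e-05 3.629911e-04

bundle$connectivity$graphs[["0.1"]]
#>   node_a node_b    weight       adj_p
#> 1     M1   vOFC 0.7223664 0.002494549
```

The table is the per-region go–wait delta contrast, averaged 0.3–0.5 s and
1–4 Hz: `mean`/`sem` are in z units across sessions and `adj_p` is
Bonferroni-adjusted over regions — the planted motor channel M1 is strongly
positive and significant. (A32D is also positive: its planted *wait* theta
leaks into the 4 Hz bin, and z-scoring over time pushes the pre-burst window
negative on wait trials — exactly the kind of indirect effect the
dual-masked contrast, which additionally requires go-alone significance, is
designed to screen out.) The graph output is the thresholded,
significant wait–go theta network: exactly the planted M1–vOFC edge.
`bundle$stats$go_vs_wait$values` holds the dual-masked contrast map, and
`bundle$decoding$pairwise` tests which channel pairs' theta wPLI predicts
wait-trial outcome (at this 8-session scale the planted pair has the
smallest p; ~20 sessions are needed for it to survive whole-matrix FDR, as
the acceptance suite demonstrates).

Single stages compose the same way outside `run_all()`:

```r
sess <- generate_session(tmpl)
ep   <- epoch(sess$recording, sess$events, "stimulus", c(-2, 5))
ep   <- median_reference(reject_artifacts(ep, k = 4)$epochs)
cube <- wavelet_transform(ep)                  # defaults: 2-70 Hz, 139, 200
maps <- session_maps(cube)                     # z-scored TFE per condition
w    <- evoked_wpli(wpli(cube), baseline = c(-0.7, -0.5))
```

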