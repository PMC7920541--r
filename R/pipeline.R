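# End-to-end orchestration: simulate (or load) sessions, preprocess,
# time-frequency decompose, accumulate session-level maps and connectivity,
# run the group statistics and the outcome decoding, and assemble a results
# bundle with a provenance manifest.

#' Analysis configuration with the pipeline's default parameters
#'
#' Defaults: epoch window `[-2, 5)` s; rejection threshold k = 4; Morlet
#' decomposition 2-70 Hz, 139 frequencies, 200 time points, cycles (2, 0.7);
#' power baseline `[-1, -0.75]` s; wPLI baseline `[-0.7, -0.5]` s; delta
#' band 1-4 Hz summarized 0.3-0.5 s; theta band 4-7 Hz summarized 0.5-2 s;
#' decoding window 0.5-0.9 s; alpha 0.05; graph thresholds 0.1 and 0.15;
#' SVM 75/25 split, 10 folds, 10 repeats. Any override is recorded in the
#' manifest.
#'
#' @param session_template a [session_config()] used for simulated sessions
#'   (its seed is re-derived per session from `seed`).
#' @param n_sessions number of sessions (default 20).
#' @param seed master seed.
#' @param ... overrides for any default listed above (see source for field
#'   names).
#' @return a `run_config` list.
#' @export
run_config <- function(session_template = session_config(),
                       n_sessions = 20, seed = 1, ...) {
  cfg <- list(
    session_template = session_template, n_sessions = n_sessions,
    seed = seed,
    epoch_window = c(-2, 5), alignment = "stimulus", reject_k = 4,
    f_min = 2, f_max = 70, n_freqs = 139, n_times = 200, cycles = c(2, 0.7),
    power_baseline = c(-1, -0.75), wpli_baseline = c(-0.7, -0.5),
    delta_band = c(1, 4), delta_window = c(0.3, 0.5),
    theta_band = c(4, 7), theta_window = c(0.5, 2),
    beta_band = c(13, 30), decode_window = c(0.5, 0.9),
    alpha = 0.05, graph_thresholds = c(0.1, 0.15),
    svm_split = 0.75, svm_folds = 10, svm_repeats = 10,
    svm_lambda_grid = c(0.001, 0.01, 0.1),
    seed_region = "M1", svm_window = c(-0.5, 2))
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  cfg$overridden <- names(overrides)
  class(cfg) <- "run_config"
  cfg
}

# Mean over a frequency band of a wpli stack -> electrodes x electrodes x
# times array (masked bins dropped from the average).
wpli_band_time <- function(stack, band) {
  fidx <- freq_indices(stack$freqs, band)
  x <- aperm(stack$wpli[, , fidx, , drop = FALSE], c(1, 2, 4, 3))
  out <- rowMeans(x, na.rm = TRUE, dims = 3)
  out[is.nan(out)] <- NA_real_
  out
}

#' Run the full analysis pipeline on simulated sessions
#'
#' Per session: generate, epoch, reject artifacts (k x SD rule), median
#' reference, Morlet transform, session TFE maps per condition, and evoked
#' wPLI per condition. Across sessions: dual-masked trial-type contrasts
#' with whole-matrix FDR, band/window summary tables with Bonferroni
#' correction, wPLI condition contrasts with FDR over the pair matrix and
#' thresholded network graphs, and (optionally) outcome decoding. The run is
#' deterministic given `config$seed`.
#'
#' @param config a [run_config()].
#' @param stages character subset of `c("stats", "connectivity",
#'   "decoding")`; the simulation/preprocess/spectral stages always run.
#' @return a results bundle (list) with elements `maps`, `stats`,
#'   `connectivity`, `decoding`, `ground_truth`, and `manifest`.
#' @export
run_all <- function(config, stages = c("stats", "connectivity", "decoding")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  conds <- c("go-correct", "wait-correct", "wait-incorrect")
  ns <- config$n_sessions
  labels <- config$session_template$channel_labels
  n_ch <- length(labels)

  tfe_stacks <- list()       # condition -> sessions x t x f x e
  pair_means <- list()       # measure -> condition -> list of matrices
  theta_time <- list(); beta_time <- list()
  gt <- list(); counts <- list()

  for (s in seq_len(ns)) {
    scfg <- config$session_template
    scfg$seed <- (config$seed * 1009L + s * 7919L) %% .Machine$integer.max
    sess <- generate_session(scfg)
    gt[[s]] <- sess$ground_truth
    ep <- epoch(sess$recording, sess$events, config$alignment,
                config$epoch_window)
    rej <- reject_artifacts(ep, k = config$reject_k)
    ep <- median_reference(rej$epochs)
    cube <- wavelet_transform(ep, config$f_min, config$f_max, config$n_freqs,
                              config$cycles, config$n_times)
    maps <- session_maps(cube, conds, config$power_baseline)
    for (cond in names(maps)) {
      if (is.null(tfe_stacks[[cond]]))
        tfe_stacks[[cond]] <- array(NA_real_, c(ns, dim(maps[[cond]])))
      tfe_stacks[[cond]][s, , , ] <- maps[[cond]]
    }
    counts[[s]] <- list(trials_in = nrow(sess$events),
                        trials_rejected = rej$n_rejected,
                        trials_dropped = ep$n_dropped)
    if (any(c("connectivity", "decoding") %in% stages)) {
      csel <- tfe_conditions(cube$events)
      for (cond in conds) {
        keep <- csel[[cond]]
        if (sum(keep) < 2) next
        st <- evoked_wpli(wpli(cube, trials = keep), config$wpli_baseline)
        pair_means[["delta"]][[cond]][[s]] <-
          wpli_band_window(st, config$delta_band, config$delta_window)
        pair_means[["theta"]][[cond]][[s]] <-
          wpli_band_window(st, config$theta_band, config$theta_window)
        pair_means[["decode"]][[cond]][[s]] <-
          wpli_band_window(st, config$theta_band, config$decode_window)
        if (cond != "go-correct" && "decoding" %in% stages) {
          theta_time[[cond]][[s]] <- wpli_band_time(st, config$theta_band)
          if (config$beta_band[1] <= config$f_max)
            beta_time[[cond]][[s]] <- wpli_band_time(st, config$beta_band)
        }
      }
    }
    rm(cube)
  }

  bundle <- list(maps = tfe_stacks, ground_truth = gt)
  times <- NULL; freqs <- NULL
  if (length(tfe_stacks)) {
    ref <- session_maps_axes(config)
    times <- ref$times; freqs <- ref$freqs
  }

  if ("stats" %in% stages) {
    go <- tfe_stacks[["go-correct"]]; wc <- tfe_stacks[["wait-correct"]]
    stats_out <- list()
    if (!is.null(go) && !is.null(wc)) {
      # drop sessions missing either condition (empty-condition maps are NA)
      ok <- which(apply(is.finite(matrix(go, ns)), 1, all) &
                    apply(is.finite(matrix(wc, ns)), 1, all))
      if (length(ok) < 3) stop("fewer than 3 sessions with both conditions")
      go <- go[ok, , , , drop = FALSE]; wc <- wc[ok, , , , drop = FALSE]
      stats_out$go_vs_wait <- dual_masked_contrast(go, wc, config$alpha)
      stats_out$wait_vs_go <- dual_masked_contrast(wc, go, config$alpha)
      bw <- function(stack_diff, band, window) {
        tidx <- time_indices(times, window)
        fidx <- freq_indices(freqs, band)
        out <- apply(stack_diff[, tidx, fidx, , drop = FALSE], c(1, 4), mean)
        colnames(out) <- labels
        out
      }
      stats_out$delta_sessions <- bw(go - wc, config$delta_band,
                                     config$delta_window)
      stats_out$theta_sessions <- bw(wc - go, config$theta_band,
                                     config$theta_window)
      stats_out$delta_table <- band_summary_table(stats_out$delta_sessions,
                                                  m = n_ch)
      stats_out$theta_table <- band_summary_table(stats_out$theta_sessions,
                                                  m = n_ch)
    }
    bundle$stats <- stats_out
  }

  if ("connectivity" %in% stages) {
    conn <- list()
    pm <- pair_means
    ok <- function(cond, measure) {
      xs <- pm[[measure]][[cond]]
      !is.null(xs) && sum(!vapply(xs, is.null, logical(1))) >= 3
    }
    if (ok("go-correct", "delta") && ok("wait-correct", "delta")) {
      both <- function(measure) {
        a <- pm[[measure]][["go-correct"]]; b <- pm[[measure]][["wait-correct"]]
        nn <- function(l) which(!vapply(l, is.null, logical(1)))
        keep <- intersect(nn(a), nn(b))
        list(go = a[keep], wait = b[keep])
      }
      d <- both("delta"); th <- both("theta")
      conn$delta_go_vs_wait <- wpli_condition_contrast(
        d$go, d$wait, config$delta_band, config$delta_window, config$alpha)
      conn$theta_wait_vs_go <- wpli_condition_contrast(
        th$wait, th$go, config$theta_band, config$theta_window, config$alpha)
      conn$graphs <- threshold_graph(conn$theta_wait_vs_go$mean,
                                     conn$theta_wait_vs_go$mask,
                                     config$graph_thresholds,
                                     conn$theta_wait_vs_go$adj_p)
    }
    bundle$connectivity <- conn
  }

  if ("decoding" %in% stages) {
    bundle$decoding <- run_decoding(config, tfe_stacks, pair_means,
                                    theta_time, beta_time, times, freqs,
                                    labels)
  }

  bundle$manifest <- list(
    package_version = as.character(utils::packageVersion("oscnet")),
    r_version = R.version.string,
    seed = config$seed, n_sessions = ns,
    config = config[setdiff(names(config), "session_template")],
    session_template = config$session_template[
      setdiff(names(config$session_template),
              c("burst_specs", "coupling_specs"))],
    counts = counts, stages = stages, timestamp = format(Sys.time()))
  bundle
}

# The time/frequency axes the session maps were computed on (recomputed from
# the config so the bundle does not need to retain a tf_cube).
session_maps_axes <- function(config) {
  fs <- config$session_template$fs
  sigma_t <- n_cycles_at(config$f_min, config$f_min, config$cycles) /
    (2 * pi * config$f_min)
  support <- 3 * sigma_t
  w <- config$epoch_window
  n_samp <- round((w[2] - w[1]) * fs)
  tvec0 <- w[1]
  t_lo <- tvec0 + support
  t_hi <- (w[1] + (n_samp - 1) / fs) - support
  list(times = seq(t_lo, t_hi, length.out = config$n_times),
       freqs = seq(config$f_min, config$f_max, length.out = config$n_freqs))
}

run_decoding <- function(config, tfe_stacks, pair_means, theta_time,
                         beta_time, times, freqs, labels) {
  out <- list()
  wc <- tfe_stacks[["wait-correct"]]; wi <- tfe_stacks[["wait-incorrect"]]
  if (is.null(wc) || is.null(wi)) return(out)
  fidx <- freq_indices(freqs, config$theta_band)
  theta_of <- function(stack)                       # sessions x el x times
    aperm(apply(stack[, , fidx, , drop = FALSE], c(1, 2, 4), mean), c(1, 3, 2))
  ds_pow <- outcome_dataset(theta_of(wc), theta_of(wi))
  out$univariate <- univariate_outcome_regression(ds_pow$x, ds_pow$y,
                                                  config$alpha)

  complete <- function(lst) which(!vapply(lst, is.null, logical(1)))
  sess_ok <- intersect(complete(pair_means[["decode"]][["wait-correct"]]),
                       complete(pair_means[["decode"]][["wait-incorrect"]]))
  if (length(sess_ok) >= 5) {
    stack_pairs <- function(cond) {
      xs <- pair_means[["decode"]][[cond]][sess_ok]
      arr <- array(NA_real_, c(length(xs), dim(xs[[1]])))
      for (i in seq_along(xs)) arr[i, , ] <- xs[[i]]
      arr
    }
    ds_w <- outcome_dataset(stack_pairs("wait-correct"),
                            stack_pairs("wait-incorrect"))
    ds_w$x[is.na(ds_w$x)] <- 0
    out$pairwise <- wpli_outcome_regression(ds_w$x, ds_w$y, config$alpha,
                                            labels)
    seed_idx <- match(config$seed_region, labels)
    if (!is.na(seed_idx)) {
      xm <- ds_w$x[, seed_idx, -seed_idx, drop = TRUE]
      colnames(xm) <- labels[-seed_idx]
      if (length(ds_w$y) >= ncol(xm) + 2) {
        out$multivariate <- multivariate_connectivity_model(xm, ds_w$y)
      } else {
        out$notes <- c(out$notes,
                       "multivariate model skipped: fewer rows than features")
      }

      tsel <- which(times >= config$svm_window[1] &
                      times <= config$svm_window[2])
      svm_feats <- function(time_list) {
        xs <- time_list[sess_ok]
        arr <- array(NA_real_,
                     c(length(xs), length(labels) - 1, length(tsel)))
        for (i in seq_along(xs))
          arr[i, , ] <- xs[[i]][seed_idx, -seed_idx, tsel]
        arr
      }
      fc <- svm_feats(theta_time[["wait-correct"]])
      fi <- svm_feats(theta_time[["wait-incorrect"]])
      xa <- abind_first(fc, fi)
      xa[is.na(xa)] <- 0
      y <- c(rep(1, length(sess_ok)), rep(0, length(sess_ok)))
      out$svm_theta <- svm_timecourse(
        xa, y, times[tsel], config$svm_split, config$svm_folds,
        config$svm_repeats, config$svm_lambda_grid, config$decode_window,
        seed = config$seed)
      if (length(beta_time)) {
        bc <- svm_feats(beta_time[["wait-correct"]])
        bi <- svm_feats(beta_time[["wait-incorrect"]])
        xb <- abind_first(bc, bi)
        xb[is.na(xb)] <- 0
        out$svm_beta <- svm_timecourse(
          xb, y, times[tsel], config$svm_split, config$svm_folds,
          config$svm_repeats, config$svm_lambda_grid, config$decode_window,
          seed = config$seed)
      } else {
        out$notes <- c(out$notes,
                       "beta-band control skipped: band outside frequency grid")
      }
    }
  }
  out
}

#' Summarize a results bundle into report tables
#'
#' Produces per-region band summary tables (region, mean, SEM, adjusted p;
#' Bonferroni-adjusted values above 1 are set to 1), network edge lists and
#' a decoding summary. Missing stages are omitted with a note. If `dir` is
#' given, tables are also written as CSV plus a markdown overview.
#'
#' @param bundle result of [run_all()].
#' @param dir optional output directory.
#' @return list of data frames (`delta_table`, `theta_table`, `edges_*`,
#'   `decoding_summary`) and `notes`.
#' @export
make_report <- function(bundle, dir = NULL) {
  out <- list(notes = character(0))
  if (!is.null(bundle$stats$delta_table)) {
    out$delta_table <- bundle$stats$delta_table
    out$theta_table <- bundle$stats$theta_table
  } else out$notes <- c(out$notes, "stats stage missing; band tables omitted")
  if (!is.null(bundle$connectivity$graphs)) {
    for (th in names(bundle$connectivity$graphs))
      out[[paste0("edges_", th)]] <- bundle$connectivity$graphs[[th]]
  } else out$notes <- c(out$notes, "connectivity stage missing; graphs omitted")
  if (!is.null(bundle$decoding$multivariate)) {
    mv <- bundle$decoding$multivariate
    out$decoding_summary <- data.frame(
      feature = names(mv$beta), beta = mv$beta, se = mv$se, p = mv$p,
      row.names = NULL, stringsAsFactors = FALSE)
    out$decoding_pseudo_r2 <- mv$pseudo_r2
  } else out$notes <- c(out$notes, "decoding stage missing; summary omitted")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      if (is.data.frame(out[[nm]]))
        utils::write.csv(out[[nm]], file.path(dir, paste0(nm, ".csv")),
                         row.names = FALSE)
    }
    md <- c("# Analysis report", "",
            paste0("- sessions: ", bundle$manifest$n_sessions),
            paste0("- seed: ", bundle$manifest$seed),
            if (length(out$notes)) paste0("- note: ", out$notes))
    writeLines(md, file.path(dir, "report.md"))
    jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}
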