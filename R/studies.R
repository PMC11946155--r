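#' Scaled session configuration for desk-scale recovery studies
#'
#' The full study conditions (30 channels, 1000 Hz, two blocks) make repeated
#' whole-cohort simulation unnecessarily heavy for recovery studies whose
#' questions are statistical, not spatial. This configuration keeps the task
#' structure (1100 ms SOA, equiprobable shuffled Go/No-Go), the 1 Hz spectral
#' resolution (125-sample prestimulus window at 250 Hz padded to 250), and
#' the cohort size, while reducing channels and sampling rate.
#'
#' @param n_channels channels (default 6).
#' @param fs sampling rate (default 250).
#' @param n_blocks blocks of 75 + 75 trials (default 1).
#' @return an [session_config()].
#' @export
recovery_config <- function(n_channels = 6, fs = 250, n_blocks = 1) {
  session_config(n_channels = n_channels, fs = fs, n_blocks = n_blocks)
}

#' Noise-parameter recovery study
#'
#' Simulates participants whose oscillation bumps are confined to 6-20 Hz (so
#' the 2-5 and 21-24 Hz flanks carry pure noise), runs the participant
#' pipeline, converts fitted noise powers back to generator PSD units with
#' [noise_measurement_gain()], and reports the per-seed recovery ratios.
#'
#' @param n_seeds number of simulated participants (default 20).
#' @param master_seed integer master seed.
#' @param pink_power,white_power generator PSD truths.
#' @param n_trials trials per condition (default 1000; the envelope-constrained
#'   fit needs well-averaged spectra, see the vignette).
#' @return data frame: seed, `p_ratio`, `w_ratio` (fitted / true).
#' @export
noise_recovery_study <- function(n_seeds = 20, master_seed = 1,
                                 pink_power = 12, white_power = 0.25,
                                 n_trials = 1000) {
  cfg <- session_config(n_channels = 1, fs = 250, n_go_per_block = n_trials,
                        n_nogo_per_block = n_trials, n_blocks = 1)
  bands <- data.frame(
    name = c("TA", "A1", "AB"), centre_hz = c(8, 10, 15),
    bandwidth_hz = c(2, 2, 3), rms_uv = c(2.5, 4, 2),
    topo_centre = c(0.35, 0.85, 0.55), topo_width = c(0.25, 0.25, 0.25))
  kap <- noise_measurement_gain(round(0.5 * cfg$fs), cfg$fs)
  out <- lapply(seq_len(n_seeds), function(s) {
    tr <- ground_truth(pink_power_at_1hz = pink_power,
                       white_power = white_power, bands = bands,
                       omission_rate = 0, commission_rate = 0)
    pp <- participant_pipeline(cfg, tr, derive_seed(master_seed, paste0("noise/", s)),
                               min_trials = 50)
    data.frame(seed = s, p_ratio = stats::median(pp$noise$p) / kap / pink_power,
               w_ratio = stats::median(pp$noise$w) / kap / white_power)
  })
  do.call(rbind, out)
}

#' Constructed oscillation-spectrum case matrix with planted bands
#'
#' Emulates noise-free oscillation spectra for a cohort without running the
#' full pipeline: per participant, each band has a log-normally jittered
#' amplitude and a slightly jittered centre; channels apply a smooth
#' topography plus channel-level amplitude noise; a small positive spectral
#' noise floor is added per bin.
#'
#' @param n_participants,n_channels cohort geometry.
#' @param centres_hz planted band centres (default `c(2, 8, 10, 15, 25)`).
#' @param widths_hz Gaussian widths of the spectral bumps.
#' @param amps_uv base peak amplitudes.
#' @param seed integer seed.
#' @param noise_uv RMS of the per-bin noise floor.
#' @return list: `X` (cases x 31 bins), `participant`, `freq_hz`.
#' @export
simulate_oscillation_cases <- function(n_participants = 47, n_channels = 30,
                                       centres_hz = c(2, 8, 10, 15, 25),
                                       widths_hz = c(1, 1, 1, 1, 1),
                                       amps_uv = c(3, 3, 4, 3, 3),
                                       seed = 1, noise_uv = 0.1) {
  set.seed(seed)
  nb <- length(centres_hz)
  f <- 0:30
  topo_centres <- seq(0.15, 0.85, length.out = nb)
  X <- matrix(0, n_participants * n_channels, length(f))
  pid <- rep(seq_len(n_participants), each = n_channels)
  for (p in seq_len(n_participants)) {
    amp_p <- amps_uv * exp(stats::rnorm(nb, 0, 0.2))
    cen_p <- centres_hz + stats::rnorm(nb, 0, 0.1)
    for (c in seq_len(n_channels)) {
      topo <- vapply(seq_len(nb), function(b)
        make_topography(n_channels, topo_centres[b])[c], numeric(1))
      a <- amp_p * topo * exp(stats::rnorm(nb, 0, 0.1))
      s <- colSums(a * t(vapply(seq_len(nb), function(b)
        exp(-((f - cen_p[b])^2) / (2 * widths_hz[b]^2)), numeric(length(f)))))
      X[(p - 1) * n_channels + c, ] <- s + abs(stats::rnorm(length(f), 0, noise_uv))
    }
  }
  list(X = X, participant = pid, freq_hz = f)
}

#' Constructed mean-ERP case matrix with planted deflections
#'
#' Per participant and channel, the mean ERP is a sum of Gaussian-windowed
#' deflections with jittered amplitudes plus smooth residual noise (what
#' survives averaging a finite number of epochs: low-passed background EEG).
#'
#' @param n_participants,n_channels cohort geometry.
#' @param latencies_ms,widths_ms,amps_uv deflection parameters (signed peaks).
#' @param fs sampling rate of the ERP axis (default 500, i.e. 2 ms steps).
#' @param seed integer seed.
#' @param resid_uv RMS of the smooth residual noise.
#' @return list: `X` (cases x time), `participant`, `time_ms`.
#' @export
simulate_erp_cases <- function(n_participants = 47, n_channels = 30,
                               latencies_ms = c(100, 145, 240, 330, 450),
                               widths_ms = c(15, 18, 30, 45, 70),
                               amps_uv = c(-8, -6, -6, 10, 5),
                               fs = 500, seed = 1, resid_uv = 0.4) {
  set.seed(seed)
  t_ms <- seq(-100, 500 - 1000 / fs, by = 1000 / fs)
  nd <- length(latencies_ms)
  topo_centres <- c(0.4, 0.7, 0.45, 0.8, 0.55)[seq_len(nd)]
  shapes <- vapply(seq_len(nd), function(d)
    exp(-((t_ms - latencies_ms[d])^2) / (2 * widths_ms[d]^2)), numeric(length(t_ms)))
  n_cases <- n_participants * n_channels
  nt <- length(t_ms)
  X <- matrix(0, n_cases, nt)
  pid <- rep(seq_len(n_participants), each = n_channels)
  topo <- vapply(seq_len(nd), function(d)
    make_topography(n_channels, topo_centres[d]), numeric(n_channels))
  for (p in seq_len(n_participants)) {
    amp_p <- amps_uv * exp(stats::rnorm(nd, 0, 0.25))
    rows <- (p - 1) * n_channels + seq_len(n_channels)
    X[rows, ] <- topo %*% (amp_p * t(shapes))
  }
  # band-limited residual noise (what survives averaging 0.1-30 Hz background
  # EEG over ~150 epochs), via an FFT low-pass with a 30-35 Hz cosine ramp
  fgrid <- c(0, seq_len(nt - 1)) * fs / nt
  fgrid <- pmin(fgrid, fs - fgrid)
  mask <- ifelse(fgrid <= 30, 1, ifelse(fgrid >= 35, 0,
                                        0.5 * (1 + cos(pi * (fgrid - 30) / 5))))
  R <- matrix(stats::rnorm(nt * n_cases), nt, n_cases)
  R <- Re(stats::mvfft(stats::mvfft(R) * mask, inverse = TRUE)) / nt
  R <- sweep(R, 2, apply(R, 2, stats::sd), "/") * resid_uv
  X <- X + t(R)
  list(X = X, participant = pid, time_ms = t_ms)
}

#' End-to-end linkage recovery study
#'
#' For each cohort seed: simulate a 47-participant cohort with the planted
#' coupling pattern (alpha -> Go P3b +, beta -> Go N2c -, pink -> No-Go N1b
#' -, pink -> No-Go N1c +) at the given strength, run the full pipeline, and
#' record for each planted link whether the stepwise regression of the
#' matched ERP component selected a predictor of the matched source with the
#' planted sign.
#'
#' @param n_cohorts number of cohort seeds (default 20).
#' @param master_seed integer master seed.
#' @param strength coupling strength (default 0.5).
#' @param n_participants cohort size (default 47).
#' @param config session configuration (default [recovery_config()]).
#' @param min_trials inclusion threshold (default 25, one third of the
#'   per-condition trial count, mirroring the 50-of-150 full-scale rule).
#' @return list: `hits` (cohorts x 4 logical matrix), `rates` (per link),
#'   `n_regressions`, `n_selected_total`.
#' @export
linkage_recovery_study <- function(n_cohorts = 20, master_seed = 1,
                                   strength = 0.5, n_participants = 47,
                                   config = recovery_config(),
                                   min_trials = 25) {
  truth <- ground_truth(couplings = default_couplings(strength))
  links <- data.frame(
    link = c("alpha_P3b", "beta_N2c", "pink_N1b", "pink_N1c"),
    source_hz = c(10, 25, NA, NA),          # NA: pink-noise predictor
    cond = c("go", "go", "nogo", "nogo"),
    target_ms = c(330, 240, 100, 145),
    sign = c(1, -1, -1, 1))
  hits <- matrix(NA, n_cohorts, nrow(links),
                 dimnames = list(NULL, links$link))
  n_reg <- 0L; n_sel <- 0L
  for (k in seq_len(n_cohorts)) {
    res <- cohort_pipeline(config, truth, n_participants,
                           master_seed = derive_seed(master_seed, paste0("cohort/", k)),
                           min_trials = min_trials)
    pred_peak <- res$fpca$peak_hz[res$fpca$selected]
    pred_names <- colnames(res$predictors)
    td <- tidy_stepwise(res$linkage$primary)
    n_reg <- n_reg + length(res$linkage$primary)
    n_sel <- n_sel + sum(!is.na(td$predictor))
    for (j in seq_len(nrow(links))) {
      ln <- links[j, ]
      ts <- res[[paste0("tpca_", ln$cond)]]
      dv_i <- match_components(ts$peak_ms[ts$selected], ln$target_ms, max_dist = 25)
      if (is.na(dv_i)) { hits[k, j] <- FALSE; next }
      dv <- paste0(ln$cond, "_T", round(ts$peak_ms[ts$selected]))
      dv <- make.unique(dv)[dv_i]
      sel <- td[td$dependent == dv & !is.na(td$predictor), ]
      if (is.na(ln$source_hz)) {
        ok_pred <- sel$predictor == "PN"
      } else {
        src_cols <- pred_names[seq_along(pred_peak)][abs(pred_peak - ln$source_hz) <= 2]
        ok_pred <- sel$predictor %in% src_cols
      }
      hits[k, j] <- any(ok_pred & sign(sel$beta) == ln$sign)
    }
  }
  list(hits = hits, rates = colMeans(hits), n_regressions = n_reg,
       n_selected_total = n_sel)
}

#' Stepwise null false-selection rate by direct simulation
#'
#' Fraction of runs in which at least one of `k` pure-noise predictors is
#' selected for a pure-noise response at the given thresholds.
#'
#' @param n_runs simulation replicates (default 2000).
#' @param n cases per run (default 47).
#' @param k predictors (default 7).
#' @param seed integer seed.
#' @param p_enter,p_remove stepwise thresholds.
#' @return list: `rate` (any-selection rate), `n_selected` per run.
#' @export
stepwise_null_rate <- function(n_runs = 2000, n = 47, k = 7, seed = 1,
                               p_enter = 0.05, p_remove = 0.10) {
  set.seed(seed)
  n_selected <- vapply(seq_len(n_runs), function(r) {
    X <- as.data.frame(matrix(stats::rnorm(n * k), n, k))
    names(X) <- paste0("x", seq_len(k))
    y <- stats::rnorm(n)
    length(stepwise_regress(X, y, p_enter, p_remove)$selected)
  }, numeric(1))
  list(rate = mean(n_selected > 0), n_selected = n_selected)
}
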