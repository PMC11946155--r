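#' Full single-participant pipeline: session to spectra, noise, ERPs, behaviour
#'
#' Generates (or accepts) a session, band-pass filters it, classifies trial
#' validity, epochs, rejects artifacts, matches accepted epoch counts between
#' conditions, derives prestimulus amplitude spectra and their within-subject
#' means, fits and subtracts the pink + white noise model per channel on the
#' pooled Go/No-Go spectrum, averages the ERPs (-100..500 ms, half-sampled),
#' and summarises behaviour.
#'
#' @param config an [session_config()].
#' @param truth an [ground_truth()].
#' @param seed master seed for this participant's session and subsampling.
#' @param min_trials inclusion threshold for accepted epochs per condition.
#' @param session optionally, a pre-generated `oscdyn_session` to process.
#' @return list: `excluded`, `n_accepted` (per condition before matching),
#'   `n_matched`, `rejection_counts`, `osc` (channels x 31 oscillation
#'   amplitudes, 0-30 Hz), `observed` (pooled amplitude spectra), `noise`
#'   (per-channel `p`, `w`, `n_clipped`), `erp` (list go/nogo channel x time
#'   matrices), `erp_time_ms`, `behaviour`, `freq_hz`.
#' @export
participant_pipeline <- function(config, truth, seed, min_trials = 50,
                                 session = NULL) {
  session <- session %||% generate_session(config, truth, seed = seed)
  fs <- config$fs
  rec <- bandpass_filter(session$recording)
  valid <- classify_trials(session$events, config$soa_ms, fs)
  epochs <- extract_epochs(rec, session$events, valid)
  epochs <- reject_artifacts(epochs)
  rejc <- attr(epochs, "rejection_counts")
  acc <- which(epochs$valid)
  go_set <- epochs_subset(epochs, acc[epochs$condition[acc] == "go"])
  nogo_set <- epochs_subset(epochs, acc[epochs$condition[acc] == "nogo"])
  n_acc <- c(go = dim(go_set$data)[1], nogo = dim(nogo_set$data)[1])
  m <- match_epoch_counts(go_set, nogo_set, min_trials = min_trials,
                          seed = derive_seed(seed, "match"))
  beh <- summarize_behaviour(session$events)
  if (m$excluded) {
    return(list(excluded = TRUE, n_accepted = n_acc, n_matched = m$n_matched,
                rejection_counts = rejc, behaviour = beh))
  }
  nch <- config$n_channels

  sp_go <- epoch_spectra(m$go)
  sp_nogo <- epoch_spectra(m$nogo)
  freq <- attr(sp_go, "freq_hz")
  mgo <- apply(sp_go, c(2, 3), mean)
  mnogo <- apply(sp_nogo, c(2, 3), mean)
  pooled <- (mgo + mnogo) / 2

  osc <- matrix(0, nch, length(freq))
  noise <- data.frame(channel = config$channels, p = NA_real_, w = NA_real_,
                      n_clipped = NA_integer_)
  for (c in seq_len(nch)) {
    amp <- pooled[c, ]
    pw <- amp[freq >= 1]^2
    fit <- fit_pink_white(pw, freq_hz = freq[freq >= 1])
    ext <- extend_noise(fit, lo = 1, hi = max(freq))
    sub <- subtract_noise(amp[freq >= 1], freq[freq >= 1], ext)
    osc[c, freq >= 1] <- sub$osc_amplitude
    osc[c, freq < 1] <- amp[freq < 1]  # 0 Hz bin: no 1/f model, kept observed
    noise$p[c] <- fit$p; noise$w[c] <- fit$w; noise$n_clipped[c] <- sub$n_clipped
  }

  erp_window <- function(set) {
    sel <- set$time_ms >= -100 & set$time_ms < 500
    avg <- apply(set$data[, , sel, drop = FALSE], c(2, 3), mean)
    half_sample(matrix(avg, nch))
  }
  erp <- list(go = erp_window(m$go), nogo = erp_window(m$nogo))
  t_ms <- epochs$time_ms[epochs$time_ms >= -100 & epochs$time_ms < 500]
  erp_time <- half_sample(t_ms)

  list(excluded = FALSE, n_accepted = n_acc, n_matched = m$n_matched,
       rejection_counts = rejc, osc = osc, observed = pooled, noise = noise,
       erp = erp, erp_time_ms = erp_time, behaviour = beh, freq_hz = freq)
}

#' Match component peaks to named targets
#'
#' Assigns each target (e.g. a planted band centre or ERP latency) the
#' selected component whose peak is nearest, returning `NA` where the nearest
#' peak is farther than `max_dist`.
#'
#' @param peaks peak variable (Hz or ms) of each selected component.
#' @param targets named numeric vector of target positions.
#' @param max_dist maximum admissible distance.
#' @return named integer vector: index into `peaks` per target (or `NA`).
#' @export
match_components <- function(peaks, targets, max_dist = Inf) {
  out <- vapply(targets, function(tg) {
    if (!length(peaks)) return(NA_integer_)
    i <- which.min(abs(peaks - tg))
    if (abs(peaks[i] - tg) > max_dist) NA_integer_ else i
  }, integer(1))
  names(out) <- names(targets)
  out
}

#' Full cohort pipeline: simulate, process, decompose, link
#'
#' Simulates `n_participants` jittered participants, runs
#' [participant_pipeline()] on each, stacks cases (participant x channel) for
#' the frequency PCA of oscillation spectra and the per-condition temporal
#' PCAs of the ERPs, extracts per-participant global-mean component
#' amplitudes and the pink/white noise amplitudes at 1 Hz, and (optionally)
#' runs the stepwise linkage suite.
#'
#' @param config an [session_config()].
#' @param base_truth the cohort's base [ground_truth()].
#' @param n_participants cohort size (excluded participants are dropped).
#' @param master_seed integer master seed.
#' @param jitter_sd between-participant log-normal amplitude jitter.
#' @param cutoff PCA variance cutoff percent.
#' @param kappa Promax power.
#' @param min_trials inclusion threshold.
#' @param run_regressions run [run_linkage_suite()] (default `TRUE`).
#' @return list: `fpca`, `tpca_go`, `tpca_nogo`, `predictors`, `erp_amp`,
#'   `behaviour`, `noise`, `linkage`, `excluded` (ids), `participants`.
#' @export
cohort_pipeline <- function(config, base_truth, n_participants, master_seed,
                            jitter_sd = 0.2, cutoff = 1.5, kappa = 3,
                            min_trials = 50, run_regressions = TRUE) {
  truths <- cohort_truths(base_truth, n_participants, master_seed, jitter_sd)
  pps <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    pps[[i]] <- participant_pipeline(
      config, truths[[i]], derive_seed(master_seed, paste0("participant/", i)),
      min_trials = min_trials)
  }
  keep <- which(!vapply(pps, `[[`, logical(1), "excluded"))
  excluded <- setdiff(seq_len(n_participants), keep)
  if (length(keep) < 3) stop("fewer than 3 participants retained", call. = FALSE)
  nch <- config$n_channels
  pid <- rep(keep, each = nch)

  osc_cases <- do.call(rbind, lapply(pps[keep], `[[`, "osc"))
  freq <- pps[[keep[1]]]$freq_hz
  f_sol <- fpca(osc_cases, pid, freq_hz = freq, cutoff = cutoff, kappa = kappa)

  erp_time <- pps[[keep[1]]]$erp_time_ms
  t_sol <- lapply(c(go = "go", nogo = "nogo"), function(cond) {
    cases <- do.call(rbind, lapply(pps[keep], function(p) p$erp[[cond]]))
    tpca(cases, pid, time_ms = erp_time, cutoff = cutoff)
  })

  noise_tab <- do.call(rbind, lapply(keep, function(i) {
    cbind(participant = i, pps[[i]]$noise)
  }))
  pn <- vapply(keep, function(i) mean(sqrt(pps[[i]]$noise$p)), numeric(1))
  wn <- vapply(keep, function(i) mean(sqrt(pps[[i]]$noise$w)), numeric(1))

  predictors <- data.frame(row.names = as.character(keep))
  if (!is.null(f_sol$amplitudes)) {
    fa <- f_sol$amplitudes
    colnames(fa) <- make.unique(paste0("F", f_sol$peak_hz[f_sol$selected], "Hz"))
    predictors <- cbind(predictors, fa[as.character(keep), , drop = FALSE])
  }
  predictors$PN <- pn
  predictors$WN <- wn

  erp_amp <- data.frame(row.names = as.character(keep))
  for (cond in c("go", "nogo")) {
    ts <- t_sol[[cond]]
    if (!is.null(ts$amplitudes)) {
      ta <- ts$amplitudes
      colnames(ta) <- make.unique(paste0(cond, "_T", round(ts$peak_ms[ts$selected])))
      erp_amp <- cbind(erp_amp, ta[as.character(keep), , drop = FALSE])
    }
  }

  behaviour <- do.call(rbind, lapply(pps[keep], `[[`, "behaviour"))
  rownames(behaviour) <- as.character(keep)

  linkage <- if (run_regressions && ncol(erp_amp) > 0 &&
                 nrow(predictors) > ncol(predictors) + 2) {
    run_linkage_suite(predictors, erp_amp, behaviour)
  } else NULL

  list(fpca = f_sol, tpca_go = t_sol$go, tpca_nogo = t_sol$nogo,
       predictors = predictors, erp_amp = erp_amp, behaviour = behaviour,
       noise = noise_tab, linkage = linkage, excluded = excluded,
       participants = keep,
       n_accepted = t(vapply(pps[keep], `[[`, numeric(2), "n_accepted")),
       case_ratio_f = nrow(osc_cases) / ncol(osc_cases),
       case_ratio_t = nrow(osc_cases) / length(erp_time))
}

#' Run the whole pipeline from a configuration file
#'
#' Executes simulate, preprocess, spectra, noise, f-PCA, t-PCA, behaviour and
#' regression in order, writes every stage table as CSV plus a reproducibility
#' manifest (config snapshot, master seed, derived per-participant seeds,
#' output digests, package version) and a human-readable run report.
#'
#' @param config_path YAML configuration file (see [read_config()]).
#' @param out_dir output directory.
#' @param seed master seed.
#' @return invisibly, the manifest list.
#' @export
run_all <- function(config_path, out_dir, seed) {
  cfg <- read_config(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_part <- cfg$cohort$n_participants %||% 10
  an <- cfg$analysis
  res <- cohort_pipeline(cfg$config, cfg$truth, n_part, master_seed = seed,
                         jitter_sd = cfg$cohort$jitter_sd %||% 0.2,
                         cutoff = an$cutoff %||% 1.5, kappa = an$kappa %||% 3,
                         min_trials = an$min_trials %||% 50)

  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    write_csv_(df, p)
    paths[[length(paths) + 1L]] <<- p
  }
  put(cbind(participant = rownames(res$predictors), res$predictors), "predictors")
  put(cbind(participant = rownames(res$erp_amp), res$erp_amp), "erp_amplitudes")
  put(cbind(participant = rownames(res$behaviour), res$behaviour), "behaviour")
  put(res$noise, "noise_parameters")
  put(data.frame(freq_hz = res$fpca$freq_hz,
                 res$fpca$structure[, res$fpca$selected, drop = FALSE]),
      "fpca_loadings")
  put(data.frame(component = seq_along(res$fpca$variance_pct),
                 peak_hz = res$fpca$peak_hz,
                 variance_pct = res$fpca$variance_pct,
                 selected = seq_along(res$fpca$variance_pct) %in% res$fpca$selected),
      "fpca_selection")
  for (cond in c("go", "nogo")) {
    ts <- res[[paste0("tpca_", cond)]]
    put(data.frame(time_ms = ts$time_ms,
                   ts$loadings[, ts$selected, drop = FALSE]),
        paste0("tpca_", cond, "_loadings"))
    put(data.frame(component = seq_along(ts$variance_pct),
                   peak_ms = ts$peak_ms, variance_pct = ts$variance_pct,
                   selected = seq_along(ts$variance_pct) %in% ts$selected),
        paste0("tpca_", cond, "_selection"))
  }
  if (!is.null(res$linkage)) {
    put(tidy_stepwise(res$linkage$primary), "regressions_primary")
    if (length(res$linkage$secondary)) {
      put(tidy_stepwise(res$linkage$secondary), "regressions_secondary")
    }
  }

  manifest <- list(
    config = yaml::read_yaml(config_path), master_seed = seed,
    participant_seeds = vapply(seq_len(n_part), function(i)
      derive_seed(seed, paste0("participant/", i)), integer(1)),
    excluded = res$excluded,
    outputs = as.list(tools::md5sum(unlist(paths))),
    package_version = as.character(utils::packageVersion("oscdyn")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  sig <- if (!is.null(res$linkage)) {
    s <- tidy_stepwise(res$linkage$primary)
    s[!is.na(s$predictor), , drop = FALSE]
  } else data.frame()
  report <- c(
    sprintf("participants: %d retained, %d excluded", length(res$participants),
            length(res$excluded)),
    sprintf("accepted epochs per condition (matched): %s",
            paste(res$n_accepted[, 1], collapse = " ")),
    sprintf("f-PCA: %d components selected (peaks %s Hz)",
            length(res$fpca$selected),
            paste(res$fpca$peak_hz[res$fpca$selected], collapse = ", ")),
    sprintf("t-PCA go/nogo: %d / %d components selected",
            length(res$tpca_go$selected), length(res$tpca_nogo$selected)),
    sprintf("significant regressions: %d", nrow(sig))
  )
  writeLines(report, file.path(out_dir, "run_report.txt"))
  invisible(manifest)
}
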