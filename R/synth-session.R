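#' Session configuration for the equiprobable Go/No-Go task
#'
#' Defaults reproduce the recording/task setup the pipeline targets: 30-channel
#' EEG at 1000 Hz, a fixed 1100 ms stimulus onset asynchrony, and two blocks of
#' 75 Go + 75 No-Go tones in shuffled order.
#'
#' @param n_channels number of EEG channels.
#' @param fs sampling rate in Hz.
#' @param soa_ms stimulus onset asynchrony in ms; `soa_ms * fs / 1000` must be
#'   an integer number of samples.
#' @param n_go_per_block,n_nogo_per_block trials per block and condition.
#' @param n_blocks number of blocks.
#' @param seed integer seed for the session.
#' @return a list of class `oscdyn_config`.
#' @export
session_config <- function(n_channels = 30, fs = 1000, soa_ms = 1100,
                           n_go_per_block = 75, n_nogo_per_block = 75,
                           n_blocks = 2, seed = 1) {
  if (fs <= 0) stop("fs must be > 0", call. = FALSE)
  soa_samples <- soa_ms * fs / 1000
  if (abs(soa_samples - round(soa_samples)) > 1e-9) {
    stop("soa_ms * fs must be an integer number of samples", call. = FALSE)
  }
  if (n_go_per_block < 1 || n_nogo_per_block < 1 || n_blocks < 1 || n_channels < 1) {
    stop("counts must be >= 1", call. = FALSE)
  }
  structure(list(
    n_channels = as.integer(n_channels), fs = fs, soa_ms = soa_ms,
    soa_samples = as.integer(round(soa_samples)),
    n_go_per_block = as.integer(n_go_per_block),
    n_nogo_per_block = as.integer(n_nogo_per_block),
    n_blocks = as.integer(n_blocks), seed = as.integer(seed),
    channels = paste0("ch", seq_len(n_channels))
  ), class = "oscdyn_config")
}

#' Smooth per-channel topography weights
#'
#' Channels have no head-model geometry here; a topography is simply a smooth
#' non-negative weight profile over the channel index (a Gaussian hump on a
#' floor), distinct per component so spatial PCA structure exists.
#'
#' @param n_channels channel count.
#' @param centre hump centre as a fraction of the channel axis in `[0, 1]`.
#' @param width hump width (fraction of the axis).
#' @param floor baseline weight.
#' @return numeric weight vector of length `n_channels`.
#' @export
make_topography <- function(n_channels, centre = 0.5, width = 0.25, floor = 0.2) {
  x <- if (n_channels == 1L) 0.5 else (seq_len(n_channels) - 1) / (n_channels - 1)
  floor + (1 - floor) * exp(-((x - centre)^2) / (2 * width^2))
}

#' Ground truth for a synthetic session
#'
#' Describes every generative ingredient: band-limited oscillations, pink noise
#' (one-sided PSD `p/f`), white noise (uniform PSD), stimulus-locked ERP
#' deflection templates, trial-wise couplings from prestimulus sources to ERP
#' template amplitudes, and behaviour parameters. Coupling reference moments
#' (used to standardise the prestimulus source amplitude) are frozen at
#' construction from the *base* amplitudes, so cohort-level amplitude jitter
#' propagates into the planted between-participant linkages.
#'
#' @param pink_power_at_1hz pink-noise one-sided PSD at 1 Hz, microvolt^2/Hz.
#' @param white_power white-noise one-sided PSD, microvolt^2/Hz.
#' @param bands data frame with columns `name`, `centre_hz`, `bandwidth_hz`,
#'   `rms_uv`, and optionally a list-column `topo` of per-channel weights.
#' @param erps data frame with columns `name`, `condition` (`"go"`/`"nogo"`),
#'   `latency_ms`, `width_ms` (Gaussian SD of the deflection), `amplitude_uv`
#'   (signed peak), and optionally a `topo` list-column.
#' @param couplings data frame with columns `source` (a band name or
#'   `"pink"`), `target` (`"<condition>_<erp name>"`), `sign` (+1/-1),
#'   `strength` (>= 0), or `NULL` for none.
#' @param rt_mean_ms,rt_sd_ms Go reaction-time moments before truncation to
#'   100-1000 ms.
#' @param omission_rate,commission_rate error probabilities in `[0, 1]`.
#' @param pink_topo,white_topo optional per-channel multipliers on noise power.
#' @return a list of class `oscdyn_truth`.
#' @export
ground_truth <- function(pink_power_at_1hz = 12, white_power = 0.25,
                         bands = default_bands(), erps = default_erps(),
                         couplings = NULL,
                         rt_mean_ms = 340, rt_sd_ms = 70,
                         omission_rate = 0.042, commission_rate = 0.062,
                         pink_topo = NULL, white_topo = NULL) {
  stopifnot(pink_power_at_1hz >= 0, white_power >= 0,
            all(bands$rms_uv >= 0), rt_mean_ms > 0, rt_sd_ms >= 0)
  if (omission_rate < 0 || omission_rate > 1 || commission_rate < 0 || commission_rate > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(couplings)) {
    if (!all(couplings$sign %in% c(-1, 1))) stop("coupling sign must be +1 or -1", call. = FALSE)
    known <- c("pink", bands$name)
    if (!all(couplings$source %in% known)) {
      stop("coupling source not a known band or 'pink': ",
           paste(setdiff(couplings$source, known), collapse = ", "), call. = FALSE)
    }
    targets <- paste0(erps$condition, "_", erps$name)
    if (!all(couplings$target %in% targets)) {
      stop("coupling target not a known ERP template: ",
           paste(setdiff(couplings$target, targets), collapse = ", "), call. = FALSE)
    }
  }
  # reference moments for coupling standardisation, frozen at the base truth
  ref <- list()
  for (b in seq_len(nrow(bands))) ref[[bands$name[b]]] <- bands$rms_uv[b]
  ref[["pink"]] <- sqrt(pink_power_at_1hz)  # scaled by the spectral mass factor at generation
  structure(list(
    pink_power_at_1hz = pink_power_at_1hz, white_power = white_power,
    bands = bands, erps = erps, couplings = couplings,
    rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms,
    omission_rate = omission_rate, commission_rate = commission_rate,
    pink_topo = pink_topo, white_topo = white_topo,
    coupling_ref = ref, coupling_rel_sd = 0.35
  ), class = "oscdyn_truth")
}

#' Default oscillation bands (delta/theta, theta/alpha, alpha, alpha/beta, beta)
#' @return data frame of band parameters.
#' @export
default_bands <- function() {
  data.frame(
    name = c("DT", "TA", "A1", "AB", "B1"),
    centre_hz = c(2, 8, 10, 15, 25),
    bandwidth_hz = c(2, 2, 2, 3, 3),
    rms_uv = c(3, 2.5, 4, 2, 2),
    topo_centre = c(0.15, 0.35, 0.85, 0.55, 0.45),
    topo_width = c(0.3, 0.25, 0.25, 0.25, 0.3)
  )
}

#' Default ERP deflection templates for Go and No-Go
#' @return data frame of ERP template parameters.
#' @export
default_erps <- function() {
  data.frame(
    name = c("N1b", "N1c", "N2c", "P3b", "SW1",
             "N1b", "N1c", "N2b", "P3a", "SW1"),
    condition = c(rep("go", 5), rep("nogo", 5)),
    latency_ms = c(100, 145, 240, 330, 450, 100, 145, 230, 300, 450),
    width_ms = c(15, 18, 30, 45, 70, 15, 18, 28, 40, 70),
    amplitude_uv = c(-8, -5, -6, 10, 5, -8, -5, -5, 8, 4),
    topo_centre = c(0.4, 0.7, 0.45, 0.8, 0.55, 0.4, 0.7, 0.45, 0.4, 0.55),
    topo_width = c(0.25, 0.2, 0.25, 0.25, 0.3, 0.25, 0.2, 0.25, 0.25, 0.3)
  )
}

#' Couplings mirroring the planted prestimulus-to-ERP linkage structure
#'
#' Signs are the signs of the planted effect on the *signed* measured ERP
#' amplitude: alpha enhances Go P3b (+), beta deepens Go N2c (-), pink noise
#' deepens No-Go N1b (-) and shrinks No-Go N1c (+).
#'
#' @param strength coupling strength (default 0.5).
#' @return data frame of couplings.
#' @export
default_couplings <- function(strength = 0.5) {
  data.frame(
    source = c("A1", "B1", "pink", "pink"),
    target = c("go_P3b", "go_N2c", "nogo_N1b", "nogo_N1c"),
    sign = c(1, -1, -1, 1),
    strength = strength
  )
}

#' Generate the event table for a session
#'
#' Blocks of shuffled Go/No-Go tones at a fixed SOA; Go responses drawn from a
#' normal RT distribution truncated to `[100, 1000]` ms, with omissions at the
#' configured rate; commissions (No-Go responses) injected at their rate.
#'
#' @param config an [session_config()].
#' @param truth an [ground_truth()].
#' @param seed integer seed.
#' @param first_onset_sample sample index of the first stimulus onset.
#' @return data frame with columns `onset_sample`, `code` (`"go"`/`"nogo"`),
#'   `rt_ms` (`NA` if no response).
#' @export
generate_events <- function(config, truth, seed, first_onset_sample = NULL) {
  set.seed(seed)
  pre_pad <- 2 * config$fs  # room for the first prestimulus window
  first <- first_onset_sample %||% (pre_pad + 1L)
  codes <- unlist(lapply(seq_len(config$n_blocks), function(b) {
    sample(rep(c("go", "nogo"), c(config$n_go_per_block, config$n_nogo_per_block)))
  }))
  n <- length(codes)
  onsets <- first + (seq_len(n) - 1L) * config$soa_samples
  rtrunc_norm <- function(k, mean, sd, lo = 100, hi = 1000) {
    plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
    stats::qnorm(stats::runif(k, plo, phi), mean, sd)
  }
  rt <- rep(NA_real_, n)
  is_go <- codes == "go"
  respond_go <- is_go & stats::runif(n) >= truth$omission_rate
  rt[respond_go] <- rtrunc_norm(sum(respond_go), truth$rt_mean_ms, truth$rt_sd_ms)
  commit <- !is_go & stats::runif(n) < truth$commission_rate
  rt[commit] <- rtrunc_norm(sum(commit), truth$rt_mean_ms, truth$rt_sd_ms)
  data.frame(onset_sample = onsets, code = codes, rt_ms = rt)
}

band_topo <- function(truth, i, n_channels) {
  make_topography(n_channels, truth$bands$topo_centre[i] %||% 0.5,
                  truth$bands$topo_width[i] %||% 0.25)
}

erp_topo <- function(truth, i, n_channels) {
  make_topography(n_channels, truth$erps$topo_centre[i] %||% 0.5,
                  truth$erps$topo_width[i] %||% 0.25)
}

#' Generate a complete synthetic EEG session
#'
#' The continuous recording is the sample-for-sample sum of four parts:
#' band-limited oscillations (Gaussian-noise-driven 4th-order Butterworth
#' band-pass latents, one latent per band, spread over channels by its
#' topography), pink noise and white noise (independent per channel), and ERP
#' templates (sums of Gaussian-windowed deflections) inserted at stimulus
#' onsets. For each coupling, the target template's amplitude on trial k is
#' scaled by `1 + sign(template) * coupling_sign * strength * z_k`, where `z_k`
#' standardises the prestimulus (-500..0 ms) RMS amplitude of the source with
#' the cohort-level reference moments frozen in the truth object.
#'
#' @param config an [session_config()].
#' @param truth an [ground_truth()].
#' @param seed master seed for this session (default `config$seed`).
#' @param return_parts if `TRUE`, the four additive parts are attached.
#' @return list of class `oscdyn_session` with `recording` (list: `data`
#'   channels x samples matrix in microvolts, `fs`, `channels`), `events`,
#'   `truth`, `trial_scales` (per-trial coupling internals), and optionally
#'   `parts`.
#' @export
generate_session <- function(config, truth, seed = config$seed, return_parts = FALSE) {
  nch <- config$n_channels
  fs <- config$fs
  events <- generate_events(config, truth, derive_seed(seed, "events"))
  n_trials <- nrow(events)
  n <- max(events$onset_sample) + config$soa_samples + 2L * fs
  n <- stats::nextn(n, c(2, 3, 5))  # composite length keeps the synthesis FFTs fast

  pink <- matrix(0, nch, n)
  white <- matrix(0, nch, n)
  ptopo <- truth$pink_topo %||% rep(1, nch)
  wtopo <- truth$white_topo %||% rep(1, nch)
  for (c in seq_len(nch)) {
    pink[c, ] <- generate_pink_noise(n, fs, truth$pink_power_at_1hz * ptopo[c],
                                     derive_seed(seed, paste0("pink/", c)))
    white[c, ] <- generate_white_noise(n, fs, truth$white_power * wtopo[c],
                                       derive_seed(seed, paste0("white/", c)))
  }

  osc <- matrix(0, nch, n)
  latents <- list()
  for (i in seq_len(nrow(truth$bands))) {
    b <- truth$bands[i, ]
    lo <- max(b$centre_hz - b$bandwidth_hz / 2, 0.5)
    hi <- min(b$centre_hz + b$bandwidth_hz / 2, fs / 2 * 0.95)
    set.seed(derive_seed(seed, paste0("band/", b$name)))
    drive <- stats::rnorm(n)
    filt <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
    lat <- signal::filtfilt(filt, drive)
    lat <- lat / stats::sd(lat)  # unit-RMS latent
    latents[[b$name]] <- lat
    osc <- osc + (b$rms_uv * band_topo(truth, i, nch)) %o% lat
  }

  # trial-wise standardized prestimulus source amplitudes for couplings
  win <- round(0.5 * fs)                      # [-500, 0) ms
  pres <- function(series, k) {
    idx <- (events$onset_sample[k] - win):(events$onset_sample[k] - 1L)
    v <- series[idx]
    sqrt(mean((v - mean(v))^2))
  }
  # spectral mass factor converting sqrt(p) to an expected pink window RMS
  kgrid <- seq_len(n %/% 2L) * fs / n
  pink_mass <- sqrt(sum(1 / kgrid[kgrid >= 1] * fs / n))

  trial_scales <- NULL
  erp_scale <- matrix(1, n_trials, nrow(truth$erps))  # multiplicative per template
  if (!is.null(truth$couplings) && nrow(truth$couplings) > 0) {
    rows <- list()
    for (j in seq_len(nrow(truth$couplings))) {
      cp <- truth$couplings[j, ]
      if (cp$source == "pink") {
        # pooled-channel prestimulus RMS of the pink part
        a <- vapply(seq_len(n_trials), function(k) {
          idx <- (events$onset_sample[k] - win):(events$onset_sample[k] - 1L)
          seg <- pink[, idx, drop = FALSE]
          seg <- seg - rowMeans(seg)
          sqrt(mean(seg^2))
        }, numeric(1))
        m_ref <- truth$coupling_ref[["pink"]] * pink_mass * sqrt(mean(ptopo))
      } else {
        bi <- match(cp$source, truth$bands$name)
        a <- truth$bands$rms_uv[bi] *
          vapply(seq_len(n_trials), function(k) pres(latents[[cp$source]], k), numeric(1))
        m_ref <- truth$coupling_ref[[cp$source]]
      }
      z <- (a - m_ref) / (truth$coupling_rel_sd * m_ref)
      ti <- match(cp$target, paste0(truth$erps$condition, "_", truth$erps$name))
      amp_sign <- sign(truth$erps$amplitude_uv[ti])
      sc <- 1 + cp$sign * amp_sign * cp$strength * z
      erp_scale[, ti] <- erp_scale[, ti] * sc
      rows[[j]] <- data.frame(trial = seq_len(n_trials), source = cp$source,
                              target = cp$target, amplitude = a, z = z, scale = sc)
    }
    trial_scales <- do.call(rbind, rows)
  }

  erp <- matrix(0, nch, n)
  for (i in seq_len(nrow(truth$erps))) {
    e <- truth$erps[i, ]
    topo <- erp_topo(truth, i, nch)
    sd_samp <- e$width_ms * fs / 1000
    lat_samp <- e$latency_ms * fs / 1000
    half <- ceiling(4 * sd_samp)
    rel <- (-half):(half)
    g <- exp(-((rel - 0)^2) / (2 * sd_samp^2))
    for (k in which(events$code == e$condition)) {
      centre <- events$onset_sample[k] + round(lat_samp)
      idx <- centre + rel
      keep <- idx >= 1 & idx <= n
      add <- (e$amplitude_uv * erp_scale[k, i] * topo) %o% g[keep]
      erp[, idx[keep]] <- erp[, idx[keep]] + add
    }
  }

  data <- osc + pink + white + erp
  out <- list(
    recording = list(data = data, fs = fs, channels = config$channels),
    events = events, truth = truth, config = config,
    trial_scales = trial_scales
  )
  if (return_parts) out$parts <- list(oscillation = osc, pink = pink,
                                      white = white, erp = erp)
  class(out) <- "oscdyn_session"
  out
}

#' Jittered per-participant ground truths for a cohort
#'
#' Between-participant variability is log-normal jitter (sd `jitter_sd` on the
#' log scale) applied independently to every amplitude-scale quantity: band RMS
#' amplitudes, ERP peak amplitudes, and the pink/white noise *amplitudes*
#' (their powers are jittered by the squared multiplier). Coupling reference
#' moments stay at the base values so planted couplings generate
#' between-participant linkage.
#'
#' @param base_truth the base [ground_truth()].
#' @param n_participants cohort size.
#' @param master_seed integer master seed.
#' @param jitter_sd log-scale SD of the amplitude jitter.
#' @return list of `oscdyn_truth` objects, one per participant.
#' @export
cohort_truths <- function(base_truth, n_participants, master_seed, jitter_sd = 0.2) {
  lapply(seq_len(n_participants), function(i) {
    set.seed(derive_seed(master_seed, paste0("jitter/", i)))
    t_i <- base_truth
    t_i$pink_power_at_1hz <- base_truth$pink_power_at_1hz *
      exp(stats::rnorm(1, 0, jitter_sd))^2
    t_i$white_power <- base_truth$white_power * exp(stats::rnorm(1, 0, jitter_sd))^2
    t_i$bands$rms_uv <- base_truth$bands$rms_uv *
      exp(stats::rnorm(nrow(base_truth$bands), 0, jitter_sd))
    t_i$erps$amplitude_uv <- base_truth$erps$amplitude_uv *
      exp(stats::rnorm(nrow(base_truth$erps), 0, jitter_sd))
    t_i  # coupling_ref untouched: frozen at base
  })
}
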