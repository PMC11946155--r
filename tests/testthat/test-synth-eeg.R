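test_that("pink noise has 1/f power and zero-power gives silence", {
  expect_identical(generate_pink_noise(100, 1000, 0, 1), numeric(100))
  expect_error(generate_pink_noise(1, 1000, 1, 1), "n_samples")
  expect_error(generate_pink_noise(100, 1000, -1, 1), "power")

  n <- 2^16; fs <- 1000
  slope <- periodogram_slope(function(s) generate_pink_noise(n, fs, 4, s),
                             n, fs, n_seeds = 50, f_lo = 2, f_hi = 100)
  expect_lt(abs(slope - (-1)), 0.05)

  # direct 1/f ratio: power at 2 Hz ~ 2x power at 4 Hz after 100 realizations
  ps <- 0
  for (s in 1:100) ps <- ps + one_sided_periodogram(generate_pink_noise(n, fs, 4, s), fs)
  ps <- ps / 100
  f <- seq_along(ps) * fs / n
  p2 <- mean(ps[abs(f - 2) < 0.25]); p4 <- mean(ps[abs(f - 4) < 0.25])
  expect_lt(abs(p2 / p4 - 2) / 2, 0.10)
})

test_that("white noise variance matches its one-sided PSD and is flat", {
  expect_identical(generate_white_noise(50, 1000, 0, 1), numeric(50))
  x <- generate_white_noise(1e6, 1000, 1, 1)
  expect_lt(abs(var(x) - 500) / 500, 0.05)
  n <- 2^15
  slope <- periodogram_slope(function(s) generate_white_noise(n, 1000, 1, s),
                             n, 1000, n_seeds = 50, f_lo = 2, f_hi = 100)
  expect_lt(abs(slope), 0.05)
})

test_that("noiseless session reconstructs its ERP template", {
  cfg <- session_config(n_channels = 2, fs = 500, n_go_per_block = 10,
                        n_nogo_per_block = 10, n_blocks = 1)
  erps <- data.frame(name = "P3", condition = "go", latency_ms = 300,
                     width_ms = 40, amplitude_uv = 10,
                     topo_centre = 0.5, topo_width = 0.25)
  tr <- ground_truth(pink_power_at_1hz = 0, white_power = 0,
                     bands = default_bands()[0, ], erps = erps,
                     omission_rate = 0, commission_rate = 0)
  s <- generate_session(cfg, tr, seed = 3)
  ep <- extract_epochs(s$recording, s$events)
  go <- ep$data[ep$condition == "go", , , drop = FALSE]
  avg <- apply(go, c(2, 3), mean)
  topo <- make_topography(2, 0.5, 0.25)
  i300 <- which(ep$time_ms == 300)
  expect_equal(avg[1, i300], 10 * topo[1], tolerance = 1e-6)
  expect_equal(ep$time_ms[which.max(avg[1, ])], 300)
})

test_that("event table has the configured trial count and exact SOA spacing", {
  cfg <- session_config()  # 2 blocks x (75 + 75)
  ev <- generate_events(cfg, ground_truth(), seed = 9)
  expect_equal(nrow(ev), 300)
  expect_true(all(diff(ev$onset_sample) == cfg$soa_samples))
  expect_equal(sum(ev$code == "go"), 150)
})

test_that("the recording is the exact sum of its generated parts", {
  cfg <- session_config(n_channels = 3, fs = 250, n_go_per_block = 10,
                        n_nogo_per_block = 10, n_blocks = 1)
  tr <- ground_truth()
  s <- generate_session(cfg, tr, seed = 4, return_parts = TRUE)
  total <- s$parts$oscillation + s$parts$pink + s$parts$white + s$parts$erp
  expect_equal(s$recording$data, total, tolerance = 0)
  # the pink part alone is reproduced by the same derived seed
  pink1 <- generate_pink_noise(ncol(s$recording$data), cfg$fs,
                               tr$pink_power_at_1hz,
                               derive_seed(4, "pink/1"))
  expect_equal(s$parts$pink[1, ], pink1, tolerance = 0)
})

test_that("prestimulus spectrum matches pink + white ground truth off the bands", {
  cfg <- session_config(n_channels = 1, fs = 250, n_go_per_block = 220,
                        n_nogo_per_block = 220, n_blocks = 1)
  bands <- data.frame(name = c("TA", "A1", "AB"), centre_hz = c(8, 10, 15),
                      bandwidth_hz = c(2, 2, 3), rms_uv = c(2.5, 4, 2),
                      topo_centre = 0.5, topo_width = 0.25)
  tr <- ground_truth(bands = bands, omission_rate = 0, commission_rate = 0)
  s <- generate_session(cfg, tr, seed = 12)
  ep <- extract_epochs(s$recording, s$events)  # raw, unfiltered
  sp <- epoch_spectra(ep)
  pw <- apply(sp, c(2, 3), mean)[1, ]^2
  freq <- attr(sp, "freq_hz")
  kap <- noise_measurement_gain(round(0.5 * cfg$fs), cfg$fs)
  model <- kap * (tr$pink_power_at_1hz / pmax(freq, 1) + tr$white_power)
  off_band <- freq %in% c(2:5, 20:24)  # bands (+smearing) live in 6..19
  expect_true(all(abs(pw[off_band] / model[off_band] - 1) < 0.15))
  # band centres carry clear extra power
  expect_true(all(pw[freq %in% c(8, 10)] > 1.5 * model[freq %in% c(8, 10)]))
})

test_that("planted couplings scale single-trial ERP templates with the prestimulus source", {
  cfg <- session_config(n_channels = 2, fs = 250, n_go_per_block = 75,
                        n_nogo_per_block = 75, n_blocks = 1)
  tr <- ground_truth(couplings = data.frame(
    source = "A1", target = "go_P3b", sign = 1, strength = 0.5))
  for (seed in 1:5) {
    s <- generate_session(cfg, tr, seed = seed)
    sc <- s$trial_scales
    # internal: source amplitude and scale are positively related
    expect_gt(cor(sc$amplitude, sc$scale), 0.3)
    # external: alpha amplitude measured from the recording itself
    bf <- signal::butter(4, c(8, 12) / (cfg$fs / 2), type = "pass")
    alpha <- signal::filtfilt(bf, s$recording$data[2, ])
    win <- round(0.5 * cfg$fs)
    a_meas <- vapply(seq_len(nrow(s$events)), function(k) {
      idx <- (s$events$onset_sample[k] - win):(s$events$onset_sample[k] - 1)
      sqrt(mean(alpha[idx]^2))
    }, numeric(1))
    expect_gt(cor(a_meas, sc$scale), 0.3)
  }
})

test_that("unknown coupling targets and invalid configs are rejected", {
  expect_error(ground_truth(couplings = data.frame(
    source = "A1", target = "go_NOPE", sign = 1, strength = 0.5)), "target")
  expect_error(ground_truth(couplings = data.frame(
    source = "gamma", target = "go_P3b", sign = 1, strength = 0.5)), "source")
  expect_error(session_config(soa_ms = 1100.5), "integer")
  expect_error(ground_truth(omission_rate = 1.2), "rates")
})

test_that("cohort truths jitter amplitudes but freeze coupling references", {
  base <- ground_truth()
  ts <- cohort_truths(base, 5, master_seed = 2, jitter_sd = 0.2)
  expect_length(ts, 5)
  p_vals <- vapply(ts, `[[`, numeric(1), "pink_power_at_1hz")
  expect_gt(sd(log(p_vals)), 0)
  for (t_i in ts) expect_identical(t_i$coupling_ref, base$coupling_ref)
})
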