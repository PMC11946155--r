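make_rec <- function(x, fs = 1000) list(data = matrix(x, nrow = 1), fs = fs,
                                        channels = "ch1")

test_that("band-pass passes 10 Hz untouched, stops 50 Hz and DC", {
  fs <- 1000
  t <- (0:19999) / fs
  x50 <- sin(2 * pi * 50 * t)
  y50 <- bandpass_filter(make_rec(x50))$data[1, ]
  expect_lt(sd(y50) / sd(x50), 0.05)

  x10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass_filter(make_rec(x10))$data[1, ]
  mid <- 5000:15000
  expect_lt(abs(sd(y10[mid]) / sd(x10[mid]) - 1), 0.05)
  # zero phase: cross-correlation peaks at lag 0
  cc <- stats::ccf(y10[mid], x10[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  ydc <- bandpass_filter(make_rec(rep(5, 20000)))$data[1, ]
  expect_lt(max(abs(ydc)), 1e-9)

  expect_error(bandpass_filter(make_rec(x10), lo = 0.1, hi = 600), "Nyquist|fs/2")
  expect_equal(length(y10), 20000)  # length preserved
})

test_that("trial validity follows the closed 100-500 ms window and prestimulus rule", {
  fs <- 1000
  ev <- data.frame(onset_sample = c(3000, 4100, 5200, 6300, 7400),
                   code = c("go", "go", "nogo", "go", "nogo"),
                   rt_ms = c(340, 520, NA, 100, NA))
  v <- classify_trials(ev, soa_ms = 1100, fs = fs)
  expect_true(v[1])        # valid go at 340 ms
  expect_false(v[2])       # late press invalidates this go trial
  expect_true(v[3])        # clean nogo
  expect_true(v[4])        # boundary: 100 ms counts as inside (closed)
  expect_true(v[5])        # clean nogo
  # nogo with a press in its interstimulus period is an invalid commission
  ev_c <- data.frame(onset_sample = c(3000, 4100), code = c("nogo", "nogo"),
                     rt_ms = c(700, NA))
  vc <- classify_trials(ev_c, 1100, fs)
  expect_false(vc[1])
  expect_false(vc[2])      # that press also lands in trial 2's prestim window
  # boundary 500 ms is inside, but contaminates the next prestimulus window
  ev2 <- data.frame(onset_sample = c(3000, 4100), code = c("go", "go"),
                    rt_ms = c(500, 300))
  v2 <- classify_trials(ev2, 1100, fs)
  expect_true(v2[1])
  expect_true(v2[2])  # press at 3500 is 600 ms before onset 4100: outside
  ev3 <- data.frame(onset_sample = c(3000, 4100), code = c("go", "go"),
                    rt_ms = c(700, 300))
  expect_false(classify_trials(ev3, 1100, fs)[2])  # 700 ms press -> prestim hit
  expect_error(classify_trials(data.frame(onset_sample = c(100, 100),
                                          code = c("go", "go"),
                                          rt_ms = c(NA, NA)), 1100, fs),
               "increasing")
})

test_that("epoch extraction yields the half-open window with exact sample counts", {
  fs <- 1000
  rec <- list(data = matrix(seq_len(10000), nrow = 1), fs = fs, channels = "a")
  ev <- data.frame(onset_sample = 5000, code = "go", rt_ms = 300)
  ep <- extract_epochs(rec, ev)
  expect_equal(dim(ep$data), c(1, 1, 1000))
  expect_equal(range(ep$time_ms), c(-500, 499))
  expect_equal(sum(ep$time_ms >= -500 & ep$time_ms < 0), 500)
  expect_error(extract_epochs(rec, data.frame(onset_sample = 10, code = "go",
                                              rt_ms = NA)), "bounds")
})

test_that("artifact rules reject by the stated thresholds in the stated order", {
  ep <- constructed_artifact_epochs()
  # single epochs for each rule
  one <- epochs_subset(ep, 1)
  expect_equal(reject_artifacts(one)$reason, "extreme")  # also jumps; order wins
  one <- epochs_subset(ep, 13)
  expect_equal(reject_artifacts(one)$reason, "jump")
  one <- epochs_subset(ep, 28)
  expect_equal(reject_artifacts(one)$reason, "flat")
  # an epoch identically zero everywhere is flat
  z <- epochs_subset(ep, 50)
  z$data[] <- 0
  expect_equal(reject_artifacts(z)$reason, "flat")
  expect_error(reject_artifacts(epochs_subset(ep, 1), flat_win_ms = 2000), "epoch")
})

test_that("rejection counts on the constructed fixture match the construction exactly", {
  ep <- reject_artifacts(constructed_artifact_epochs())
  counts <- attr(ep, "rejection_counts")
  expect_equal(unname(counts["extreme"]), 12)
  expect_equal(unname(counts["jump"]), 15)
  expect_equal(unname(counts["flat"]), 8)
  expect_equal(unname(counts["none"]), 65)
})

test_that("epoch-count matching subsamples reproducibly and flags exclusion", {
  ep <- constructed_artifact_epochs()
  go <- epochs_subset(ep, which(ep$condition == "go"))    # 50 trials
  nogo <- epochs_subset(ep, which(ep$condition == "nogo"))
  nogo_small <- epochs_subset(nogo, 1:38)
  m <- match_epoch_counts(go, nogo_small, min_trials = 30, seed = 7)
  expect_false(m$excluded)
  expect_equal(dim(m$go$data)[1], 38)
  expect_equal(dim(m$nogo$data)[1], 38)
  expect_true(all(m$go$condition == "go"))  # labels preserved
  # determinism
  m2 <- match_epoch_counts(go, nogo_small, min_trials = 30, seed = 7)
  expect_identical(m$go$data, m2$go$data)
  # below threshold -> excluded
  m3 <- match_epoch_counts(epochs_subset(go, 1:20), nogo, min_trials = 30)
  expect_true(m3$excluded)
  # equal counts unchanged
  m4 <- match_epoch_counts(go, nogo, min_trials = 30, seed = 1)
  expect_identical(m4$go$data, go$data)
})
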