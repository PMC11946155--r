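test_that("an exact predictor is selected alone with beta 1 and R^2 1", {
  set.seed(2)
  X <- data.frame(x1 = rnorm(40), x2 = rnorm(40), x3 = rnorm(40), x4 = rnorm(40))
  y <- X$x1
  r <- suppressWarnings(stepwise_regress(X, y))  # lm warns on a perfect fit
  expect_equal(r$selected, "x1")
  expect_equal(unname(r$beta["x1"]), 1, tolerance = 1e-9)
  expect_equal(r$r_squared, 1, tolerance = 1e-9)
})

test_that("threshold edge cases: never enter, full model, beta equals r", {
  set.seed(5)
  X <- data.frame(matrix(rnorm(47 * 4), 47, 4))
  y <- 0.5 * X[[1]] + rnorm(47)
  expect_length(stepwise_regress(X, y, p_enter = 0)$selected, 0)
  full <- stepwise_regress(X, y, p_enter = 1, p_remove = 1)
  expect_setequal(full$selected, names(X))

  r1 <- stepwise_regress(X[, 1, drop = FALSE], y, p_enter = 1, p_remove = 1)
  expect_equal(unname(r1$beta), cor(X[[1]], y), tolerance = 1e-9)
  # |t| and p are consistent with the residual df
  expect_equal(unname(r1$p), 2 * pt(abs(unname(r1$t)), 45, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("input validation: missing values, too few cases, duplicates", {
  X <- data.frame(a = c(1, 2, NA), b = 1:3)
  expect_error(stepwise_regress(X, 1:3), "missing")
  expect_error(stepwise_regress(data.frame(a = rnorm(5), b = rnorm(5),
                                           c = rnorm(5), d = rnorm(5)),
                                rnorm(5)), "few cases")
  Xd <- data.frame(a = rnorm(20), b = rnorm(20)); names(Xd) <- c("a", "a")
  expect_error(stepwise_regress(Xd, rnorm(20)), "duplicate")
})

test_that("the stepwise path matches an independent re-implementation", {
  for (s in 1:200) {
    set.seed(3000 + s)
    n <- 40; k <- 5
    X <- as.data.frame(matrix(rnorm(n * k), n, k))
    names(X) <- paste0("x", 1:k)
    beta <- c(0.6, 0.3, 0, 0, 0) * sample(c(-1, 1), k, replace = TRUE)
    y <- as.matrix(X) %*% beta + rnorm(n)
    got <- stepwise_regress(X, y)$selected
    want <- stepwise_oracle(X, y)
    expect_identical(got, want)
  }
})

test_that("null false-selection rate matches the direct simulation oracle", {
  # package implementation on one seeded stream of null datasets
  impl <- stepwise_null_rate(n_runs = 2000, n = 47, k = 7, seed = 11)
  # independent oracle implementation on a different stream
  set.seed(22)
  oracle_sel <- vapply(1:2000, function(r) {
    X <- as.data.frame(matrix(rnorm(47 * 7), 47, 7))
    names(X) <- paste0("x", 1:7)
    length(stepwise_oracle(X, rnorm(47))) > 0
  }, logical(1))
  expect_lt(abs(impl$rate - mean(oracle_sel)), 0.03)
})

test_that("a moderate true effect is selected with matching frequency and sign", {
  run_freq <- function(fun, seed0, n_runs = 600) {
    hits <- vapply(seq_len(n_runs), function(r) {
      set.seed(seed0 + r)
      X <- as.data.frame(matrix(rnorm(47 * 7), 47, 7))
      names(X) <- paste0("x", 1:7)
      y <- 0.4 * X$x2 + rnorm(47)
      sel <- fun(X, y)
      "x2" %in% sel
    }, logical(1))
    mean(hits)
  }
  f_impl <- run_freq(function(X, y) stepwise_regress(X, y)$selected, 5000)
  f_oracle <- run_freq(stepwise_oracle, 9000)
  expect_gt(f_impl, 0.5)             # selected in the majority of runs
  expect_lt(abs(f_impl - f_oracle), 0.05)
  # sign correctness when selected
  set.seed(5001)
  X <- as.data.frame(matrix(rnorm(47 * 7), 47, 7)); names(X) <- paste0("x", 1:7)
  y <- 0.4 * X$x2 + rnorm(47)
  r <- stepwise_regress(X, y)
  if ("x2" %in% r$selected) expect_gt(r$beta["x2"], 0)
})

test_that("the linkage suite wires predictors, ERPs and behaviour together", {
  set.seed(8)
  n <- 47
  pred <- data.frame(A1 = rnorm(n), B1 = rnorm(n), PN = rnorm(n))
  erp <- data.frame(go_P3b = 0.8 * pred$A1 + rnorm(n, 0, 0.5),
                    go_N2c = rnorm(n))
  beh <- data.frame(mean_rt_ms = -0.8 * erp$go_P3b + rnorm(n, 0, 0.5),
                    omission_pct = rnorm(n))
  out <- run_linkage_suite(pred, erp, beh)
  expect_named(out, c("primary", "secondary"))
  expect_true("A1" %in% out$primary$go_P3b$selected)
  expect_gt(out$primary$go_P3b$beta["A1"], 0)
  # go_P3b is EEG-affected, so it enters the secondary suite
  expect_true("go_P3b" %in% out$secondary$mean_rt_ms$selected)
  expect_lt(out$secondary$mean_rt_ms$beta["go_P3b"], 0)
  expect_error(run_linkage_suite(pred[1:10, ], erp, beh), "misaligned")
  td <- tidy_stepwise(out$primary)
  expect_true(all(c("dependent", "predictor", "beta", "t", "p") %in% names(td)))
})
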