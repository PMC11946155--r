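test_that("half-sampling keeps every second sample", {
  expect_length(half_sample(numeric(600)), 300)
  expect_equal(half_sample(rep(2, 10)), rep(2, 5))
  fs <- 1000; t <- (0:599) / fs
  x <- sin(2 * pi * 30 * t)
  expect_equal(half_sample(x), x[seq(1, 600, 2)], tolerance = 0)
  m <- matrix(1:20, 2, 10)
  expect_equal(half_sample(m), m[, c(1, 3, 5, 7, 9)])
})

test_that("covariance PCA: shares, reconstruction, closed-form toy case", {
  set.seed(1)
  X <- cbind(rnorm(50), 0, 0) + 5
  p <- pca_covariance(X)
  expect_equal(p$variance_pct[1], 100, tolerance = 1e-9)

  X2 <- matrix(rnorm(200), 40, 5)
  p2 <- pca_covariance(X2)
  recon <- p2$scores %*% t(p2$loadings)
  expect_lt(max(abs(recon - sweep(X2, 2, colMeans(X2)))), 1e-8)
  expect_equal(sum(p2$variance_pct), 100, tolerance = 1e-6)

  # toy covariance [[2,1],[1,2]]: eigenvalues 3 and 1, shares 75/25
  A <- matrix(c(2, 1, 1, 2), 2, 2)
  X3 <- MASS_free_mvn(1000, A)
  ev <- eigen(cov(X3), symmetric = TRUE)$values
  p3 <- pca_covariance(X3)
  expect_equal(p3$eigenvalues, ev, tolerance = 1e-12)
  expect_equal(p3$variance_pct, ev / sum(ev) * 100, tolerance = 1e-9)
  expect_error(pca_covariance(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("varimax preserves communalities, improves the criterion, matches the angle oracle", {
  set.seed(7)
  L <- matrix(rnorm(30), 10, 3)
  r <- rotate_varimax(L)
  expect_lt(max(abs(crossprod(r$rotmat) - diag(3))), 1e-8)
  expect_lt(max(abs(rowSums(r$loadings^2) - rowSums(L^2))), 1e-8)
  sc <- sqrt(rowSums(L^2))
  expect_gte(varimax_criterion(r$loadings / sc), varimax_criterion(L / sc) - 1e-12)

  # already varimax-optimal: rotation is identity up to sign/permutation
  L0 <- rbind(diag(c(2, 3)), matrix(0, 2, 2))
  r0 <- rotate_varimax(L0)
  expect_lt(align_loadings_diff(L0, r0$loadings), 1e-6)

  # two-factor textbook fixture against the 0.001-rad grid oracle
  # tighter convergence than the default so the comparison is limited by the
  # oracle grid, not by the iteration stop rule
  L2 <- matrix(c(0.8, 0.7, 0.3, 0.2,
                 0.3, 0.2, 0.8, 0.75), 4, 2)
  r2 <- rotate_varimax(L2, tol = 1e-10)
  oracle <- varimax_angle_oracle(L2)
  expect_lt(align_loadings_diff(oracle, r2$loadings), 1e-3)
})

test_that("promax returns a coherent oblique solution and recovers factor correlation", {
  # orthogonal simple structure: nothing to obliquify
  L <- rbind(diag(c(2, 3)), matrix(0, 4, 2)) + 0
  pm <- rotate_promax(L)
  expect_lt(max(abs(pm$Phi - diag(2))), 1e-6)
  expect_lt(align_loadings_diff(L, pm$pattern), 1e-6)

  # structure = pattern x Phi, diag(Phi) = 1, on an arbitrary solution
  set.seed(3)
  vm <- rotate_varimax(pca_covariance(matrix(rnorm(600), 100, 6))$loadings[, 1:3])
  pm2 <- rotate_promax(vm$loadings)
  expect_lt(max(abs(pm2$structure - pm2$pattern %*% pm2$Phi)), 1e-8)
  expect_equal(unname(diag(pm2$Phi)), rep(1, ncol(pm2$Phi)), tolerance = 1e-8)

  # planted factor correlation 0.5, two factors, 1000 cases, 20 seeds
  err <- vapply(1:20, function(s) {
    set.seed(s)
    Phi <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
    Fk <- matrix(rnorm(2000), 1000, 2) %*% chol(Phi)
    Lam <- rbind(cbind(runif(6, 0.7, 1), 0), cbind(0, runif(6, 0.7, 1)))
    X <- Fk %*% t(Lam) + matrix(rnorm(12000, 0, 0.3), 1000, 12)
    p <- pca_covariance(X)
    vmx <- rotate_varimax(p$loadings[, 1:2])
    pmx <- rotate_promax(vmx$loadings)
    abs(abs(pmx$Phi[1, 2]) - 0.5)
  }, numeric(1))
  expect_lt(median(err), 0.1)
})

test_that("promax degeneracy check on diag(Phi)", {
  set.seed(9)
  vm <- rotate_varimax(matrix(rnorm(40), 10, 4))
  pm <- rotate_promax(vm$loadings)
  expect_equal(unname(diag(pm$Phi)), rep(1, 4), tolerance = 1e-8)
})

test_that("component selection applies the variance cutoff in order", {
  expect_equal(select_components(c(40, 30, 10, 1.4)), c(1, 2, 3))
  expect_equal(select_components(c(10, 40, 2, 1.4), 1.5), c(2, 1, 3))
  expect_equal(select_components(c(40, 30, 10, 1.4), 0), c(1, 2, 3, 4))
  expect_length(select_components(c(1, 1.2), 1.5), 0)
})

test_that("component amplitudes: forward construction, zeros, linearity", {
  # single component: data = amplitude_case x unit temporal waveform
  set.seed(11)
  wave <- exp(-((1:50 - 25)^2) / 50)
  a <- rnorm(40, mean = 6)
  pid <- rep(1:20, each = 2)
  X <- a %o% wave
  p <- pca_covariance(X)
  amp <- component_amplitude(p$loadings, p$scores, pid, 1, centre = p$centre)
  truth <- tapply(a * max(wave), pid, mean)
  expect_equal(unname(amp[, 1]), as.numeric(truth[rownames(amp)]), tolerance = 1e-6)

  # all-zero scores give zero amplitude (no centre term supplied)
  amp0 <- component_amplitude(p$loadings, p$scores * 0, pid, 1)
  expect_true(all(amp0 == 0))

  # doubling the data doubles the amplitudes
  p2 <- pca_covariance(2 * X)
  amp2 <- component_amplitude(p2$loadings, p2$scores, pid, 1, centre = p2$centre)
  expect_equal(unname(amp2[, 1]), 2 * unname(amp[, 1]), tolerance = 1e-6)
  expect_error(component_amplitude(p$loadings, p$scores, pid, 99), "component")
})

test_that("planted spectral bands are recovered as selected f-PCA components", {
  hits <- vapply(1:20, function(s) {
    d <- simulate_oscillation_cases(seed = s)
    sol <- fpca(d$X, d$participant)
    all(vapply(c(2, 8, 10, 15, 25), function(c0)
      any(abs(sol$peak_hz - c0) <= 1), logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("three well-separated planted bands give a three-component selection", {
  counts <- vapply(1:20, function(s) {
    d <- simulate_oscillation_cases(centres_hz = c(4, 12, 22),
                                    widths_hz = c(1, 1, 1),
                                    amps_uv = c(3, 4, 3), seed = s)
    sol <- fpca(d$X, d$participant)
    ok <- all(vapply(c(4, 12, 22), function(c0)
      any(abs(sol$peak_hz - c0) <= 1), logical(1)))
    if (ok) length(sol$selected) else NA_integer_
  }, integer(1))
  expect_true(all(!is.na(counts)))
  expect_gte(mean(counts == 3), 0.9)
  expect_true(all(counts <= 4))
})

test_that("planted ERP deflection latencies are recovered by the temporal PCA", {
  lat <- c(100, 145, 240, 330, 450)
  res <- vapply(1:20, function(s) {
    d <- simulate_erp_cases(seed = s)
    sol <- tpca(d$X, d$participant, d$time_ms)
    pk <- sol$peak_ms[sol$selected]
    c(planted = all(vapply(lat, function(l0) any(abs(pk - l0) <= 10), logical(1))),
      strict = all(vapply(pk, function(p0) any(abs(lat - p0) <= 10), logical(1))))
  }, logical(2))
  expect_gte(mean(res["planted", ]), 0.9)
  expect_gte(mean(res["strict", ]), 0.9)
})
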