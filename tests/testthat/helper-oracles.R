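# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive and separate from the package's implementations.

# Brute-force lattice maximiser for the constrained pink+white fit: scans a
# 2000 x 2000 (p, w) lattice (vectorised over p via the per-w feasibility
# bound) and returns the best feasible lattice point.
lattice_noise_fit <- function(S, f, n_grid = 2000) {
  csum <- sum(1 / f)
  nb <- length(f)
  p_max <- min(S * f)
  w_max <- min(S)
  p_grid <- seq(0, p_max, length.out = n_grid)
  w_grid <- seq(0, w_max, length.out = n_grid)
  dp <- if (n_grid > 1) p_grid[2] - p_grid[1] else 0
  best <- list(obj = -Inf, p = 0, w = 0)
  for (w in w_grid) {
    pmax_w <- min((S - w) * f)
    if (pmax_w < 0) next
    p <- p_grid[max(1, findInterval(pmax_w + 1e-15, p_grid))]
    obj <- p * csum + w * nb
    if (obj > best$obj) best <- list(obj = obj, p = p, w = w)
  }
  best$resolution_bound <- dp * csum + (w_grid[2] - w_grid[1]) * nb
  best
}

# Random non-negative power spectrum on 1..30 Hz: pink + white + 0-3 bumps,
# multiplicative noise.
random_power_spectrum <- function(seed) {
  set.seed(seed)
  f <- 1:30
  S <- runif(1, 0, 20) / f + runif(1, 0, 4)
  for (b in seq_len(sample(0:3, 1))) {
    S <- S + runif(1, 0, 8) * exp(-((f - runif(1, 4, 26))^2) / (2 * runif(1, 0.5, 2)^2))
  }
  S * abs(1 + 0.3 * rnorm(length(f)))
}

# Exhaustive single-angle Varimax for two factors: grid search over the
# rotation angle at 0.001 rad resolution (with Kaiser normalisation to match
# the implementation's criterion).
varimax_angle_oracle <- function(L, normalize = TRUE) {
  sc <- sqrt(rowSums(L^2))
  Ln <- if (normalize) L / sc else L
  th_grid <- seq(0, pi / 2, by = 0.0002)
  vals <- vapply(th_grid, function(th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    varimax_criterion(Ln %*% R)
  }, numeric(1))
  th <- th_grid[which.max(vals)]
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  if (normalize) (Ln %*% R) * sc else L %*% R
}

# Align columns of B to A up to permutation and sign; returns max abs
# elementwise difference after the best alignment.
align_loadings_diff <- function(A, B) {
  k <- ncol(A)
  perms <- function(v) if (length(v) == 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  best <- Inf
  for (pm in perms(seq_len(k))) {
    d <- max(abs(A - sweep(B[, pm, drop = FALSE], 2,
                           sign(colSums(A * B[, pm, drop = FALSE])) , "*")))
    best <- min(best, d)
  }
  best
}

# Independent re-implementation of the forward-entry / backward-removal
# stepwise path (same rules, different code).
stepwise_oracle <- function(X, y, p_enter = 0.05, p_remove = 0.10, max_iter = 50) {
  X <- as.matrix(X)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(ncol(X)))
  colnames(X) <- nm
  included <- character(0)
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    avail <- setdiff(nm, included)
    if (length(avail)) {
      ps <- vapply(avail, function(v) {
        d <- data.frame(y = y, X[, c(included, v), drop = FALSE])
        co <- summary(stats::lm(y ~ ., data = d))$coefficients
        if (!(v %in% rownames(co))) Inf else co[v, 4]
      }, numeric(1))
      if (min(ps) <= p_enter) {
        included <- c(included, avail[which.min(ps)])
        changed <- TRUE
      }
    }
    if (length(included)) {
      d <- data.frame(y = y, X[, included, drop = FALSE])
      co <- summary(stats::lm(y ~ ., data = d))$coefficients
      pv <- vapply(included, function(v)
        if (v %in% rownames(co)) co[v, 4] else Inf, numeric(1))
      if (max(pv) > p_remove) {
        included <- setdiff(included, included[which.max(pv)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  included
}

# Welch-style averaged periodogram slope on log-log axes over [f_lo, f_hi].
periodogram_slope <- function(gen, n, fs, n_seeds, f_lo, f_hi) {
  ps <- 0
  for (s in seq_len(n_seeds)) ps <- ps + one_sided_periodogram(gen(s), fs)
  ps <- ps / n_seeds
  f <- seq_along(ps) * fs / n
  sel <- f >= f_lo & f <= f_hi
  unname(stats::coef(stats::lm(log(ps[sel]) ~ log(f[sel])))[2])
}

one_sided_periodogram <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  2 * Mod(X[2:(n %/% 2 + 1)])^2 / (fs * n)
}

# small multivariate-normal sampler (keeps the tests dependency-free)
MASS_free_mvn <- function(n, Sigma) {
  matrix(rnorm(n * ncol(Sigma)), n) %*% chol(Sigma)
}

# 100 constructed epochs with known artifact violations: 12 extreme (2 of
# which also contain a >50 uV jump -- order must record "extreme"), 15 jump,
# 8 flat, 65 clean. Baseline: 1 uV 7 Hz sinusoid on both channels.
constructed_artifact_epochs <- function() {
  fs <- 1000
  nt <- 1000
  t <- (seq_len(nt) - 1) / fs
  base <- sin(2 * pi * 7 * t)
  data <- array(rep(base, each = 100 * 2), c(100, 2, nt))
  for (k in 1:12) data[k, 1, 500] <- 130                  # extreme
  for (k in 1:2) data[k, 2, 300] <- data[k, 2, 299] + 60  # extreme + jump
  for (k in 13:27) data[k, 2, 400] <- data[k, 2, 399] + 60  # jump only
  for (k in 28:35) data[k, 1, 201:360] <- data[k, 1, 201]   # 160 ms hold: flat
  structure(list(
    data = data, time_ms = -500 + (seq_len(nt) - 1),
    condition = rep(c("go", "nogo"), 50), valid = rep(TRUE, 100),
    reason = rep("none", 100), fs = fs
  ), class = "oscdyn_epochs")
}
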