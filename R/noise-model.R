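#' Fit the constrained pink + white noise model to a power spectrum
#'
#' The noise model is pink noise with power `p / f` plus white noise with
#' uniform power `w` per bin. Validity requires the oscillation residual
#' `S(f) - p/f - w` to be non-negative at every integer bin of the fit range,
#' so that subtraction can never produce (physically impossible) negative
#' oscillation power. Among all valid `(p, w)` the fit returns the pair
#' maximising the total extracted noise `sum(p/f + w)` over the fit range.
#'
#' With `x = 1/f` this is a two-variable linear program: maximise
#' `p * sum(1/f) + w * n_bins` subject to `p >= 0`, `w >= 0`,
#' `p/f + w <= S(f)`. It is solved exactly by vertex enumeration: lines
#' through every pair of spectrum points in `(1/f, S)` space, plus the two
#' single-constraint axis candidates (`p = 0, w = min S`;
#' `w = 0, p = min S(f) * f`). Ties are broken toward larger `w`.
#'
#' @param power_spectrum numeric vector of power (microvolt^2) per 1-Hz bin;
#'   element i is the bin at `freq_hz[i]`.
#' @param freq_hz integer bin frequencies matching `power_spectrum`. Defaults
#'   to `1:length(power_spectrum)` i.e. a spectrum starting at 1 Hz.
#' @param fit_lo,fit_hi fit range in Hz (defaults 2 and 24).
#' @return list of class `oscdyn_noisefit`: `p` (pink power at 1 Hz), `w`
#'   (white power per bin), `fit_freq`, `residuals` (per fit bin, always
#'   `>= -1e-9`), `support` (bins where the residual is numerically zero),
#'   `objective`.
#' @export
fit_pink_white <- function(power_spectrum, freq_hz = seq_along(power_spectrum),
                           fit_lo = 2, fit_hi = 24) {
  sel <- freq_hz >= fit_lo & freq_hz <= fit_hi
  if (!any(sel)) stop("empty fit range", call. = FALSE)
  S <- power_spectrum[sel]
  f <- freq_hz[sel]
  if (any(S < 0)) stop("negative input power", call. = FALSE)
  x <- 1 / f
  csum <- sum(x)          # objective weight on p
  nb <- length(f)         # objective weight on w
  eps <- 1e-9

  cand_p <- c(0, min(S * f))
  cand_w <- c(min(S), 0)
  if (nb >= 2) {
    ij <- utils::combn(nb, 2)
    dx <- x[ij[1, ]] - x[ij[2, ]]
    ok <- abs(dx) > 1e-12
    p2 <- (S[ij[1, ok]] - S[ij[2, ok]]) / dx[ok]
    w2 <- S[ij[1, ok]] - p2 * x[ij[1, ok]]
    cand_p <- c(cand_p, p2)
    cand_w <- c(cand_w, w2)
  }
  keep <- cand_p >= -eps & cand_w >= -eps
  cand_p <- pmax(cand_p[keep], 0)
  cand_w <- pmax(cand_w[keep], 0)
  # feasibility: p * x + w <= S at every bin. The absolute slack keeps
  # vertex-construction roundoff feasible while guaranteeing residuals
  # >= -1e-9 everywhere in the fit range.
  feas <- vapply(seq_along(cand_p), function(i) {
    all(cand_p[i] * x + cand_w[i] <= S + 5e-10)
  }, logical(1))
  cand_p <- cand_p[feas]; cand_w <- cand_w[feas]
  if (length(cand_p) == 0) stop("no feasible noise fit found", call. = FALSE)
  obj <- cand_p * csum + cand_w * nb
  best <- which(obj > max(obj) - 1e-12 * max(1, max(obj)))
  best <- best[which.max(cand_w[best])]  # tie-break toward larger w
  p <- cand_p[best]; w <- cand_w[best]
  res <- S - p * x - w
  structure(list(
    p = p, w = w, fit_freq = f, residuals = res,
    support = f[abs(res) <= 1e-6 * pmax(S, 1)],
    objective = p * csum + w * nb
  ), class = "oscdyn_noisefit")
}

#' Evaluate the fitted noise model over a frequency range
#'
#' @param fit an `oscdyn_noisefit`.
#' @param lo,hi integer bin range in Hz (defaults 1 and 30); `lo >= 1`
#'   because `1/f` is undefined at 0.
#' @return data frame with `freq_hz`, `pn_power`, `wn_power` (microvolt^2)
#'   and `pn_amplitude`, `wn_amplitude` (microvolts).
#' @export
extend_noise <- function(fit, lo = 1, hi = 30) {
  if (lo < 1) stop("lo must be >= 1 (1/f undefined at 0)", call. = FALSE)
  f <- seq(lo, hi)
  data.frame(freq_hz = f,
             pn_power = fit$p / f, wn_power = rep(fit$w, length(f)),
             pn_amplitude = sqrt(fit$p / f), wn_amplitude = sqrt(rep(fit$w, length(f))))
}

#' Subtract fitted noise from an observed amplitude spectrum
#'
#' Subtraction is in the power domain (power is additive across independent
#' processes): `osc_power = max(S^2 - pn_power - wn_power, 0)`. Inside the fit
#' range the validity constraint guarantees clipping never activates beyond
#' numerical epsilon; outside it (e.g. 1 Hz and 25-30 Hz) clipped bins are
#' counted.
#'
#' @param observed_amplitude amplitude spectrum in microvolts per bin.
#' @param freq_hz bin frequencies for `observed_amplitude`.
#' @param noise data frame from [extend_noise()].
#' @return list: `freq_hz`, `osc_amplitude` (microvolts), `osc_power`,
#'   `clipped` (logical per bin), `n_clipped`.
#' @export
subtract_noise <- function(observed_amplitude, freq_hz, noise) {
  idx <- match(freq_hz, noise$freq_hz)
  if (anyNA(idx)) stop("bin mismatch between spectrum and noise model", call. = FALSE)
  pw <- observed_amplitude^2 - noise$pn_power[idx] - noise$wn_power[idx]
  clipped <- pw < -1e-9
  pw <- pmax(pw, 0)
  list(freq_hz = freq_hz, osc_amplitude = sqrt(pw), osc_power = pw,
       clipped = clipped, n_clipped = sum(clipped))
}

#' Expected measured bin power per unit of true one-sided PSD
#'
#' The amplitude-spectrum estimator is calibrated for deterministic tones
#' (coherent-gain correction). For a stochastic process of one-sided PSD `v`,
#' the *average amplitude* at a bin converges to the Rayleigh mean, so the
#' squared mean amplitude is `kappa * v` with
#' `kappa = (pi/2) * fs * mean(w^2) / (n * mean(w)^2)`
#' (window power gain over squared coherent gain, times the fs/n resolution
#' factor, times the Rayleigh pi/4). Use this to convert fitted noise powers
#' back to generator PSD units.
#'
#' @param n epoch length in samples before padding.
#' @param fs sampling rate in Hz.
#' @param taper_fraction taper fraction of the analysis window.
#' @return scalar gain `kappa` (measured power per unit PSD).
#' @export
noise_measurement_gain <- function(n, fs, taper_fraction = 0.10) {
  w <- taper_window(n, taper_fraction)
  (pi / 2) * fs * mean(w^2) / (n * mean(w)^2)
}

#' Unconstrained aperiodic baseline fit (negative-power demonstration)
#'
#' Fits `log(power) = log(a) - chi * log(f)` by ordinary least squares over
#' the fit range (a free-exponent, near-pink "aperiodic" baseline) and counts
#' the bins where subtracting it leaves negative power -- the pathology the
#' constrained fit is built to avoid.
#'
#' @inheritParams fit_pink_white
#' @return list: `a`, `chi`, `residual_power` per fit bin, `n_negative`.
#' @export
aperiodic_baseline_demo <- function(power_spectrum,
                                    freq_hz = seq_along(power_spectrum),
                                    fit_lo = 2, fit_hi = 24) {
  sel <- freq_hz >= fit_lo & freq_hz <= fit_hi
  if (!any(sel)) stop("empty fit range", call. = FALSE)
  S <- power_spectrum[sel]; f <- freq_hz[sel]
  if (any(S < 0)) stop("negative input power", call. = FALSE)
  co <- stats::coef(stats::lm(log(pmax(S, 1e-12)) ~ log(f)))
  a <- exp(co[[1]]); chi <- -co[[2]]
  baseline <- a * f^(-chi)
  res <- S - baseline
  list(a = a, chi = chi, freq_hz = f, baseline = baseline,
       residual_power = res, n_negative = sum(res < -1e-12))
}
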