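#' Generate a pink-noise (1/f) voltage series
#'
#' Pink noise has one-sided power spectral density `power_at_1hz / f`
#' (microvolt^2 per Hz). Synthesis is by frequency-domain shaping: spectral
#' amplitudes proportional to `f^(-1/2)`, independent uniform random phases,
#' inverse FFT. The series has exactly zero mean (the DC bin is excluded).
#'
#' @param n_samples number of samples (>= 2).
#' @param fs sampling rate in Hz.
#' @param power_at_1hz one-sided PSD at 1 Hz, in microvolt^2/Hz (>= 0).
#' @param seed integer seed.
#' @return numeric vector of length `n_samples`, in microvolts.
#' @export
generate_pink_noise <- function(n_samples, fs, power_at_1hz, seed) {
  if (!is.numeric(n_samples) || n_samples < 2) {
    stop("n_samples must be >= 2", call. = FALSE)
  }
  if (power_at_1hz < 0) stop("power_at_1hz must be >= 0", call. = FALSE)
  n <- as.integer(n_samples)
  if (power_at_1hz == 0) return(numeric(n))
  set.seed(seed)
  kmax <- n %/% 2L
  f <- (1:kmax) * fs / n
  # one-sided periodogram PSD = 2|X_k|^2 / (fs * N); match it to p/f
  amp <- sqrt(power_at_1hz / f * fs * n / 2)
  phase <- stats::runif(kmax, 0, 2 * pi)
  X <- complex(modulus = amp, argument = phase)
  if (n %% 2L == 0L) {
    # Nyquist bin must be real; random sign, amplitude for a one-bin PSD
    X[kmax] <- sqrt(power_at_1hz / f[kmax] * fs * n) * sign(stats::runif(1) - 0.5)
  }
  full <- complex(real = numeric(n))
  full[2:(kmax + 1L)] <- X
  if (n %% 2L == 0L) {
    full[seq(n, kmax + 2L)] <- Conj(X[seq_len(kmax - 1L)])
  } else {
    full[seq(n, kmax + 2L)] <- Conj(X[seq_len(kmax)])
  }
  Re(stats::fft(full, inverse = TRUE)) / n
}

#' Generate a white-noise voltage series
#'
#' White noise has a uniform one-sided PSD of `power` microvolt^2/Hz over
#' `[0, fs/2]`, hence sample variance `power * fs / 2`.
#'
#' @inheritParams generate_pink_noise
#' @param power one-sided PSD in microvolt^2/Hz (>= 0).
#' @return numeric vector of length `n_samples`, in microvolts.
#' @export
generate_white_noise <- function(n_samples, fs, power, seed) {
  if (!is.numeric(n_samples) || n_samples < 1) {
    stop("n_samples must be >= 1", call. = FALSE)
  }
  if (power < 0) stop("power must be >= 0", call. = FALSE)
  n <- as.integer(n_samples)
  if (power == 0) return(numeric(n))
  set.seed(seed)
  stats::rnorm(n, mean = 0, sd = sqrt(power * fs / 2))
}
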