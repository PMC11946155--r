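#' Split-cosine-bell (Tukey) taper
#'
#' A "10% Hanning window" in the split-cosine-bell sense: raised-cosine ramps
#' over the first and last `n * taper_fraction / 2` samples, unity in between.
#' `taper_fraction = 1` reduces to a full Hann window. The window mean (its
#' coherent gain) is `1 - taper_fraction/2` up to discretisation.
#'
#' @param n window length (>= 4).
#' @param taper_fraction total tapered fraction in `(0, 1]` (default 0.10).
#' @return numeric weight vector of length `n`.
#' @export
taper_window <- function(n, taper_fraction = 0.10) {
  if (n < 4) stop("n must be >= 4", call. = FALSE)
  if (taper_fraction <= 0 || taper_fraction > 1) {
    stop("taper_fraction must lie in (0, 1]", call. = FALSE)
  }
  w <- rep(1, n)
  m <- floor(n * taper_fraction / 2)
  if (m > 0) {
    # half-sample offset makes the ramp mean exactly 1/2, hence the window
    # mean (coherent gain) exactly 1 - taper_fraction/2
    ramp <- 0.5 * (1 - cos(pi * (seq_len(m) - 0.5) / m))
    w[seq_len(m)] <- ramp
    w[n + 1 - seq_len(m)] <- ramp
  }
  w
}

#' Single-sided amplitude spectrum of one prestimulus epoch channel
#'
#' The series is de-meaned (DC zeroed across the epoch), tapered, zero-padded
#' to `pad_to` points, and Fourier transformed. Single-sided amplitudes are
#' `2|X_k| / n_orig` for `0 < k <` Nyquist (and `|X_0| / n_orig` at DC),
#' normalised by the original (unpadded) length, then divided by the taper's
#' coherent gain (its mean). With 500 samples at 1000 Hz padded to 1000, bins
#' are spaced at exactly 1 Hz; bins 0..`max_hz` are returned.
#'
#' @param x voltage series (one channel, one epoch), microvolts.
#' @param fs sampling rate in Hz.
#' @param pad_to padded length (default 1000); must be >= `length(x)`.
#' @param taper_fraction taper fraction for [taper_window()].
#' @param max_hz highest bin retained (default 30).
#' @return list of class `oscdyn_spectrum`: `freq_hz`, `amplitude_uv`.
#' @export
amplitude_spectrum <- function(x, fs, pad_to = 1000, taper_fraction = 0.10,
                               max_hz = 30) {
  n <- length(x)
  if (n > pad_to) stop("epoch longer than pad_to", call. = FALSE)
  w <- taper_window(n, taper_fraction)
  xt <- (x - mean(x)) * w
  X <- stats::fft(c(xt, rep(0, pad_to - n)))
  df <- fs / pad_to
  kmax <- floor(max_hz / df)
  amp <- numeric(kmax + 1L)
  amp[1] <- Mod(X[1]) / n
  amp[2:(kmax + 1L)] <- 2 * Mod(X[2:(kmax + 1L)]) / n
  amp <- amp / mean(w)  # coherent-gain correction
  structure(list(freq_hz = (0:kmax) * df, amplitude_uv = amp),
            class = "oscdyn_spectrum")
}

#' Amplitude spectra for every accepted epoch and channel
#'
#' Applies [amplitude_spectrum()] to the prestimulus slice `[-500, 0)` ms of
#' every epoch. Vectorised over epochs via a matrix FFT.
#'
#' @param epochs an `oscdyn_epochs` (accepted trials).
#' @param pad_to,taper_fraction,max_hz as in [amplitude_spectrum()].
#' @return array `trials x channels x bins` plus attribute `freq_hz`.
#' @export
epoch_spectra <- function(epochs, pad_to = NULL, taper_fraction = 0.10, max_hz = 30) {
  fs <- epochs$fs
  pre <- which(epochs$time_ms >= -500 & epochs$time_ms < 0)
  n <- length(pre)
  pad_to <- pad_to %||% (2L * n)  # halves the bin spacing: fs/pad_to
  w <- taper_window(n, taper_fraction)
  df <- fs / pad_to
  kmax <- floor(max_hz / df)
  nt <- dim(epochs$data)[1]; nch <- dim(epochs$data)[2]
  out <- array(NA_real_, c(nt, nch, kmax + 1L))
  for (c in seq_len(nch)) {
    m <- matrix(epochs$data[, c, pre], nt, n)
    m <- (m - rowMeans(m)) * rep(w, each = nt)
    M <- stats::mvfft(rbind(t(m), matrix(0, pad_to - n, nt)))
    amp <- 2 * Mod(M[seq_len(kmax + 1L), , drop = FALSE]) / n
    amp[1, ] <- amp[1, ] / 2
    out[, c, ] <- t(amp / mean(w))
  }
  attr(out, "freq_hz") <- (0:kmax) * df
  out
}

#' Mean amplitude spectra per channel and condition
#'
#' Arithmetic mean over epochs within condition; the pooled spectrum is the
#' mean of the Go-mean and No-Go-mean spectra (not the trial-weighted mean).
#'
#' @param spectra array from [epoch_spectra()].
#' @param condition per-trial condition labels.
#' @return list with `go`, `nogo`, `pooled` (channels x bins matrices) and
#'   `freq_hz`.
#' @export
mean_spectra <- function(spectra, condition) {
  if (dim(spectra)[1] == 0) stop("no spectra to average", call. = FALSE)
  avg <- function(idx) {
    if (!any(idx)) return(NULL)
    apply(spectra[idx, , , drop = FALSE], c(2, 3), mean)
  }
  go <- avg(condition == "go"); nogo <- avg(condition == "nogo")
  pooled <- if (is.null(go)) nogo else if (is.null(nogo)) go else (go + nogo) / 2
  list(go = go, nogo = nogo, pooled = pooled, freq_hz = attr(spectra, "freq_hz"))
}
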