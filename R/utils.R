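#' Derive a child seed from a master seed and a label
#'
#' All randomness in the package flows from a single master seed. Stage- and
#' participant-level seeds are derived deterministically by hashing the master
#' seed together with a string label (e.g. `"participant3/pink"`), so that any
#' stage can be re-run in isolation and reproduce its output bit-for-bit.
#'
#' @param master integer master seed.
#' @param label character label naming the consumer of the seed.
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  m <- 2147483647  # 2^31 - 1, keeps every derived seed a valid 32-bit integer
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(paste(label, collapse = "/"))) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h %% (m - 1L) + 1)
}

#' Rolling range (max minus min) over a sliding window
#'
#' Used by the flat-line artifact rule: an epoch is flat if any window of
#' `width` samples has a voltage range below threshold. Computed with a
#' doubling decomposition of windowed max/min, O(n log width) and fully
#' vectorised.
#'
#' @param x numeric vector.
#' @param width window length in samples (`>= 1`).
#' @return numeric vector of length `length(x) - width + 1` with the range of
#'   each window.
#' @export
rolling_range <- function(x, width) {
  n <- length(x)
  stopifnot(width >= 1, width <= n)
  roll <- function(v, w, fun) {
    # windowed extreme of width w via binary (doubling) combination
    span <- 1L
    out <- v
    while (span < w) {
      step <- min(span, w - span)
      m <- length(out) - step
      out <- fun(out[seq_len(m)], out[seq_len(m) + step])
      span <- span + step
    }
    out
  }
  roll(x, width, pmax) - roll(x, width, pmin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data frame as CSV (stable, no row names)
#' @param df data frame. @param path output path.
#' @keywords internal
write_csv_ <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
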