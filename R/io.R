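#' Write a recording as raw float32 binary plus JSON sidecar
#'
#' Channel-major float32 samples with a JSON sidecar carrying channel names,
#' sampling rate and dimensions; the event table goes to TSV with columns
#' `onset_sample`, `code`, `rt_ms` (empty when no response).
#'
#' @param session an `oscdyn_session`.
#' @param dir output directory (created if needed).
#' @param stem file stem (default `"recording"`).
#' @return invisibly, the paths written.
#' @export
write_recording <- function(session, dir, stem = "recording") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- session$recording
  bin <- file.path(dir, paste0(stem, ".f32"))
  con <- file(bin, "wb")
  writeBin(as.numeric(t(rec$data)), con, size = 4)  # channel-major rows
  close(con)
  side <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(list(
    channels = rec$channels, fs = rec$fs,
    n_channels = nrow(rec$data), n_samples = ncol(rec$data),
    dtype = "float32", order = "channel_major"
  ), side, auto_unbox = TRUE, pretty = TRUE)
  ev <- file.path(dir, paste0(stem, "_events.tsv"))
  events <- session$events
  events$rt_ms <- ifelse(is.na(events$rt_ms), "", sprintf("%.6f", events$rt_ms))
  utils::write.table(events, ev, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bin, side, ev))
}

#' Read a recording written by [write_recording()]
#'
#' @param dir directory. @param stem file stem.
#' @return list with `recording` (data/fs/channels) and `events`.
#' @export
read_recording <- function(dir, stem = "recording") {
  meta <- jsonlite::read_json(file.path(dir, paste0(stem, ".json")),
                              simplifyVector = TRUE)
  con <- file(file.path(dir, paste0(stem, ".f32")), "rb")
  x <- readBin(con, numeric(), n = meta$n_channels * meta$n_samples, size = 4)
  close(con)
  data <- t(matrix(x, meta$n_samples, meta$n_channels))
  ev <- utils::read.table(file.path(dir, paste0(stem, "_events.tsv")),
                          header = TRUE, sep = "\t",
                          colClasses = c("integer", "character", "character"))
  ev$rt_ms <- suppressWarnings(as.numeric(ev$rt_ms))
  list(recording = list(data = data, fs = meta$fs, channels = meta$channels),
       events = ev)
}

#' Read a structured pipeline configuration file
#'
#' YAML with sections `session`, `truth` (including `bands`, `erps`,
#' `couplings` lists), `cohort` and `analysis`; absent fields fall back to
#' the package defaults.
#'
#' @param path YAML file path.
#' @return list with `config` (`oscdyn_config`), `truth` (`oscdyn_truth`),
#'   `cohort`, `analysis`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  s <- raw$session %||% list()
  config <- do.call(session_config, s)
  t <- raw$truth %||% list()
  to_df <- function(x) if (is.null(x)) NULL else
    do.call(rbind, lapply(x, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  args <- t[setdiff(names(t), c("bands", "erps", "couplings"))]
  if (!is.null(t$bands)) args$bands <- to_df(t$bands)
  if (!is.null(t$erps)) args$erps <- to_df(t$erps)
  if (!is.null(t$couplings)) args$couplings <- to_df(t$couplings)
  truth <- do.call(ground_truth, args)
  list(config = config, truth = truth,
       cohort = raw$cohort %||% list(n_participants = 10, jitter_sd = 0.2),
       analysis = raw$analysis %||% list())
}
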