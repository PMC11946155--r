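#' Summarise Go/No-Go behaviour for one participant
#'
#' Six measures from the event table: omission errors (Go trials with no
#' response before the next stimulus), slow RT errors (RT > 500 ms), fast RT
#' errors (RT < 100 ms), mean RT and within-participant RT SD over valid
#' (100-500 ms) responses, and commission errors (No-Go trials with any
#' response). Error measures are percentages of the condition's trial count;
#' responses in the late interstimulus window count as slow errors, not
#' omissions.
#'
#' @param events event table with `code` and `rt_ms`.
#' @return one-row data frame: `omission_pct`, `slow_rt_pct`, `fast_rt_pct`,
#'   `mean_rt_ms`, `rt_sd_ms`, `commission_pct`.
#' @export
summarize_behaviour <- function(events) {
  go <- events$code == "go"
  nogo <- events$code == "nogo"
  if (!any(go) || !any(nogo)) {
    stop("behaviour undefined without both Go and No-Go trials", call. = FALSE)
  }
  rt_go <- events$rt_ms[go]
  valid_rt <- rt_go[!is.na(rt_go) & rt_go >= 100 & rt_go <= 500]
  data.frame(
    omission_pct = 100 * mean(is.na(rt_go)),
    slow_rt_pct = 100 * mean(!is.na(rt_go) & rt_go > 500),
    fast_rt_pct = 100 * mean(!is.na(rt_go) & rt_go < 100),
    mean_rt_ms = if (length(valid_rt)) mean(valid_rt) else NA_real_,
    rt_sd_ms = if (length(valid_rt) > 1) stats::sd(valid_rt) else 0,
    commission_pct = 100 * mean(!is.na(events$rt_ms[nogo]))
  )
}
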