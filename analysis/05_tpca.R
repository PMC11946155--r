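#!/usr/bin/env Rscript
# Separate temporal PCAs of the Go and No-Go mean ERPs (-100..500 ms,
# half-sampled): covariance input, Kaiser normalisation, unrestricted
# Varimax, 1.5% cutoff, per-participant global mean peak amplitudes.
#
# Usage: Rscript analysis/05_tpca.R  (expects scratch/participants.rds from 02)

library(oscdyn)

pps <- readRDS("scratch/participants.rds")
config <- recovery_config()
keep <- which(!vapply(pps, `[[`, logical(1), "excluded"))
pid <- rep(keep, each = config$n_channels)
t_ms <- pps[[keep[1]]]$erp_time_ms

erp_amp <- data.frame(participant = keep)
for (cond in c("go", "nogo")) {
  cases <- do.call(rbind, lapply(pps[keep], function(p) p$erp[[cond]]))
  sol <- tpca(cases, pid, time_ms = t_ms)
  sel <- sol$selected
  write.csv(data.frame(time_ms = t_ms, sol$loadings[, sel, drop = FALSE]),
            sprintf("results/tpca_%s_loadings.csv", cond), row.names = FALSE)
  write.csv(data.frame(component = seq_along(sol$variance_pct),
                       peak_ms = sol$peak_ms,
                       variance_pct = sol$variance_pct,
                       selected = seq_along(sol$variance_pct) %in% sel),
            sprintf("results/tpca_%s_selection.csv", cond), row.names = FALSE)
  a <- sol$amplitudes
  colnames(a) <- make.unique(paste0(cond, "_T", round(sol$peak_ms[sel])))
  erp_amp <- cbind(erp_amp, a)
  cat(sprintf("%s t-PCA: %d cases x %d variables (ratio %.1f); %d components, peaks %s ms\n",
              cond, nrow(cases), ncol(cases), nrow(cases) / ncol(cases),
              length(sel), paste(sort(round(sol$peak_ms[sel])), collapse = ", ")))
}
write.csv(erp_amp, "results/erp_amplitudes.csv", row.names = FALSE)
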