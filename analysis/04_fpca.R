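#!/usr/bin/env Rscript
# Frequency PCA of the noise-free oscillation spectra: covariance input,
# cases = participant x channel, Varimax extraction with a 1.5% variance
# cutoff, Promax rotation of the retained components, per-participant global
# mean amplitudes. Writes scaled loadings, the selection table, and the
# predictor table (component amplitudes plus PN/WN amplitudes at 1 Hz).
#
# Usage: Rscript analysis/04_fpca.R  (expects scratch/participants.rds from 02)

library(oscdyn)

pps <- readRDS("scratch/participants.rds")
config <- recovery_config()
keep <- which(!vapply(pps, `[[`, logical(1), "excluded"))
pid <- rep(keep, each = config$n_channels)
osc <- do.call(rbind, lapply(pps[keep], `[[`, "osc"))
freq <- pps[[keep[1]]]$freq_hz

sol <- fpca(osc, pid, freq_hz = freq)
sel <- sol$selected

write.csv(data.frame(freq_hz = freq, sol$structure[, sel, drop = FALSE]),
          "results/fpca_loadings.csv", row.names = FALSE)
write.csv(data.frame(component = seq_along(sol$variance_pct),
                     peak_hz = sol$peak_hz,
                     variance_pct_promax = sol$variance_pct),
          "results/fpca_selection.csv", row.names = FALSE)

amp <- sol$amplitudes
colnames(amp) <- make.unique(paste0("F", sol$peak_hz[sel], "Hz"))
np <- read.csv("results/noise_parameters.csv")
pn <- tapply(sqrt(np$p), np$participant, mean)
wn <- tapply(sqrt(np$w), np$participant, mean)
pred <- data.frame(participant = keep, amp,
                   PN = as.numeric(pn[as.character(keep)]),
                   WN = as.numeric(wn[as.character(keep)]))
write.csv(pred, "results/predictors.csv", row.names = FALSE)

cat(sprintf("f-PCA: %d cases x %d variables (ratio %.1f)\n",
            nrow(osc), ncol(osc), nrow(osc) / ncol(osc)))
cat(sprintf("%d components at >=1.5%% variance, peaks at %s Hz\n",
            length(sel), paste(sort(sol$peak_hz), collapse = ", ")))
cat(sprintf("total retained variance (orthogonal shares): %.1f%%\n",
            sum(sol$variance_pct_varimax[sol$variance_pct_varimax >= 1.5])))
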