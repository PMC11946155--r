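#!/usr/bin/env Rscript
# The six behavioural measures per participant: omission %, slow-RT %
# (RT > 500 ms), fast-RT % (RT < 100 ms), mean RT and within-subject RT SD
# over valid 100-500 ms responses, commission %.
#
# Usage: Rscript analysis/06_behaviour.R [master_seed]

library(oscdyn)

args <- commandArgs(trailingOnly = TRUE)
master_seed <- if (length(args) >= 1) as.integer(args[1]) else 20250901L

config <- recovery_config()
truth <- ground_truth(couplings = default_couplings(0.5))
truths <- cohort_truths(truth, 47, master_seed)

beh <- do.call(rbind, lapply(1:47, function(i) {
  ev <- generate_events(config, truths[[i]],
                        derive_seed(derive_seed(master_seed,
                                                paste0("participant/", i)),
                                    "events"))
  cbind(participant = i, summarize_behaviour(ev))
}))
write.csv(beh, "results/behaviour.csv", row.names = FALSE)

cat(sprintf("omission %.1f%% (range %.1f-%.1f), commission %.1f%%\n",
            mean(beh$omission_pct), min(beh$omission_pct), max(beh$omission_pct),
            mean(beh$commission_pct)))
cat(sprintf("mean RT %.1f ms, RT SD %.1f ms, slow %.1f%%, fast %.1f%%\n",
            mean(beh$mean_rt_ms), mean(beh$rt_sd_ms),
            mean(beh$slow_rt_pct), mean(beh$fast_rt_pct)))
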