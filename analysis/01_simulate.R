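#!/usr/bin/env Rscript
# Simulate the study cohort: 47 participants, equiprobable auditory Go/No-Go
# at a fixed 1100 ms SOA, with the planted prestimulus-to-ERP coupling
# pattern (alpha -> Go P3b +, beta -> Go N2c -, pink -> No-Go N1b -,
# pink -> No-Go N1c +) at strength 0.5. Writes one participant's recording
# in full (float32 + JSON + events TSV) under scratch/ as a format
# demonstration; downstream stages regenerate sessions from seeds, which is
# cheaper than storing ~50 continuous EEG recordings.
#
# Usage: Rscript analysis/01_simulate.R [master_seed]

library(oscdyn)

args <- commandArgs(trailingOnly = TRUE)
master_seed <- if (length(args) >= 1) as.integer(args[1]) else 20250901L

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)
config <- recovery_config()          # 6 channels, 250 Hz, one 75+75 block
truth <- ground_truth(couplings = default_couplings(0.5))
n_participants <- 47

truths <- cohort_truths(truth, n_participants, master_seed)
s1 <- generate_session(config, truths[[1]],
                       seed = derive_seed(master_seed, "participant/1"))
write_recording(s1, "scratch/participant01")

events_all <- do.call(rbind, lapply(seq_len(n_participants), function(i) {
  ev <- generate_events(config, truths[[i]],
                        derive_seed(derive_seed(master_seed,
                                                paste0("participant/", i)),
                                    "events"))
  cbind(participant = i, ev)
}))
write.csv(events_all, "results/events.csv", row.names = FALSE)

cat(sprintf("cohort: %d participants, %d trials each (%d go / %d nogo)\n",
            n_participants, nrow(s1$events),
            sum(s1$events$code == "go"), sum(s1$events$code == "nogo")))
cat(sprintf("participant 1 recording: %d channels x %d samples at %g Hz\n",
            nrow(s1$recording$data), ncol(s1$recording$data), config$fs))
cat("master seed:", master_seed, "- sessions are regenerated from derived seeds downstream\n")
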