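#!/usr/bin/env Rscript
# Step 2: exercise the preprocessing rules on an artifact-laden recording.
#
# A clean synthetic trial is contaminated with the three canonical artifact
# kinds, flagged with the amplitude / jump / SD criteria, and summarised.
# Writes results/02_noise_report.tsv and results/02_exclusions.tsv.

suppressMessages(library(hftmspc))
dir.create("results", showWarnings = FALSE)

sched <- build_exp1_schedule("FHHFFH", "PV", n_cycles = 36,
                             violation_index = 34)
params <- cascade_params(fs = 500, epoch_len = 5)
tr <- simulate_trial(sched, params, rng_seed = 21)
rec <- tr$recording

set.seed(22)
spec <- data.frame(
  channel = sample(nrow(rec$data), 40, replace = TRUE),
  sample = sample(200:(ncol(rec$data) - 200), 40),
  kind = sample(c("spike80", "jump30"), 40, replace = TRUE))
dirty <- inject_artifacts(rec, spec)

std <- standardize(dirty)
cyc <- round(sched$streams[[1]]$onset * std$fs) + 1L
rep <- flag_noise(std, cyc)

summary <- aggregate(noisy ~ channel, rep$noisy_cycles, mean)
names(summary)[2] <- "frac_noisy_cycles"
summary$bad <- summary$channel %in% rep$bad_channels
write.table(summary, "results/02_noise_report.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("flagged %d noisy samples across %d channels; bad channels: %s\n",
            sum(rep$noisy_sample_mask), nrow(std$data),
            if (length(rep$bad_channels))
              paste(rep$bad_channels, collapse = ", ") else "none"))

if (length(rep$bad_channels)) {
  fixed <- interpolate_bad_channels(std, rep$bad_channels)
  cat("bad channels replaced by inverse-distance neighbour means\n")
}

## trial/participant exclusion bookkeeping on a mock multi-trial session
set.seed(23)
trials <- data.frame(
  participant = rep(c("P01", "P02"), each = 12),
  trial = rep(1:12, 2),
  n_channels = 64,
  n_bad_channels = c(rpois(12, 2), rpois(12, 8)),
  reported = 20 + c(sample(-2:2, 12, TRUE), sample(-6:6, 12, TRUE)),
  true_count = 20)
ex <- apply_exclusions(trials, "exp2")
write.table(ex$participants, "results/02_exclusions.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("participants excluded: %s\n",
            paste(ex$participants$participant[ex$participants$excluded],
                  collapse = ", ")))
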