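#!/usr/bin/env Rscript
# Step 4: the core contrast -- stimulus- vs response-referenced
# multispectral phase coherence on ground-truthed trials.
#
# Three trial types are analysed: stimulus-locked interaction (g_low only),
# response-locked interaction under latency jitter (g_high only), and a
# constant-delay control where the two variants must agree.  Writes
# results/04_mspc_values.tsv.

suppressMessages(library(hftmspc))
dir.create("results", showWarnings = FALSE)

sched <- build_exp1_schedule("FHHFFH", "PV", n_cycles = 36,
                             violation_index = 34)
ims <- enumerate_ims(1.2, 15, 2)

cases <- list(
  stim_locked = cascade_params(g_low = 0.5, g_high = 0,
                               fs = 250, epoch_len = 5),
  response_locked = cascade_params(g_low = 0, g_high = 0.5,
                                   fs = 250, epoch_len = 5),
  constant_delay = cascade_params(g_low = 0.5, g_high = 0.3,
                                  tau_jitter_sd = 0, noise_level = 0,
                                  fs = 250, epoch_len = 5))

all <- list()
for (nm in names(cases)) {
  tr <- simulate_trial(sched, cases[[nm]], rng_seed = 41)
  r <- mspc_trial(tr$recording, sched, ims, "both", epoch_len = 5)
  r$case <- nm
  all[[nm]] <- r
  m <- aggregate(value ~ variant, r, mean)
  cat(sprintf("%-16s K=%2d  MSPCstim %.3f  MSPCres %.3f\n", nm, r$K[1],
              m$value[m$variant == "stim"], m$value[m$variant == "res"]))
}
out <- do.call(rbind, all)
write.table(out, "results/04_mspc_values.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

nc <- null_calibrate(K = all[[1]]$K[1], n_perm = 2000, rng_seed = 42)
cat(sprintf(
  "independence null at K=%d: mean %.3f (closed form %.3f), 95th pct %.3f\n",
  all[[1]]$K[1], nc$null_mean, nc$rayleigh, nc$threshold_95))
cat("stimulus-locked trials load on MSPCstim, jittered response-locked trials on MSPCres,\n")
cat("and with constant delays the two variants coincide\n")
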