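#!/usr/bin/env Rscript
# Cohort-level reproduction of the headline modulator contrasts.
#
# Runs eight synthetic preparations per condition (5HT, DA, DA+5HT,
# DA+TEA, TEA), each with its own conductance draws and a within-run
# control baseline, analyses every recording with the full pipeline, and
# evaluates the directional outcomes: 5HT and TEA desynchronize burst
# waveforms, DA does not, and DA co-application protects synchrony while
# raising the measured coupling conductance.

suppressPackageStartupMessages(library(cgsync))
dir.create("results", showWarnings = FALSE)

rep1 <- suppressWarnings(run_reproduction(n = 8, seed = 1))
write_results(list(reproduction_sync = rep1$sync_table,
                   reproduction_coupling = rep1$coupling_table,
                   reproduction_verdicts = rep1$verdicts), "results")

print(rep1)
st <- split(rep1$sync_table, rep1$sync_table$condition)
cat("\nEpoch means (control -> acute):\n")
for (cond in names(st)) {
  cat(sprintf("  %-7s %.3f -> %.3f\n", cond,
              mean(st[[cond]]$r2_control), mean(st[[cond]]$r2_acute)))
}
cat("\nAll directional checks are recomputed from freshly simulated cohorts;\n")
cat("results/reproduction_verdicts.csv holds the machine-readable verdicts.\n")
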