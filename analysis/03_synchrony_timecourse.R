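#!/usr/bin/env Rscript
# Synchrony time courses under modulator perfusion.
#
# For one preparation per condition (control baseline, then ramped
# perfusion of 5HT or DA), computes the per-burst R2 time course, the
# three reporting epochs (control / acute / late) and the acute-minimum
# time. Writes the full SyncPoint series and epoch tables to results/.

suppressPackageStartupMessages(library(cgsync))
dir.create("results", showWarnings = FALSE)

series <- list()
epochs <- list()
for (cond in c("5HT", "DA")) {
  prep <- suppressWarnings(simulate_preparation(cond, seed = 1001))
  s <- prep$analysis$sync
  s$condition <- cond
  series[[cond]] <- s
  ep <- prep$epochs
  ep$condition <- cond
  ep$t_min <- prep$t_min
  epochs[[cond]] <- ep
  cat(sprintf("%s: control R2 %.3f, acute %.3f, late %.3f; acute minimum %.0f s after perfusion\n",
              cond,
              ep$mean_r2[ep$label == "control"],
              ep$mean_r2[ep$label == "acute"],
              ep$mean_r2[ep$label == "late"],
              prep$t_min - prep$perfusion_t))
}
write_results(list(sync_timecourse = do.call(rbind, series),
                   sync_epochs = do.call(rbind, epochs)), "results")

cat("\n5HT produces an acute fall in per-burst waveform synchrony after\n")
cat("perfusion begins, while DA leaves the time course essentially flat —\n")
cat("the single-preparation analogue of the cohort contrast in script 05.\n")
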