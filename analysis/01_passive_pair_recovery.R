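#!/usr/bin/env Rscript
# Exact-oracle validation of the electrical-coupling estimator.
#
# Simulates noiseless passive two-compartment pairs over a grid of membrane
# and junctional resistances, runs the -2..-8 nA alternating step protocol,
# and compares the recovered input/transfer resistances, coupling
# coefficients and Bennett conductances with the closed-form circuit
# solution. Writes the recovery table to results/.

suppressPackageStartupMessages(library(cgsync))
dir.create("results", showWarnings = FALSE)

rows <- list()
for (Rm in c(2, 5, 10)) {
  for (Rc in c(2, 10, 50)) {
    spec <- passive_pair_spec(Rm1 = Rm, Rm2 = Rm, Rc = Rc)
    an <- analytic_passive_pair(spec)
    cr <- coupling_from_protocol(simulate_passive_pair(spec, seed = 1),
                                 c("LC4", "LC5"))
    rows[[length(rows) + 1L]] <- data.frame(
      Rm = Rm, Rc_true = Rc, Gc_true = 1 / Rc,
      Rin_est = cr$Rin_1, Rin_true = an$Rin1,
      R12_est = cr$R12_from1, R12_true = an$R12,
      cc_est = cr$cc_12, cc_true = an$cc12,
      Gc_est = cr$Gc_pooled,
      Gc_rel_err = abs(cr$Gc_pooled - 1 / Rc) * Rc,
      dir_asymmetry = abs(cr$Gc_dir12 - cr$Gc_dir21) /
        mean(c(cr$Gc_dir12, cr$Gc_dir21)))
  }
}
tab <- do.call(rbind, rows)
write_results(list(passive_pair_recovery = tab), "results")

cat("Passive-pair recovery over the Rm x Rc grid:\n")
print(tab[, c("Rm", "Rc_true", "Gc_true", "Gc_est", "Gc_rel_err")],
      digits = 4, row.names = FALSE)
cat(sprintf("\nWorst relative Gc error: %.3g; worst direction asymmetry: %.3g\n",
            max(tab$Gc_rel_err), max(tab$dir_asymmetry)))
cat("The estimator recovers the true junctional conductance to numerical\n")
cat("precision on noiseless data, in both injection directions.\n")
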