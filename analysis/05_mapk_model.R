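#!/usr/bin/env Rscript
# Mechanistic MAPK surrogate: steady-state 10x10 dose matrices of pMEK and
# pERK (relative to drug-free) for the three model variants, Bliss excess
# on pERK inhibition, and the 8 h post-dose timecourses at cobimetinib
# 0.5 uM with and without 133 nM belvarafenib.

suppressPackageStartupMessages(library(combotrans))
dir.create("results", showWarnings = FALSE)

variants <- c("NRAS_Q61", "NRAS_Q61_NO_FEEDBACK", "BRAF_V600E")
summary_rows <- list()
for (kind in variants) {
  v <- mapk_variant(kind)
  dm <- mapk_dose_matrix(v)
  base <- sprintf("results/mapk_%s", tolower(kind))
  write.csv(cbind(belva_uM = dm$doses_belva, dm$pmek_rel),
            paste0(base, "_pmek_rel.csv"), row.names = FALSE)
  write.csv(cbind(belva_uM = dm$doses_belva, dm$perk_rel),
            paste0(base, "_perk_rel.csv"), row.names = FALSE)
  write.csv(cbind(belva_uM = dm$doses_belva, dm$bliss$bliss_excess),
            paste0(base, "_perk_bliss_excess.csv"), row.names = FALSE)

  b0 <- steady_state(v, 0, 0)
  cobi <- steady_state(v, 0, 0.5)
  combo <- steady_state(v, 0.133, 0.5)
  tc <- mapk_timecourse(v, cobimetinib = 0.5, belvarafenib = 0)
  tc$belvarafenib_uM <- 0
  tc2 <- mapk_timecourse(v, cobimetinib = 0.5, belvarafenib = 0.133)
  tc2$belvarafenib_uM <- 0.133
  write.csv(rbind(tc, tc2), paste0(base, "_timecourse.csv"),
            row.names = FALSE)

  summary_rows[[kind]] <- data.frame(
    variant = kind, pmek_baseline = b0$pmek,
    pmek_fold_cobi = cobi$pmek / b0$pmek,
    pmek_fold_combo = combo$pmek / b0$pmek,
    max_bliss_excess_perk = dm$max_bliss_excess)
}
summary <- do.call(rbind, summary_rows)
write.csv(summary, "results/mapk_summary.csv", row.names = FALSE)

cat("MAPK surrogate signatures:\n")
print(summary, digits = 3, row.names = FALSE)
cat("\nOnly the NRAS Q61 variant with active pRAF feedback shows the\n")
cat("paradoxical pMEK rise under MEK inhibition (fold > 1), its reversal\n")
cat("by 133 nM of the panRAF inhibitor, and the largest pERK Bliss\n")
cat("excess; removing the feedback or switching to the monomer-driven\n")
cat("BRAF variant collapses both signatures.\n")
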