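#!/usr/bin/env Rscript
# Normalization-based differential expression on the simulated cohort:
# geNorm-style stability selection of endogenous controls, control and
# median normalization, delta-delta-Ct fold changes, and the empirical-Bayes
# moderated t-test with BH adjustment.

library(ctrank)

ct <- read_ct_matrix("results/de_ct.tsv")
design <- read_design("results/de_design.tsv",
                      control_candidates = c("ctrl_01", "ctrl_02"))

stab <- stability_m(ct, design$control_candidates)
print(stab)
write_results(stab$m_values, "results/control_stability.tsv")

norm <- control_normalize(ct, stab$selected)
fc <- ddct_fold_change(norm, design, reference_group = "control")
mod <- moderated_de(norm, design, reference_group = "control")
cat(sprintf("moderation: d0 = %.2f, s0^2 = %.4f over %d detectors\n",
            mod$hyper$d0, mod$hyper$s0_sq, mod$hyper$n_used))

tab <- merge(fc, mod$table[, c("detector", "t", "df", "p", "q")], by = "detector")
write_results(tab[order(tab$p), ], "results/moderated_de_table.tsv")

med <- median_normalize(ct)
fc_med <- ddct_fold_change(med, design, reference_group = "control")
write_results(fc_med, "results/median_fold_changes.tsv")

sig <- tab[abs(tab$log2_fold_change) >= 1 & tab$p <= 0.01, ]
cat(sprintf("moderated filter hits (|log2FC| >= 1, p <= 0.01): %d\n", nrow(sig)))
print(sig[order(sig$p), c("detector", "log2_fold_change", "p", "q")],
      row.names = FALSE)
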