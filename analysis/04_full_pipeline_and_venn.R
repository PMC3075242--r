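#!/usr/bin/env Rscript
# The complete workflow in one call: ranking, both normalizations, the three
# significance filters, their Venn overlap, amplification-kinetics curation,
# and the curated focus list.

library(ctrank)

ct <- read_ct_matrix("results/de_ct.tsv")
design <- read_design("results/de_design.tsv",
                      control_candidates = c("ctrl_01", "ctrl_02"))

# amplification curves for a few wells: one clean doubling reaction and one
# inefficient reaction whose detector should be curated out of the focus list
curves <- bind_curves(
  simulate_curves(efficiency = 2.0, detector = "de1", sample = "case_1"),
  simulate_curves(efficiency = 2.0, detector = "de2", sample = "case_1"),
  simulate_curves(efficiency = 1.5, detector = "de3", sample = "case_1"))

res <- run_pipeline(ct, design, reference_group = "control", curves = curves)
print(res)

write_results(res$table, "results/pipeline_table.tsv")
write_results(res$venn, "results/venn_overlap.tsv")
write_results(res$focus, "results/focus_list.tsv")
write_results(res$qc, "results/kinetics_qc.tsv")

cat("\nfilter counts:\n")
print(filter_count_summary(res))
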