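#!/usr/bin/env Rscript
# Structural summary statistics: mol%-weighted average double bonds and
# chain length per sample, arm comparisons (one-way ANOVA + Holm-Sidak vs
# the corticosterone arm), and the saturated/unsaturated LPE partition.

suppressPackageStartupMessages({
  library(lipidstress)
  library(dplyr)
})

for (tissue in c("plasma", "hippocampus")) {
  m <- read_quant_table(file.path("results/data",
                                  paste0("quant_", tissue, ".csv")),
                        "results/data/metadata.csv")
  m <- to_molpct(apply_lod(m))
  ss <- structural_summary(m)
  readr::write_csv(ss, file.path("results",
                                 paste0("structural_summary_", tissue, ".csv")))
  cmp <- bind_rows(compare_structural_stat(ss, "db_av")$comparisons,
                   compare_structural_stat(ss, "cl_av")$comparisons)
  readr::write_csv(cmp, file.path("results",
                                  paste0("structural_comparisons_", tissue,
                                         ".csv")))
  cat("\n==", tissue, "arm means ==\n")
  print(summarise(group_by(ss, arm),
                  db_av = mean(db_av), cl_av = mean(cl_av)), n = 6)
  part <- saturation_partition(m, "LPE")
  readr::write_csv(part, file.path("results",
                                   paste0("lpe_partition_", tissue, ".csv")))
  cat("LPE unsaturated mol% by arm:\n")
  print(round(tapply(part$unsat_molpct, part$arm, mean), 3))
}
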