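#!/usr/bin/env Rscript
# Per-lipid treatment testing: one-factor linear model per lipid, the five
# contrasts of interest with pooled-variance t-tests, per-contrast
# Benjamini-Hochberg FDR, and volcano/QQ tables per contrast.

suppressPackageStartupMessages({
  library(lipidstress)
  library(dplyr)
})

for (tissue in c("plasma", "hippocampus")) {
  m <- read_quant_table(file.path("results/data",
                                  paste0("quant_", tissue, ".csv")),
                        "results/data/metadata.csv")
  m <- to_molpct(apply_lod(m))
  res <- fit_contrasts(m)
  readr::write_csv(res, file.path("results",
                                  paste0("contrasts_", tissue, ".csv")))
  cat("\n==", tissue, "==\n")
  for (cn in unique(res$contrast)) {
    rc <- res[res$contrast == cn, ]
    tag <- gsub("[^A-Za-z0-9]+", "_", cn)
    readr::write_csv(volcano_table(rc),
                     file.path("results",
                               sprintf("volcano_%s_%s.csv", tissue, tag)))
    readr::write_csv(qq_table(rc),
                     file.path("results",
                               sprintf("qq_%s_%s.csv", tissue, tag)))
    sig <- sum(rc$fdr < 0.05, na.rm = TRUE)
    cat(sprintf("  %-22s %4d tested, %3d excluded, %3d at FDR<0.05\n",
                cn, sum(rc$included), sum(!rc$included), sig))
  }
  sig_lpe <- res |>
    filter(fdr < 0.05, startsWith(species, "LPE"),
           contrast != "CORT_vs_CONTROL")
  if (nrow(sig_lpe)) {
    cat("  significant LPE species in co-treatment contrasts:",
        paste(sort(unique(sig_lpe$species)), collapse = ", "), "\n")
  }
}
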