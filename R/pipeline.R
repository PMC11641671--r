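#' Run the full downstream analysis
#'
#' Orchestrates the whole pipeline on either a simulated study (pass a
#' [sim_config()]) or on files on disk (pass paths): identification filter
#' where QC columns exist, LOD replacement, mol% normalization, per-sample
#' structural summaries and arm comparisons, the five treatment contrasts
#' with per-contrast FDR plus volcano/QQ tables, the LPE saturation
#' partition, FST group statistics, and the lipid–behavior Spearman
#' correlations in both treatment subsets. All tables are written as CSV
#' under `out_dir`, and a run manifest records the seed, per-stage species
#' counts and output digests.
#'
#' @param config A [sim_config()], or a named list with `quant` (named list
#'   `tissue = path`), `meta` (metadata CSV path) and `behavior` (CSV path).
#' @param out_dir Output directory.
#' @param fdr_threshold Volcano significance threshold (default 0.05).
#' @return The run manifest (list): `seed`, `package_version`,
#'   `species_counts` (per tissue, per stage), `excluded_per_contrast`,
#'   `outputs` (paths), `digests` (md5 per output).
#' @export
run_pipeline <- function(config, out_dir, fdr_threshold = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()

  if (inherits(config, "sim_config")) {
    sim <- simulate_study(config)
    quant <- sim$quant
    behavior <- sim$behavior
    seed <- config$seed
    gt_path <- file.path(out_dir, "ground_truth.csv")
    readr::write_csv(sim$ground_truth, gt_path)
    outputs <- c(outputs, ground_truth = gt_path)
  } else {
    stopifnot(is.list(config), !is.null(config$quant), !is.null(config$meta),
              !is.null(config$behavior))
    quant <- lapply(config$quant, read_quant_table, meta_path = config$meta)
    behavior <- read_behavior_table(config$behavior)
    seed <- NA_integer_
  }

  species_counts <- list()
  excluded <- list()

  for (tt in names(quant)) {
    m <- quant[[tt]]
    counts <- c(input = nrow(m$amounts))
    if (!is.null(m$snr) || !is.null(m$blank_intensity)) {
      m <- apply_identification_filter(m)
    }
    counts["identified"] <- nrow(m$amounts)
    m <- apply_lod(m)
    counts["after_lod"] <- nrow(m$amounts)
    mp <- to_molpct(m)

    long_path <- file.path(out_dir, paste0("quant_long_", tt, ".csv"))
    write_quant_long(m, long_path)
    outputs <- c(outputs, stats::setNames(long_path, paste0("quant_long_", tt)))

    summ <- structural_summary(mp, "all")
    s_path <- file.path(out_dir, paste0("structural_summary_", tt, ".csv"))
    readr::write_csv(summ, s_path)
    outputs <- c(outputs, stats::setNames(s_path, paste0("structural_", tt)))

    cmp <- dplyr::bind_rows(
      compare_structural_stat(summ, "db_av")$comparisons,
      compare_structural_stat(summ, "cl_av")$comparisons
    )
    c_path <- file.path(out_dir, paste0("structural_comparisons_", tt, ".csv"))
    readr::write_csv(cmp, c_path)
    outputs <- c(outputs, stats::setNames(c_path, paste0("struct_cmp_", tt)))

    lpe_path <- file.path(out_dir, paste0("lpe_partition_", tt, ".csv"))
    readr::write_csv(saturation_partition(mp, "LPE"), lpe_path)
    outputs <- c(outputs, stats::setNames(lpe_path, paste0("lpe_", tt)))

    res <- fit_contrasts(mp)
    r_path <- file.path(out_dir, paste0("contrasts_", tt, ".csv"))
    readr::write_csv(res, r_path)
    outputs <- c(outputs, stats::setNames(r_path, paste0("contrasts_", tt)))
    excl <- tapply(!res$included, res$contrast, sum)
    excluded[[tt]] <- excl
    message(tt, ": species excluded per contrast: ",
            paste(names(excl), excl, sep = "=", collapse = ", "))

    for (cn in unique(res$contrast)) {
      rc <- res[res$contrast == cn, ]
      tag <- gsub("[^A-Za-z0-9]+", "_", cn)
      v_path <- file.path(out_dir, sprintf("volcano_%s_%s.csv", tt, tag))
      readr::write_csv(volcano_table(rc, fdr_threshold), v_path)
      q_path <- file.path(out_dir, sprintf("qq_%s_%s.csv", tt, tag))
      readr::write_csv(qq_table(rc), q_path)
      outputs <- c(outputs,
                   stats::setNames(c(v_path, q_path),
                                   paste0(c("volcano_", "qq_"), tt, "_", tag)))
    }

    if ("LPE" %in% mp$species$class_code && !is.null(behavior)) {
      for (subset in c("all-arms", "cort-and-cotreated")) {
        corr <- correlate_lipids(
          mp, behavior, subset,
          species = rownames(mp$amounts)[mp$species$class_code == "LPE"]
        )
        tag <- gsub("[^A-Za-z0-9]+", "_", subset)
        p <- file.path(out_dir, sprintf("correlation_%s_%s.csv", tt, tag))
        readr::write_csv(corr, p)
        outputs <- c(outputs, stats::setNames(p, paste0("corr_", tt, "_", tag)))
      }
    }
    species_counts[[tt]] <- counts
  }

  fst <- fst_group_stats(behavior)
  fst_tbl <- dplyr::bind_rows(
    dplyr::mutate(fst$total_immobility_s$comparisons,
                  measure = "total_immobility_s"),
    dplyr::mutate(fst$latency_s$comparisons, measure = "latency_s")
  )
  f_path <- file.path(out_dir, "fst_stats.csv")
  readr::write_csv(fst_tbl, f_path)
  outputs <- c(outputs, fst_stats = f_path)

  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("lipidstress")),
    species_counts = species_counts,
    excluded_per_contrast = excluded,
    outputs = as.list(outputs),
    digests = lapply(as.list(outputs), function(p)
      unname(tools::md5sum(p)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest
}
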