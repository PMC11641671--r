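#' Treatment arms of the corticosterone stress study
#'
#' Six arms: unstressed control, corticosterone (40 mg/kg s.c.), and
#' corticosterone co-treated with St. John's wort extract Ze 117 at 30, 90
#' or 180 mg/kg, or with escitalopram at 10 mg/kg. The label-to-dose mapping
#' is fixed; `dose_mgkg` is the co-treatment dose (0 for control and
#' corticosterone-only).
#'
#' @return A tibble with columns `label`, `dose_mgkg`, `corticosterone`.
#' @export
treatment_arms <- function() {
  tibble::tibble(
    label = c("CONTROL", "CORT", "CORT_ZE30", "CORT_ZE90", "CORT_ZE180",
              "CORT_ESC"),
    dose_mgkg = c(0, 0, 30, 90, 180, 10),
    corticosterone = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE)
  )
}

arm_levels <- function() treatment_arms()$label

#' Construct a quantification matrix
#'
#' Container for a samples-by-species shotgun-lipidomics quantification:
#' a numeric matrix of pmol amounts (rows = species, columns = samples),
#' the parsed species table, the sample metadata, and optional per-species
#' QC columns (limit of detection, signal-to-noise, blank intensity).
#'
#' @param amounts Numeric matrix, species in rows (rownames = shorthand
#'   names), samples in columns (colnames = sample ids); all values >= 0.
#' @param samples Tibble with columns `sample_id`, `animal_id`, `tissue`
#'   (`"plasma"` or `"hippocampus"`), `arm` (one of [treatment_arms()]
#'   labels), rows matching the columns of `amounts`.
#' @param species Optional pre-parsed species tibble ([parse_species()] of
#'   the rownames); parsed from rownames when omitted.
#' @param lod Limit of detection in pmol: a scalar, or a per-species vector.
#'   Default 0 (no censoring).
#' @param snr,blank_intensity Optional per-species QC vectors.
#' @return An object of class `quant_matrix`.
#' @export
quant_matrix <- function(amounts, samples, species = NULL, lod = 0,
                         snr = NULL, blank_intensity = NULL) {
  stopifnot(is.matrix(amounts), is.numeric(amounts))
  if (any(amounts < 0, na.rm = TRUE) || anyNA(amounts)) {
    stop("amounts must be non-negative and complete")
  }
  if (is.null(rownames(amounts))) stop("amounts must have species rownames")
  if (anyDuplicated(rownames(amounts))) {
    stop("duplicate species name: ",
         rownames(amounts)[duplicated(rownames(amounts))][1])
  }
  samples <- tibble::as_tibble(samples)
  req <- c("sample_id", "animal_id", "tissue", "arm")
  if (!all(req %in% names(samples))) {
    stop("sample metadata must have columns ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  if (is.null(colnames(amounts))) colnames(amounts) <- samples$sample_id
  missing <- setdiff(colnames(amounts), samples$sample_id)
  if (length(missing)) {
    stop("sample(s) absent from metadata: ", paste(missing, collapse = ", "))
  }
  samples <- samples[match(colnames(amounts), samples$sample_id), ]
  bad_arm <- setdiff(unique(samples$arm), arm_levels())
  if (length(bad_arm)) stop("unknown treatment arm: ", bad_arm[1])
  if (is.null(species)) species <- parse_species(rownames(amounts))
  stopifnot(nrow(species) == nrow(amounts))
  if (length(lod) == 1L) lod <- rep(lod, nrow(amounts))
  stopifnot(length(lod) == nrow(amounts), all(lod >= 0))
  structure(
    list(amounts = amounts, samples = samples, species = species,
         lod = lod, snr = snr, blank_intensity = blank_intensity,
         unit = "pmol", lod_mask = NULL),
    class = "quant_matrix"
  )
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix: %d species x %d samples (%s)\n",
              nrow(x$amounts), ncol(x$amounts), x$unit))
  cat("tissue(s):", paste(unique(x$samples$tissue), collapse = ", "), "\n")
  cat("arms:", paste(table(x$samples$arm)[unique(x$samples$arm)],
                     unique(x$samples$arm), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$amounts)

#' Read a quantification table and its sample metadata
#'
#' The quantification table is delimited text with species shorthand names
#' in the first column and one column per sample (pmol amounts). Optional
#' per-species QC columns `lod`, `snr` and `blank_intensity` are recognised
#' by name and removed from the sample block. The metadata table maps
#' `sample_id` to `animal_id`, `tissue` and `arm`. Row and column order are
#' preserved.
#'
#' @param path Quantification table (CSV/TSV; delimiter sniffed by readr).
#' @param meta_path Sample metadata CSV.
#' @return A [quant_matrix()].
#' @export
read_quant_table <- function(path, meta_path) {
  quant <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  meta <- readr::read_csv(meta_path, show_col_types = FALSE, progress = FALSE)
  species_names <- as.character(quant[[1]])
  if (anyDuplicated(species_names)) {
    stop("duplicate species name: ",
         species_names[duplicated(species_names)][1])
  }
  quant <- quant[, -1, drop = FALSE]
  qc_cols <- intersect(c("lod", "snr", "blank_intensity"), names(quant))
  qc <- quant[qc_cols]
  quant <- quant[, setdiff(names(quant), qc_cols), drop = FALSE]
  if (!all(vapply(quant, is.numeric, logical(1)))) {
    bad <- names(quant)[!vapply(quant, is.numeric, logical(1))][1]
    stop("non-numeric amounts in sample column '", bad, "'")
  }
  amounts <- as.matrix(quant)
  rownames(amounts) <- species_names
  quant_matrix(
    amounts, meta,
    lod = if ("lod" %in% qc_cols) qc$lod else 0,
    snr = if ("snr" %in% qc_cols) qc$snr else NULL,
    blank_intensity = if ("blank_intensity" %in% qc_cols)
      qc$blank_intensity else NULL
  )
}

#' Identification quality filter
#'
#' Retains species with signal-to-noise ratio strictly greater than
#' `snr_min` and signal intensity strictly more than `blank_ratio_min`-fold
#' the corresponding blank intensity (both criteria read as strict `>`).
#' Species intensity for the blank comparison is the mean pmol amount
#' across samples. When the QC columns are absent the matrix is returned
#' unchanged with a warning.
#'
#' @param m A [quant_matrix()].
#' @param snr_min Minimum signal-to-noise ratio (exclusive). Default 5.
#' @param blank_ratio_min Minimum signal/blank ratio (exclusive). Default 5.
#' @return Filtered `quant_matrix`; the number of removed species is
#'   reported via `message()`.
#' @export
apply_identification_filter <- function(m, snr_min = 5, blank_ratio_min = 5) {
  stopifnot(inherits(m, "quant_matrix"))
  if (is.null(m$snr) && is.null(m$blank_intensity)) {
    warning("no snr/blank_intensity QC columns; identification filter skipped")
    return(m)
  }
  keep <- rep(TRUE, nrow(m$amounts))
  if (!is.null(m$snr)) keep <- keep & (m$snr > snr_min)
  if (!is.null(m$blank_intensity)) {
    mean_int <- rowMeans(m$amounts)
    keep <- keep & (mean_int > blank_ratio_min * m$blank_intensity)
  }
  message(sum(!keep), " species removed by identification filter")
  subset_quant(m, keep)
}

subset_quant <- function(m, keep) {
  m$amounts <- m$amounts[keep, , drop = FALSE]
  m$species <- m$species[keep, ]
  m$lod <- m$lod[keep]
  if (!is.null(m$snr)) m$snr <- m$snr[keep]
  if (!is.null(m$blank_intensity)) m$blank_intensity <- m$blank_intensity[keep]
  if (!is.null(m$lod_mask)) m$lod_mask <- m$lod_mask[keep, , drop = FALSE]
  m
}

#' Replace sub-LOD amounts by zero
#'
#' Every amount strictly below the species' limit of detection is set to
#' zero; values exactly at the LOD are kept. The mask of replaced cells is
#' retained (`$lod_mask`) for the per-contrast inclusion rule. Species left
#' all-zero are kept: removal happens per contrast, not globally.
#'
#' @param m A [quant_matrix()].
#' @return `quant_matrix` with censored amounts and an updated `lod_mask`.
#' @export
apply_lod <- function(m) {
  stopifnot(inherits(m, "quant_matrix"), m$unit == "pmol")
  below <- sweep(m$amounts, 1, m$lod, "<")
  m$amounts[below] <- 0
  m$lod_mask <- below
  m
}

#' Normalize to mol% per total lipids
#'
#' Within each sample, each species' amount is expressed as a percentage of
#' the summed amount over all retained species, so every sample's values
#' sum to 100. Zeros (censored species) stay zero and still contribute zero
#' to the denominator. Idempotent up to the unit change.
#'
#' @param m A [quant_matrix()].
#' @return `quant_matrix` with `unit == "molpct"`.
#' @export
to_molpct <- function(m) {
  stopifnot(inherits(m, "quant_matrix"))
  totals <- colSums(m$amounts)
  if (any(totals <= 0)) {
    stop("sample(s) with no positive amounts: ",
         paste(colnames(m$amounts)[totals <= 0], collapse = ", "))
  }
  m$amounts <- sweep(m$amounts, 2, totals, "/") * 100
  m$unit <- "molpct"
  m
}

#' Long-format view of a quantification matrix
#'
#' @param x A [quant_matrix()].
#' @param ... Unused.
#' @return Tidy tibble with one row per (sample, species): `sample_id`,
#'   `animal_id`, `tissue`, `arm`, `species`, `class_code`,
#'   `total_carbons`, `total_double_bonds`, and the amount column named
#'   after the unit (`pmol` or `molpct`).
#' @export
quant_long <- function(x, ...) {
  stopifnot(inherits(x, "quant_matrix"))
  long <- tibble::tibble(
    sample_id = rep(colnames(x$amounts), each = nrow(x$amounts)),
    species = rep(rownames(x$amounts), times = ncol(x$amounts)),
    value = as.vector(x$amounts)
  )
  names(long)[names(long) == "value"] <- x$unit
  long <- dplyr::left_join(long, x$samples, by = "sample_id")
  sp <- dplyr::rename(x$species, species = "raw_name")
  dplyr::left_join(
    long, sp[c("species", "class_code", "total_carbons", "total_double_bonds")],
    by = "species"
  )
}

#' Write the tidy long-format table
#'
#' @param m A [quant_matrix()] (pmol); its mol% view is added as a column.
#' @param path Output CSV path.
#' @export
write_quant_long <- function(m, path) {
  stopifnot(m$unit == "pmol")
  long <- quant_long(m)
  long$molpct <- quant_long(to_molpct(m))$molpct
  readr::write_csv(long, path)
  invisible(path)
}
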