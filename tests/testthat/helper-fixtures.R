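# Small in-code fixtures shared across test files.

# A quant_matrix built directly from a numeric matrix; one sample per
# animal, arms recycled over the requested labels.
toy_quant <- function(amounts, arms, tissue = "hippocampus", lod = 0,
                      snr = NULL, blank_intensity = NULL,
                      unit = c("pmol", "molpct")) {
  unit <- match.arg(unit)
  n <- ncol(amounts)
  samples <- tibble::tibble(
    sample_id = paste0("S", seq_len(n)),
    animal_id = paste0("A", seq_len(n)),
    tissue = tissue,
    arm = rep(arms, length.out = n)
  )
  colnames(amounts) <- samples$sample_id
  m <- quant_matrix(amounts, samples, lod = lod, snr = snr,
                    blank_intensity = blank_intensity)
  m$unit <- unit
  m
}

# Random registry-conformant shorthand names in canonical form.
random_species_names <- function(n, registry = lipid_class_registry()) {
  codes <- sample(registry$code, n, replace = TRUE)
  carbons <- sample(12:60, n, replace = TRUE)
  db <- vapply(carbons, function(cc) sample.int(min(cc - 1, 12), 1) - 1L,
               integer(1))
  sep <- ifelse(endsWith(codes, "O-"), "", " ")
  paste0(codes, sep, carbons, ":", db)
}

# Names for a generated matrix: distinct carbons so parses are unique.
species_names_for <- function(n) {
  paste0("PC ", seq(30, by = 2, length.out = n), ":2")
}
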