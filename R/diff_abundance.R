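#' The five treatment contrasts of interest
#'
#' Corticosterone vs control (the stress effect), and each co-treatment arm
#' (Ze 117 at 30/90/180 mg/kg, escitalopram 10 mg/kg) vs corticosterone
#' alone (the treatment effects). Each contrast is the difference of two
#' arm means within the one-factor model fit on all arms jointly.
#'
#' @return Tibble with columns `name`, `arm_a` (tested arm), `arm_b`
#'   (baseline arm).
#' @export
default_contrasts <- function() {
  tibble::tibble(
    name = c("CORT_vs_CONTROL", "ZE30+CORT_vs_CORT", "ZE90+CORT_vs_CORT",
             "ZE180+CORT_vs_CORT", "ESC+CORT_vs_CORT"),
    arm_a = c("CORT", "CORT_ZE30", "CORT_ZE90", "CORT_ZE180", "CORT_ESC"),
    arm_b = c("CONTROL", "CORT", "CORT", "CORT", "CORT")
  )
}

#' Per-contrast inclusion rule
#'
#' A lipid enters a contrast only if each of the two conditions has at
#' least one value above the limit of detection, i.e. at least one non-zero
#' value after LOD replacement.
#'
#' @param values_a,values_b Mol% (or pmol) vectors for the two conditions,
#'   after LOD replacement.
#' @return `TRUE` iff both conditions have >= 1 positive value.
#' @export
include_species <- function(values_a, values_b) {
  stopifnot(length(values_a) > 0, length(values_b) > 0)
  any(values_a > 0) && any(values_b > 0)
}

#' Fit the one-factor model and test all contrasts for every lipid
#'
#' For each lipid, a single one-factor (cell-means) linear model of mol% on
#' treatment arm is fit jointly on all arms, so the residual variance pools
#' across arms with df = N - k. Each contrast is tested with a t-test:
#' estimate = mean(arm_a) - mean(arm_b), SE = sqrt(s2 (1/n_a + 1/n_b)) with
#' s2 the pooled residual mean square, two-sided p from the t distribution
#' on N - k df. log2 fold change is log2(mean_a/mean_b), reported as NA
#' with `fc_undefined = TRUE` when either mean is zero (no pseudo-count).
#' Lipids failing the inclusion rule for a contrast keep a row with
#' `included = FALSE` and NA statistics. Benjamini–Hochberg FDR is applied
#' separately within each contrast across all included lipids.
#'
#' With zero pooled variance the p-value degenerates: 1 when the estimate
#' is also 0, else 0, flagged in `degenerate`.
#'
#' @param m A [quant_matrix()] in mol% (converted internally if in pmol;
#'   apply [apply_lod()] first so censored cells are zero).
#' @param contrasts Contrast table as [default_contrasts()].
#' @return Tibble, one row per (species, contrast): `species`, `contrast`,
#'   `arm_a`, `arm_b`, `n_a`, `n_b`, `included`, `estimate`, `log2fc`,
#'   `fc_undefined`, `t`, `df`, `p`, `fdr`, `degenerate`.
#' @export
fit_contrasts <- function(m, contrasts = default_contrasts()) {
  stopifnot(inherits(m, "quant_matrix"))
  if (m$unit != "molpct") m <- to_molpct(m)
  x <- m$amounts
  arm <- as.character(m$samples$arm)
  arms <- unique(arm)
  k <- length(arms)
  n_tot <- ncol(x)
  stopifnot(n_tot > k)

  # cell means and pooled residual mean square, vectorized over species
  idx <- lapply(arms, function(a) which(arm == a))
  names(idx) <- arms
  ns <- lengths(idx)
  means <- vapply(arms, function(a) rowMeans(x[, idx[[a]], drop = FALSE]),
                  numeric(nrow(x)))
  if (nrow(x) == 1L) means <- matrix(means, nrow = 1,
                                     dimnames = list(NULL, arms))
  fitted <- means[, arm, drop = FALSE]
  rss <- rowSums((x - fitted)^2)
  s2 <- rss / (n_tot - k)
  npos <- vapply(arms, function(a)
    rowSums(x[, idx[[a]], drop = FALSE] > 0), numeric(nrow(x)))
  if (nrow(x) == 1L) npos <- matrix(npos, nrow = 1,
                                    dimnames = list(NULL, arms))

  res <- lapply(seq_len(nrow(contrasts)), function(ci) {
    a <- contrasts$arm_a[ci]
    b <- contrasts$arm_b[ci]
    stopifnot(a %in% arms, b %in% arms)
    included <- unname(npos[, a] >= 1 & npos[, b] >= 1)
    est <- unname(means[, a] - means[, b])
    se <- unname(sqrt(s2 * (1 / ns[[a]] + 1 / ns[[b]])))
    degen <- se == 0
    t_stat <- ifelse(degen, ifelse(est == 0, 0, Inf * sign(est)), est / se)
    p <- ifelse(degen, ifelse(est == 0, 1, 0),
                2 * stats::pt(-abs(t_stat), df = n_tot - k))
    fc_undef <- unname(means[, a] <= 0 | means[, b] <= 0)
    log2fc <- ifelse(fc_undef, NA_real_, unname(log2(means[, a] / means[, b])))
    p[!included] <- NA_real_
    fdr <- rep(NA_real_, length(p))
    fdr[included] <- bh_fdr(p[included])
    tibble::tibble(
      species = rownames(x),
      contrast = contrasts$name[ci],
      arm_a = a, arm_b = b,
      n_a = ns[[a]], n_b = ns[[b]],
      included = included,
      estimate = ifelse(included, est, NA_real_),
      log2fc = ifelse(included, log2fc, NA_real_),
      fc_undefined = included & fc_undef,
      t = ifelse(included, t_stat, NA_real_),
      df = n_tot - k,
      p = p,
      fdr = fdr,
      degenerate = included & degen
    )
  })
  dplyr::bind_rows(res)
}

#' Benjamini–Hochberg FDR adjustment
#'
#' Step-up adjustment: with p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1, returned in
#' input order. Delegates to [stats::p.adjust()].
#'
#' @param p Numeric p-values in \[0, 1\].
#' @return Adjusted values (q-values) in input order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))  # all 0.03
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Volcano-plot table for one contrast
#'
#' @param results One contrast's rows from [fit_contrasts()].
#' @param fdr_threshold Significance threshold on the FDR (default 0.05).
#' @return Tibble: `species`, `log2fc`, `neglog10_p`, `fdr`, `significant`;
#'   excluded species are dropped.
#' @export
volcano_table <- function(results, fdr_threshold = 0.05) {
  stopifnot(length(unique(results$contrast)) == 1L)
  r <- results[results$included, ]
  tibble::tibble(
    species = r$species,
    log2fc = r$log2fc,
    neglog10_p = -log10(r$p),
    fdr = r$fdr,
    significant = !is.na(r$fdr) & r$fdr < fdr_threshold
  )
}

#' QQ table of observed vs expected -log10 p for one contrast
#'
#' Expected quantiles are the uniform plotting positions
#' \eqn{(i - 0.5)/n} for the sorted p-values; under a global null the
#' points lie near the diagonal.
#'
#' @param results One contrast's rows from [fit_contrasts()].
#' @return Tibble: `species` (in ascending-p order), `expected_neglog10`,
#'   `observed_neglog10`.
#' @export
qq_table <- function(results) {
  stopifnot(length(unique(results$contrast)) == 1L)
  r <- results[results$included & !is.na(results$p), ]
  ord <- order(r$p)
  n <- nrow(r)
  tibble::tibble(
    species = r$species[ord],
    expected_neglog10 = -log10((seq_len(n) - 0.5) / n),
    observed_neglog10 = -log10(r$p[ord])
  )
}
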