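#' Mol%-weighted average number of double bonds
#'
#' The average number of double bonds over a species set is the
#' mol%-weighted arithmetic mean of each species' total double-bond count:
#' \deqn{DB_{av} = \sum_i DB_i \, w_i / \sum_i w_i}
#' with weights \eqn{w_i} the species' mol% values. The weighted mean is
#' invariant to the normalization constant, so within-class scopes need no
#' renormalization: per-total-lipid mol% weights give the same answer.
#'
#' @param molpct Non-negative weights (mol% per species).
#' @param db Total double-bond counts per species.
#' @return The weighted mean, a single number.
#' @export
#' @examples
#' db_average(c(25, 75), c(1, 3))  # 2.5
db_average <- function(molpct, db) {
  weighted_structural_mean(molpct, db)
}

#' Mol%-weighted average fatty-acid chain length
#'
#' As [db_average()], with the species' total acyl carbon count in place of
#' the double-bond count.
#'
#' @param molpct Non-negative weights (mol% per species).
#' @param carbons Total acyl carbon counts per species.
#' @return The weighted mean, a single number.
#' @export
#' @examples
#' chain_length_average(c(80, 20), c(34, 52))  # 37.6
chain_length_average <- function(molpct, carbons) {
  weighted_structural_mean(molpct, carbons)
}

weighted_structural_mean <- function(w, x) {
  stopifnot(length(w) == length(x))
  if (length(w) == 0L) stop("empty scope")
  if (any(w < 0) || anyNA(w) || anyNA(x)) {
    stop("weights must be non-negative and complete")
  }
  tot <- sum(w)
  if (tot <= 0) stop("all-zero weights in scope")
  sum(x * w) / tot
}

#' Per-sample structural summary
#'
#' For each sample, computes the mol%-weighted average double bonds and
#' chain length plus the saturated/unsaturated mol% split, over either all
#' retained lipids (`scope = "all"`) or one lipid class
#' (`scope = <class code>`). Weights are mol% per total lipids; for a class
#' scope the weighted means are over the class' species only (equivalent to
#' within-class renormalization).
#'
#' @param m A [quant_matrix()]; converted to mol% internally if needed.
#' @param scope `"all"` or a class code present in the matrix.
#' @return Tibble with one row per sample: `sample_id`, `animal_id`,
#'   `tissue`, `arm`, `scope`, `db_av`, `cl_av`, `sat_molpct`,
#'   `unsat_molpct`.
#' @export
structural_summary <- function(m, scope = "all") {
  stopifnot(inherits(m, "quant_matrix"))
  if (m$unit != "molpct") m <- to_molpct(m)
  keep <- if (identical(scope, "all")) {
    rep(TRUE, nrow(m$amounts))
  } else {
    m$species$class_code == scope
  }
  if (!any(keep)) stop("no species in scope '", scope, "'")
  w <- m$amounts[keep, , drop = FALSE]
  db <- m$species$total_double_bonds[keep]
  cc <- m$species$total_carbons[keep]
  sat <- db == 0
  tibble::tibble(
    sample_id = colnames(m$amounts),
    animal_id = m$samples$animal_id,
    tissue = m$samples$tissue,
    arm = m$samples$arm,
    scope = if (identical(scope, "all")) "all-lipids" else scope,
    db_av = apply(w, 2, function(col) weighted_structural_mean(col, db)),
    cl_av = apply(w, 2, function(col) weighted_structural_mean(col, cc)),
    sat_molpct = unname(colSums(w[sat, , drop = FALSE])),
    unsat_molpct = unname(colSums(w[!sat, , drop = FALSE]))
  )
}

#' Saturated/unsaturated mol% partition of a lipid class
#'
#' Splits a class' per-sample mol% (per total lipids) into the summed mol%
#' of its saturated species (zero double bonds) and of its unsaturated
#' species (one or more); the two parts add to the class total.
#'
#' @param m A [quant_matrix()].
#' @param class_code Class to partition, e.g. `"LPE"`.
#' @return Tibble per sample: `sample_id`, `arm`, `sat_molpct`,
#'   `unsat_molpct`.
#' @export
saturation_partition <- function(m, class_code) {
  s <- structural_summary(m, scope = class_code)
  s[c("sample_id", "animal_id", "tissue", "arm", "sat_molpct", "unsat_molpct")]
}

#' Holm–Šídák step-down adjustment
#'
#' Orders the m raw p-values ascending and sets
#' \eqn{adj_{(i)} = \max_{j \le i} 1 - (1 - p_{(j)})^{m - j + 1}}, capped at
#' 1, returned in the input order. Adjusted values are never smaller than
#' the raw ones and are non-decreasing in the sorted order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
#' @examples
#' holm_sidak_adjust(c(0.01, 0.04))  # 0.0199, 0.04
holm_sidak_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  ord <- order(p)
  sidak <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- cummax(sidak)
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' One-way ANOVA with Holm–Šídák follow-up versus a reference arm
#'
#' Fits a one-way ANOVA of the values on treatment arm (between/within mean
#' squares, df k-1 and N-k), then tests each non-reference arm against the
#' reference with t-tests using the pooled within-group variance (the ANOVA
#' residual mean square, df N-k) and adjusts the family with
#' [holm_sidak_adjust()]. With zero variance both between and within
#' groups, F is defined as 0 (p = 1).
#'
#' @param values Numeric response.
#' @param arm Grouping factor/character, same length.
#' @param reference Reference arm label (default `"CORT"`).
#' @return List with `anova` (tibble: F, p, df) and `comparisons` (tibble
#'   per non-reference arm: means, SEM, raw and adjusted p).
#' @export
anova_holm_sidak <- function(values, arm, reference = "CORT") {
  stopifnot(length(values) == length(arm))
  arm <- as.character(arm)
  stopifnot(reference %in% arm)
  groups <- split(values, arm)
  if (length(groups) < 2L || any(lengths(groups) < 2L)) {
    stop("need >= 2 arms with >= 2 values each")
  }
  k <- length(groups)
  n_tot <- length(values)
  fit <- stats::lm(values ~ factor(arm))
  av <- stats::anova(fit)
  ms_within <- av["Residuals", "Mean Sq"]
  f_stat <- av[1, "F value"]
  p_anova <- av[1, "Pr(>F)"]
  if (!is.finite(f_stat)) {  # zero within-group variance
    ms_between <- av[1, "Mean Sq"]
    if (ms_between == 0) {
      f_stat <- 0
      p_anova <- 1
    } else {
      f_stat <- Inf
      p_anova <- 0
    }
  }
  means <- vapply(groups, mean, numeric(1))
  ns <- lengths(groups)
  sems <- vapply(groups, function(g) stats::sd(g) / sqrt(length(g)),
                 numeric(1))
  others <- setdiff(names(groups), reference)
  df_res <- n_tot - k
  t_stat <- vapply(others, function(a) {
    se <- sqrt(ms_within * (1 / ns[[a]] + 1 / ns[[reference]]))
    if (se == 0) {
      if (means[[a]] == means[[reference]]) 0 else Inf * sign(means[[a]] - means[[reference]])
    } else {
      (means[[a]] - means[[reference]]) / se
    }
  }, numeric(1))
  p_raw <- 2 * stats::pt(-abs(t_stat), df = df_res)
  ref_label <- reference
  list(
    anova = tibble::tibble(F = f_stat, p = p_anova,
                           df_between = k - 1, df_within = df_res),
    comparisons = tibble::tibble(
      arm = others,
      reference = ref_label,
      mean = unname(means[others]),
      sem = unname(sems[others]),
      mean_ref = means[[ref_label]],
      sem_ref = sems[[ref_label]],
      n = as.integer(ns[others]),
      t = unname(t_stat),
      p = unname(p_raw),
      adj_p = holm_sidak_adjust(p_raw)
    )
  )
}

#' Arm-level group comparison of a structural statistic
#'
#' Convenience wrapper: runs [anova_holm_sidak()] on one column of a
#' [structural_summary()] table.
#'
#' @param summary_tbl Output of [structural_summary()].
#' @param stat Column to compare (`"db_av"`, `"cl_av"`, `"sat_molpct"` or
#'   `"unsat_molpct"`).
#' @param reference Reference arm.
#' @return As [anova_holm_sidak()], with the scope and statistic recorded.
#' @export
compare_structural_stat <- function(summary_tbl, stat = "db_av",
                                    reference = "CORT") {
  stopifnot(stat %in% names(summary_tbl))
  res <- anova_holm_sidak(summary_tbl[[stat]], summary_tbl$arm, reference)
  res$comparisons$scope <- unique(summary_tbl$scope)
  res$comparisons$statistic <- stat
  res
}
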