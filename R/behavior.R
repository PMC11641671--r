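#' Spearman rank correlation
#'
#' Rho is the Pearson correlation of average (mid-) ranks, so ties are
#' handled by average ranks. The two-sided p-value uses the t
#' approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n - 2 df; when
#' \eqn{|\rho| = 1} the p-value is reported at a continuity floor
#' (`.Machine$double.xmin`) rather than exactly 0. For small samples
#' (n <= 10, no ties) an exact permutation p-value is available.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @param exact Use the exact permutation null (n <= 10 only).
#' @return List with `rho`, `p`, `n`.
#' @export
#' @examples
#' spearman_rank(c(1, 2, 3, 4), c(2, 1, 4, 3))  # rho = 0.6
spearman_rank <- function(x, y, exact = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: Spearman correlation undefined")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  if (exact) {
    if (n > 10L) stop("exact permutation p only for n <= 10")
    perms <- all_permutations(n)
    rho_null <- apply(perms, 1, function(pp) stats::cor(rx, ry[pp]))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1 - 1e-15) {
    p <- .Machine$double.xmin
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Read a forced-swim-test behavior table
#'
#' @param path CSV with columns `animal_id`, `total_immobility_s`,
#'   `latency_s` (seconds within the 600 s session).
#' @return Validated tibble.
#' @export
read_behavior_table <- function(path) {
  b <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_behavior(b)
}

validate_behavior <- function(b) {
  req <- c("animal_id", "total_immobility_s", "latency_s")
  stopifnot(all(req %in% names(b)))
  with(b, stopifnot(
    all(total_immobility_s >= 0 & total_immobility_s <= 600),
    all(latency_s >= 0 & latency_s <= 600)
  ))
  tibble::as_tibble(b)
}

#' The two correlation subsets of the study
#'
#' `all-arms` takes every treatment group; `cort-and-cotreated` takes the
#' corticosterone arm together with the three Ze 117 co-treatment arms
#' (the subset in which the lipid–behavior coupling is visible, since the
#' unstressed control sits off the stress axis). An escitalopram-including
#' variant is provided for completeness.
#'
#' @param subset One of `"all-arms"`, `"cort-and-cotreated"`,
#'   `"cort-cotreated-esc"`.
#' @return Character vector of arm labels.
#' @export
correlation_subset_arms <- function(subset = c("all-arms",
                                               "cort-and-cotreated",
                                               "cort-cotreated-esc")) {
  subset <- match.arg(subset)
  switch(subset,
    "all-arms" = arm_levels(),
    "cort-and-cotreated" = c("CORT", "CORT_ZE30", "CORT_ZE90", "CORT_ZE180"),
    "cort-cotreated-esc" = c("CORT", "CORT_ZE30", "CORT_ZE90", "CORT_ZE180",
                             "CORT_ESC")
  )
}

#' Correlate lipid species with latency to first immobility
#'
#' For every species, the Spearman rank correlation between the animals'
#' mol% values and their latency to first immobility, within a treatment
#' subset. Samples are joined to behavior records by `animal_id`; animals
#' missing behavior are dropped with a message.
#'
#' @param m A [quant_matrix()] (one tissue); converted to mol% if needed.
#' @param behavior Behavior tibble (see [read_behavior_table()]).
#' @param subset Subset name, see [correlation_subset_arms()].
#' @param species Optional character vector restricting the species tested.
#' @return Tibble per species: `species`, `subset`, `rho`, `p`, `n`.
#' @export
correlate_lipids <- function(m, behavior, subset = "cort-and-cotreated",
                             species = NULL) {
  stopifnot(inherits(m, "quant_matrix"))
  behavior <- validate_behavior(behavior)
  if (m$unit != "molpct") m <- to_molpct(m)
  arms <- correlation_subset_arms(subset)
  in_subset <- m$samples$arm %in% arms
  have_beh <- m$samples$animal_id %in% behavior$animal_id
  n_missing <- sum(in_subset & !have_beh)
  if (n_missing > 0) {
    message(n_missing, " animal(s) without behavior records dropped")
  }
  keep <- in_subset & have_beh
  stopifnot(sum(keep) >= 3)
  lat <- behavior$latency_s[match(m$samples$animal_id[keep],
                                  behavior$animal_id)]
  x <- m$amounts[, keep, drop = FALSE]
  sp <- if (is.null(species)) rownames(x) else species
  stopifnot(all(sp %in% rownames(x)))
  res <- lapply(sp, function(s) {
    v <- x[s, ]
    if (stats::sd(v) == 0) {
      return(tibble::tibble(species = s, subset = subset, rho = NA_real_,
                            p = NA_real_, n = length(v)))
    }
    r <- spearman_rank(v, lat)
    tibble::tibble(species = s, subset = subset, rho = r$rho, p = r$p,
                   n = r$n)
  })
  dplyr::bind_rows(res)
}

#' Arm-level statistics of the forced-swim-test measures
#'
#' One-way ANOVA followed by Holm–Šídák tests versus a reference arm, run
#' separately on total immobility and latency to first immobility.
#'
#' @param behavior Behavior tibble with an `arm` column.
#' @param reference Reference arm (default `"CORT"`).
#' @return Named list (`total_immobility_s`, `latency_s`) of
#'   [anova_holm_sidak()] results.
#' @export
fst_group_stats <- function(behavior, reference = "CORT") {
  stopifnot("arm" %in% names(behavior))
  lapply(
    stats::setNames(nm = c("total_immobility_s", "latency_s")),
    function(col) anova_holm_sidak(behavior[[col]], behavior$arm, reference)
  )
}

#' Select a homogeneous subgroup per arm by trimming extremes
#'
#' Within each arm, repeatedly drops the most extreme latency values —
#' alternating current maximum, then current minimum — until `k` animals
#' remain, ties broken by `animal_id` order. Deterministic given the input
#' order; the retained latencies always have variance no larger than the
#' arm's original variance.
#'
#' @param behavior Behavior tibble with `arm` and `latency_s`.
#' @param k Animals to retain per arm.
#' @return The retained rows (all arms), original order within arm.
#' @export
select_subgroup <- function(behavior, k) {
  stopifnot("arm" %in% names(behavior), k >= 1)
  parts <- split(seq_len(nrow(behavior)), behavior$arm)
  keep_idx <- unlist(lapply(parts, function(rows) {
    if (length(rows) < k) stop("arm smaller than requested subgroup size k")
    lat <- behavior$latency_s[rows]
    aid <- behavior$animal_id[rows]
    active <- seq_along(rows)
    drop_max <- TRUE
    while (length(active) > k) {
      v <- lat[active]
      pick <- if (drop_max) {
        cand <- active[v == max(v)]
        cand[order(aid[cand])][1]
      } else {
        cand <- active[v == min(v)]
        cand[order(aid[cand])][1]
      }
      active <- setdiff(active, pick)
      drop_max <- !drop_max
    }
    rows[active]
  }), use.names = FALSE)
  behavior[sort(keep_idx), ]
}
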