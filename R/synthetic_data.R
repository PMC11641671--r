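#' @importFrom rlang .data
NULL

# Fixed seed for the *structure* of a simulated study (species catalogs,
# within-class abundance shares, random effect subsets). Kept separate from
# the user seed so distinct user seeds draw distinct noise over an identical
# ground-truth structure.
STRUCTURE_SEED <- 104729L

# Per-tissue class composition: species counts, carbon/double-bond grids,
# class share of total lipid abundance, and the modal carbon number used to
# shape within-class abundance. Counts sum to 696 (plasma) and 953
# (hippocampus); the LPE class is a fixed species list (below) in both.
class_composition <- function(tissue) {
  if (tissue == "plasma") {
    comp <- tibble::tribble(
      ~class_code, ~n, ~c_min, ~c_max, ~db_max, ~share, ~c_mode,
      "CE",      60, 12, 24,  6, 0.160, 18,
      "TAG",    110, 40, 60, 11, 0.160, 52,
      "DAG",     40, 28, 40,  6, 0.030, 34,
      "PC",     110, 30, 44, 11, 0.300, 34,
      "PC O-",   40, 30, 44,  8, 0.030, 34,
      "PE",      70, 30, 44, 11, 0.060, 36,
      "PE O-",   30, 30, 44,  8, 0.020, 36,
      "PS",      25, 32, 44,  8, 0.020, 38,
      "PI",      25, 32, 44,  8, 0.030, 38,
      "PA",      15, 30, 44,  8, 0.005, 36,
      "PG",      15, 30, 44,  8, 0.005, 36,
      "CL",      13, 60, 80, 10, 0.005, 72,
      "SM",      40, 28, 44,  3, 0.090, 36,
      "Cer",     25, 28, 44,  3, 0.020, 36,
      "HexCer",  15, 28, 44,  3, 0.010, 38,
      "LPC",     25, 12, 24,  6, 0.025, 18,
      "LPC O-",   8, 12, 24,  4, 0.003, 18,
      "LPA",      5, 14, 22,  4, 0.002, 18,
      "LPI",      8, 14, 22,  5, 0.003, 18,
      "LPS",      6, 14, 22,  5, 0.002, 18
    )
  } else if (tissue == "hippocampus") {
    comp <- tibble::tribble(
      ~class_code, ~n, ~c_min, ~c_max, ~db_max, ~share, ~c_mode,
      "PC",     150, 30, 44, 11, 0.280, 34,
      "PC O-",   50, 30, 44,  8, 0.030, 34,
      "PE",     140, 30, 44, 11, 0.220, 38,
      "PE O-",   90, 30, 44,  9, 0.080, 38,
      "PS",      70, 32, 44,  8, 0.100, 40,
      "PI",      50, 32, 44,  8, 0.040, 38,
      "PA",      22, 30, 44,  8, 0.010, 36,
      "PG",      25, 30, 44,  8, 0.010, 36,
      "CL",      30, 60, 80, 10, 0.010, 72,
      "SM",      60, 28, 44,  3, 0.060, 38,
      "Cer",     50, 28, 44,  3, 0.030, 38,
      "HexCer",  45, 28, 44,  3, 0.040, 40,
      "DAG",     30, 28, 40,  6, 0.010, 34,
      "TAG",     60, 40, 60, 11, 0.020, 52,
      "CE",      20, 12, 24,  6, 0.005, 18,
      "LPC",     20, 12, 24,  6, 0.006, 18,
      "LPC O-",   8, 12, 24,  4, 0.002, 18,
      "LPA",      6, 14, 22,  4, 0.002, 18,
      "LPI",     10, 14, 22,  5, 0.003, 18,
      "LPS",      6, 14, 22,  5, 0.002, 18
    )
  } else {
    stop("unknown tissue: ", tissue)
  }
  comp
}

# The LPE class is fixed in both tissues: the unsaturated species of
# interest plus a saturated complement. `share_in_class` splits the class
# total (~0.4 mol% of all lipids) into ~0.195 saturated / ~0.205
# unsaturated mol%.
lpe_catalog <- function() {
  tibble::tibble(
    species = c("LPE 16:0", "LPE 18:0", "LPE 20:0",
                "LPE 18:1", "LPE 18:2", "LPE 20:1", "LPE 20:3",
                "LPE 20:4", "LPE 22:4", "LPE 22:5", "LPE 22:6"),
    share_in_class = c(
      0.5125 * c(0.35, 0.55, 0.10),
      0.4875 * c(0.30, 0.10, 0.08, 0.10, 0.18, 0.06, 0.06, 0.12)
    )
  )
}

LPE_CLASS_SHARE <- 0.004

# Deterministic species catalog for one tissue: species names, structural
# features and baseline abundance shares. Within-class shares decay with
# double-bond count and distance from the modal carbon number, with
# lognormal scatter, so the full catalog spans ~4 orders of magnitude.
build_catalog <- function(tissue, n_species = NULL) {
  comp <- class_composition(tissue)
  if (!is.null(n_species)) {
    scale <- (n_species - nrow(lpe_catalog())) / sum(comp$n)
    comp$n <- pmax(1L, as.integer(round(comp$n * scale)))
    # absorb rounding drift in the largest class
    drift <- (n_species - nrow(lpe_catalog())) - sum(comp$n)
    comp$n[which.max(comp$n)] <- comp$n[which.max(comp$n)] + drift
  }
  rows <- lapply(seq_len(nrow(comp)), function(i) {
    cl <- comp[i, ]
    grid <- expand.grid(carbons = cl$c_min:cl$c_max, db = 0:cl$db_max)
    grid <- grid[grid$db < grid$carbons, ]
    stopifnot(nrow(grid) >= cl$n)
    pick <- sort(sample.int(nrow(grid), cl$n))
    g <- grid[pick, ]
    raw <- exp(-0.25 * g$db) *
      exp(-((g$carbons - cl$c_mode) / 6)^2) *
      stats::rlnorm(cl$n, 0, 1.2)
    sep <- if (endsWith(cl$class_code, "O-")) "" else " "
    tibble::tibble(
      species = paste0(cl$class_code, sep, g$carbons, ":", g$db),
      class_code = cl$class_code,
      carbons = g$carbons,
      db = g$db,
      share = cl$share * raw / sum(raw)
    )
  })
  cat <- dplyr::bind_rows(rows)
  lpe <- lpe_catalog()
  parsed <- parse_species(lpe$species)
  cat <- dplyr::bind_rows(cat, tibble::tibble(
    species = lpe$species,
    class_code = "LPE",
    carbons = parsed$total_carbons,
    db = parsed$total_double_bonds,
    share = LPE_CLASS_SHARE * lpe$share_in_class
  ))
  stopifnot(!anyDuplicated(cat$species))
  cat$share <- cat$share / sum(cat$share)
  cat
}

# Default injected effects, pmol scale (multiplicative, log2). Every arm
# except the unstressed control receives corticosterone, so stress effects
# apply to all five corticosterone-containing arms; only the LPE dose
# response distinguishes the co-treatment arms from corticosterone alone.
#  * hippocampus: dose-ordered increase of every unsaturated LPE species in
#    the Ze 117 co-treatment arms and the escitalopram arm;
#  * hippocampus: a mild stress upshift of a PE O- subset;
#  * plasma: a broad random-subset stress upshift plus a stronger TAG
#    upshift (which drags the mol%-weighted average chain length up).
default_effects <- function(catalogs) {
  cort_arms <- c("CORT", "CORT_ZE30", "CORT_ZE90", "CORT_ZE180", "CORT_ESC")
  eff <- list()
  if ("hippocampus" %in% names(catalogs)) {
    cat <- catalogs$hippocampus
    lpe_unsat <- cat$species[cat$class_code == "LPE" & cat$db >= 1]
    for (spec in list(c("CORT_ZE30", 0.25), c("CORT_ZE90", 0.45),
                      c("CORT_ZE180", 0.70), c("CORT_ESC", 0.80))) {
      eff[[length(eff) + 1L]] <- tibble::tibble(
        tissue = "hippocampus", arm = spec[1],
        log2fc = as.numeric(spec[2]), species = list(lpe_unsat),
        label = "unsat_lpe_dose_response"
      )
    }
    peo <- cat$species[cat$class_code == "PE O-"]
    peo_hit <- sort(sample(peo, size = min(15L, length(peo))))
    for (arm in cort_arms) {
      eff[[length(eff) + 1L]] <- tibble::tibble(
        tissue = "hippocampus", arm = arm, log2fc = 0.6,
        species = list(peo_hit), label = "peo_stress_upshift"
      )
    }
  }
  if ("plasma" %in% names(catalogs)) {
    cat <- catalogs$plasma
    broad <- sort(sample(cat$species, size = round(0.4 * nrow(cat))))
    tags <- cat$species[cat$class_code == "TAG"]
    for (arm in cort_arms) {
      eff[[length(eff) + 1L]] <- tibble::tibble(
        tissue = "plasma", arm = arm, log2fc = 0.8,
        species = list(broad), label = "broad_stress_upshift"
      )
      eff[[length(eff) + 1L]] <- tibble::tibble(
        tissue = "plasma", arm = arm, log2fc = 0.9,
        species = list(tags), label = "tag_stress_upshift"
      )
    }
  }
  dplyr::bind_rows(eff)
}

#' Simulation configuration
#'
#' Assembles the design of a simulated corticosterone-stress lipidomics
#' study: six treatment arms at `n_per_arm` animals each, per-tissue
#' species catalogs with baseline abundance shares spanning ~4 orders of
#' magnitude, lognormal within-arm noise at coefficient of variation
#' `noise_cv`, quantile LOD censoring, multiplicative arm effects
#' (`effects`), and a behavior model coupling latency to first immobility
#' to the animal's hippocampal unsaturated-LPE mol%.
#'
#' The catalogs, within-class shares and random effect subsets are drawn
#' under a fixed internal structure seed, so two configs differing only in
#' `seed` share an identical ground truth and differ only in noise.
#'
#' @param seed Integer seed for the stochastic draw.
#' @param n_per_arm Animals per arm (default 8).
#' @param noise_cv Within-arm coefficient of variation of each species'
#'   amount (default 0.20).
#' @param lod_quantile Fraction of the lowest generated amounts censored at
#'   the limit of detection (default 0.02).
#' @param tissues Tissues to simulate.
#' @param n_species Optional named list/vector overriding the species count
#'   per tissue (catalog scaled proportionally; default 696 plasma, 953
#'   hippocampus).
#' @param effects `"default"` for the study's effect structure, `"none"`
#'   for a global null, or a custom tibble with columns `tissue`, `arm`,
#'   `log2fc`, `species` (list-column), `label`.
#' @param behavior_coupling List: `intercept` and `slope` of latency (s) on
#'   hippocampal unsaturated-LPE mol%, Gaussian `sd` (s), and
#'   `control_offset` — the extra latency of the unstressed control arm,
#'   which sits off the stress axis.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_per_arm = 8L,
                       noise_cv = 0.20,
                       lod_quantile = 0.02,
                       tissues = c("plasma", "hippocampus"),
                       n_species = NULL,
                       effects = "default",
                       behavior_coupling = list(intercept = -5, slope = 360,
                                                sd = 18, control_offset = 45)) {
  stopifnot(n_per_arm >= 1, noise_cv > 0,
            lod_quantile >= 0, lod_quantile < 1,
            all(tissues %in% c("plasma", "hippocampus")))
  catalogs <- with_structure_seed(
    lapply(stats::setNames(nm = tissues), function(tt)
      build_catalog(tt, n_species = n_species[[tt]]))
  )
  if (identical(effects, "default")) {
    effects <- with_structure_seed(default_effects(catalogs), offset = 1L)
  } else if (identical(effects, "none")) {
    effects <- tibble::tibble(tissue = character(), arm = character(),
                              log2fc = numeric(), species = list(),
                              label = character())
  }
  cfg <- structure(
    list(seed = as.integer(seed), n_per_arm = as.integer(n_per_arm),
         arms = treatment_arms(), noise_cv = noise_cv,
         lod_quantile = lod_quantile, tissues = tissues,
         catalogs = catalogs, effects = effects,
         behavior_coupling = behavior_coupling,
         total_pmol = 5e5),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

with_structure_seed <- function(expr, offset = 0L) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(STRUCTURE_SEED + offset)
  expr
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  for (tt in cfg$tissues) {
    cat <- cfg$catalogs[[tt]]
    stopifnot(nrow(cat) >= 1, all(cat$share > 0),
              abs(sum(cat$share) - 1) < 1e-9,
              all(cat$db >= 0), all(cat$db < cat$carbons))
  }
  if (nrow(cfg$effects)) {
    stopifnot(all(cfg$effects$tissue %in% cfg$tissues),
              all(cfg$effects$arm %in% cfg$arms$label),
              all(is.finite(cfg$effects$log2fc)),
              all(lengths(cfg$effects$species) >= 1))
    for (i in seq_len(nrow(cfg$effects))) {
      tt <- cfg$effects$tissue[i]
      stopifnot(all(cfg$effects$species[[i]] %in% cfg$catalogs[[tt]]$species))
    }
  }
  cfg
}

#' The default study configuration
#'
#' [sim_config()] with every default: the six-arm design at n = 8/arm,
#' 696 plasma and 953 hippocampal species, dose-ordered unsaturated-LPE
#' effects, the broad plasma corticosterone upshift, and the
#' latency–LPE behavior coupling.
#'
#' @param seed Seed for the stochastic draw.
#' @return A `sim_config`.
#' @export
default_paper_config <- function(seed = 1L) {
  sim_config(seed = seed)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "| n/arm", x$n_per_arm,
      "| cv", x$noise_cv, "\n")
  for (tt in x$tissues) {
    cat(sprintf("  %s: %d species\n", tt, nrow(x$catalogs[[tt]])))
  }
  cat("  effects:", nrow(x$effects), "injected arm effects\n")
  invisible(x)
}

#' Generate a simulated study
#'
#' Draws pmol amounts per (species, animal, tissue) as
#' `baseline x arm multiplier x lognormal noise`, where the lognormal is
#' mean-one at coefficient of variation `noise_cv` (so arm means are
#' calibrated), records the tissue-wide LOD at the configured quantile,
#' and generates forced-swim-test behavior with latency coupled to each
#' animal's hippocampal unsaturated-LPE mol%. Fully deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with elements `quant` (named list of [quant_matrix()] per
#'   tissue, pmol, uncensored; LOD recorded for [apply_lod()]), `behavior`
#'   (tibble: `animal_id`, `arm`, `total_immobility_s`, `latency_s`),
#'   `ground_truth` (tibble: one row per injected species-arm effect,
#'   plus the behavior-coupling parameters as attributes), and `config`.
#' @export
simulate_study <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  arms <- config$arms$label
  n_arm <- config$n_per_arm
  animal_id <- sprintf("R%02d", seq_len(length(arms) * n_arm))
  animal_arm <- rep(arms, each = n_arm)
  sdlog <- sqrt(log(1 + config$noise_cv^2))

  quant <- list()
  for (tt in config$tissues) {
    cat <- config$catalogs[[tt]]
    baseline <- cat$share * config$total_pmol
    mult <- matrix(1, nrow = nrow(cat), ncol = length(arms),
                   dimnames = list(cat$species, arms))
    eff <- config$effects[config$effects$tissue == tt, ]
    for (i in seq_len(nrow(eff))) {
      sp <- eff$species[[i]]
      mult[sp, eff$arm[i]] <- mult[sp, eff$arm[i]] * 2^eff$log2fc[i]
    }
    mean_mat <- baseline * mult[, animal_arm, drop = FALSE]
    noise <- matrix(
      stats::rlnorm(length(mean_mat), meanlog = -sdlog^2 / 2, sdlog = sdlog),
      nrow = nrow(mean_mat)
    )
    amounts <- mean_mat * noise
    colnames(amounts) <- paste0(animal_id, "_", substr(tt, 1, 1))
    lod <- if (config$lod_quantile > 0) {
      as.numeric(stats::quantile(amounts, config$lod_quantile))
    } else 0
    samples <- tibble::tibble(
      sample_id = colnames(amounts),
      animal_id = animal_id,
      tissue = tt,
      arm = animal_arm
    )
    quant[[tt]] <- quant_matrix(amounts, samples, lod = lod)
  }

  behavior <- simulate_behavior(config, quant, animal_id, animal_arm)

  gt <- tidyr::unnest(config$effects, "species")
  gt <- gt[c("tissue", "species", "arm", "log2fc", "label")]
  attr(gt, "behavior_coupling") <- config$behavior_coupling
  list(quant = quant, behavior = behavior, ground_truth = gt,
       config = config)
}

simulate_behavior <- function(config, quant, animal_id, animal_arm) {
  bc <- config$behavior_coupling
  n <- length(animal_id)
  if ("hippocampus" %in% names(quant)) {
    hm <- to_molpct(quant$hippocampus)
    unsat_lpe <- hm$species$class_code == "LPE" &
      hm$species$total_double_bonds >= 1
    lpe_molpct <- unname(colSums(hm$amounts[unsat_lpe, , drop = FALSE]))
  } else {
    # no hippocampal tissue simulated: latency carries arm structure only
    lpe_molpct <- rep(0.2, n)
  }
  latency <- bc$intercept + bc$slope * lpe_molpct +
    bc$control_offset * (animal_arm == "CONTROL") +
    stats::rnorm(n, 0, bc$sd)
  latency <- pmin(pmax(latency, 0), 600)
  immob_mean <- c(CONTROL = 230, CORT = 256, CORT_ZE30 = 240,
                  CORT_ZE90 = 225, CORT_ZE180 = 155, CORT_ESC = 225)
  immobility <- immob_mean[animal_arm] + stats::rnorm(n, 0, 60)
  immobility <- pmin(pmax(immobility, 0), 600)
  tibble::tibble(
    animal_id = animal_id,
    arm = animal_arm,
    total_immobility_s = unname(immobility),
    latency_s = latency
  )
}

#' Write a simulated study to delimited text files
#'
#' Emits, per tissue, a quantification CSV (species in rows, one `lod`
#' column, one column per sample) plus a shared metadata CSV, behavior CSV
#' and ground-truth CSV — the same formats [read_quant_table()] and
#' [read_behavior_table()] consume.
#'
#' @param sim Output of [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named list of written paths.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  meta <- list()
  for (tt in names(sim$quant)) {
    m <- sim$quant[[tt]]
    tbl <- tibble::as_tibble(m$amounts, rownames = "species")
    tbl <- tibble::add_column(tbl, lod = m$lod, .after = "species")
    p <- file.path(dir, paste0("quant_", tt, ".csv"))
    readr::write_csv(tbl, p)
    paths[[paste0("quant_", tt)]] <- p
    meta[[tt]] <- m$samples
  }
  p <- file.path(dir, "metadata.csv")
  readr::write_csv(dplyr::bind_rows(meta), p)
  paths$metadata <- p
  p <- file.path(dir, "behavior.csv")
  readr::write_csv(sim$behavior, p)
  paths$behavior <- p
  p <- file.path(dir, "ground_truth.csv")
  readr::write_csv(sim$ground_truth, p)
  paths$ground_truth <- p
  invisible(paths)
}
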