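# independent brute-force oracle: plain loop over species
weighted_mean_loop <- function(w, x) {
  num <- 0
  den <- 0
  for (i in seq_along(w)) {
    num <- num + x[i] * w[i]
    den <- den + w[i]
  }
  num / den
}

test_that("weighted structural averages match hand values", {
  expect_equal(db_average(5, 6), 6)                    # single species
  expect_equal(db_average(c(50, 50), c(0, 2)), 1)      # symmetry
  expect_equal(db_average(c(25, 75), c(1, 3)), 2.5)
  expect_equal(chain_length_average(10, 34), 34)
  expect_equal(chain_length_average(c(50, 50), c(16, 18)), 17)
  expect_equal(chain_length_average(c(80, 20), c(34, 52)), 37.6)
})

test_that("empty or all-zero scopes are errors", {
  expect_error(db_average(numeric(0), numeric(0)), "empty")
  expect_error(db_average(c(0, 0), c(1, 2)), "all-zero")
  expect_error(db_average(c(-1, 2), c(1, 2)))
})

test_that("averages agree with the brute-force loop oracle", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(2:40, 1)
    w <- runif(n, 0, 10)
    x <- sample(0:60, n, replace = TRUE)
    expect_equal(db_average(w, x), weighted_mean_loop(w, x),
                 tolerance = 1e-12)
  }
})

test_that("structural summaries are scale invariant and db-monotone", {
  set.seed(13)
  x <- matrix(rlnorm(48), nrow = 8,
              dimnames = list(species_names_for(8), NULL))
  m <- toy_quant(x, arms = arm_levels())
  s1 <- structural_summary(m)
  # multiply one sample's pmol by a constant: nothing changes
  x2 <- x
  x2[, 3] <- x2[, 3] * 1000
  s2 <- structural_summary(toy_quant(x2, arms = arm_levels()))
  expect_equal(s2$db_av, s1$db_av, tolerance = 1e-12)
  expect_equal(s2$cl_av, s1$cl_av, tolerance = 1e-12)
  expect_equal(s2$unsat_molpct, s1$unsat_molpct, tolerance = 1e-12)
  # increasing one species' DB (weights fixed) never decreases db_av
  w <- x[, 1]
  db <- c(0, 1, 2, 3, 4, 5, 6, 7)
  for (i in seq_along(db)) {
    db2 <- db
    db2[i] <- db2[i] + 3
    expect_gte(db_average(w, db2), db_average(w, db))
  }
})

test_that("summary bounds hold: averages lie within species ranges", {
  sim <- simulate_study(sim_config(seed = 3, tissues = "plasma",
                                   n_species = list(plasma = 120)))
  m <- to_molpct(sim$quant$plasma)
  s <- structural_summary(m)
  expect_true(all(s$db_av >= min(m$species$total_double_bonds)))
  expect_true(all(s$db_av <= max(m$species$total_double_bonds)))
  expect_true(all(s$cl_av >= min(m$species$total_carbons)))
  expect_true(all(s$cl_av <= max(m$species$total_carbons)))
  expect_equal(s$sat_molpct + s$unsat_molpct, rep(100, nrow(s)),
               tolerance = 1e-9)
})

test_that("saturation partition splits the class total by DB = 0 vs >= 1", {
  x <- matrix(c(0.10, 0.12, 99.78), ncol = 1,
              dimnames = list(c("LPE 18:0", "LPE 18:1", "PC 34:1"), NULL))
  m <- toy_quant(x, arms = "CORT", unit = "molpct")
  p <- saturation_partition(m, "LPE")
  expect_equal(p$sat_molpct, 0.10)
  expect_equal(p$unsat_molpct, 0.12)
  # class with only saturated species
  x2 <- matrix(c(0.2, 0.3, 99.5), ncol = 1,
               dimnames = list(c("LPE 18:0", "LPE 20:0", "PC 34:1"), NULL))
  p2 <- saturation_partition(toy_quant(x2, arms = "CORT", unit = "molpct"),
                             "LPE")
  expect_equal(p2$sat_molpct, 0.5)
  expect_equal(p2$unsat_molpct, 0)
})

test_that("Holm-Sidak adjustment follows the step-down definition", {
  expect_equal(holm_sidak_adjust(c(0.01, 0.04)),
               c(1 - 0.99^2, 0.04), tolerance = 1e-12)
  expect_equal(holm_sidak_adjust(0.2), 0.2)  # m = 1: adjusted == raw
  set.seed(17)
  for (rep in 1:30) {
    p <- runif(sample(2:12, 1))
    adj <- holm_sidak_adjust(p)
    # step-definition oracle
    m <- length(p)
    ord <- order(p)
    expected <- numeric(m)
    running <- 0
    for (i in seq_len(m)) {
      running <- max(running, 1 - (1 - p[ord[i]])^(m - i + 1))
      expected[ord[i]] <- min(running, 1)
    }
    expect_equal(adj, expected, tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    expect_true(!is.unsorted(adj[ord]))
  }
})

test_that("one-way ANOVA with Holm-Sidak follow-up matches hand algebra", {
  # identical groups: F = 0, p = 1
  r0 <- anova_holm_sidak(c(1, 2, 3, 1, 2, 3), rep(c("CORT", "CONTROL"),
                                                  each = 3),
                         reference = "CORT")
  expect_equal(r0$anova$F, 0)
  expect_equal(r0$anova$p, 1)
  # hand mean-square oracle on random data
  set.seed(19)
  v <- rnorm(24)
  g <- rep(c("CONTROL", "CORT", "CORT_ZE90", "CORT_ZE180"), each = 6)
  r <- anova_holm_sidak(v, g, reference = "CORT")
  means <- tapply(v, g, mean)
  grand <- mean(v)
  ss_b <- sum(6 * (means - grand)^2)
  ss_w <- sum((v - means[g])^2)
  f_hand <- (ss_b / 3) / (ss_w / 20)
  expect_equal(r$anova$F, f_hand, tolerance = 1e-10)
  expect_equal(r$anova$p, pf(f_hand, 3, 20, lower.tail = FALSE),
               tolerance = 1e-10)
  # pairwise t vs reference with pooled within-group variance
  s2 <- ss_w / 20
  t_hand <- (means[["CONTROL"]] - means[["CORT"]]) / sqrt(s2 * (2 / 6))
  row <- r$comparisons[r$comparisons$arm == "CONTROL", ]
  expect_equal(row$t, t_hand, tolerance = 1e-10)
  expect_equal(row$p, 2 * pt(-abs(t_hand), 20), tolerance = 1e-10)
  expect_equal(r$comparisons$adj_p, holm_sidak_adjust(r$comparisons$p))
  expect_equal(row$sem, sd(v[g == "CONTROL"]) / sqrt(6), tolerance = 1e-12)
})
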