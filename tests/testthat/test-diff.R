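test_that("the per-contrast inclusion rule requires a detection in both arms", {
  expect_false(include_species(c(0, 0, 0, 0), c(0.1, 0.2, 0, 0)))
  expect_true(include_species(c(0, 0.3, 0, 0), c(0, 0, 0.1, 0)))
  expect_true(include_species(c(1, 2), c(3, 4)))
})

test_that("two-arm contrast reduces to the classical pooled t-test", {
  # worked example: a = CORT [2,3,4], b = CONTROL [1,2,3]
  x <- matrix(c(1, 2, 3, 2, 3, 4), nrow = 1,
              dimnames = list("PC 34:1", NULL))
  m <- toy_quant(x, arms = rep(c("CONTROL", "CORT"), each = 3),
                 unit = "molpct")
  r <- fit_contrasts(m, default_contrasts()[1, ])
  expect_equal(r$estimate, 1)
  expect_equal(r$t, 1 / sqrt(1 * (1 / 3 + 1 / 3)), tolerance = 1e-10)
  expect_equal(r$t, 1.2247, tolerance = 1e-4)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.288, tolerance = 1e-3)
  tt <- t.test(c(2, 3, 4), c(1, 2, 3), var.equal = TRUE)
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r$p, tt$p.value, tolerance = 1e-10)
  # random two-arm datasets
  set.seed(23)
  for (rep in 1:20) {
    x <- matrix(rlnorm(12), nrow = 1, dimnames = list("PC 34:1", NULL))
    m <- toy_quant(x, arms = rep(c("CONTROL", "CORT"), each = 6),
                   unit = "molpct")
    r <- fit_contrasts(m, default_contrasts()[1, ])
    tt <- t.test(x[1, 7:12], x[1, 1:6], var.equal = TRUE)
    expect_equal(r$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(r$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("pooled-variance contrasts agree with least-squares machinery", {
  skip_if_not_installed("emmeans")
  set.seed(29)
  x <- matrix(rlnorm(48, meanlog = 2), nrow = 1,
              dimnames = list("LPE 22:6", NULL))
  arms <- rep(arm_levels(), each = 8)
  m <- toy_quant(x, arms = arms, unit = "molpct")
  r <- fit_contrasts(m)
  fit <- stats::lm(y ~ arm, data = data.frame(y = x[1, ], arm = arms))
  em <- emmeans::emmeans(fit, "arm")
  ct <- as.data.frame(emmeans::contrast(
    em, method = list(c_vs_ctrl = c(-1, 1, 0, 0, 0, 0)), adjust = "none"))
  row <- r[r$contrast == "CORT_vs_CONTROL", ]
  expect_equal(row$estimate, ct$estimate, tolerance = 1e-10)
  expect_equal(row$t, ct$t.ratio, tolerance = 1e-10)
  expect_equal(row$p, ct$p.value, tolerance = 1e-10)
  expect_equal(row$df, ct$df)
})

test_that("log2 fold change handles equality, doubling and zero means", {
  x <- matrix(c(rep(2, 4), rep(2, 4),            # identical arms
                rep(1, 4), rep(2, 4),            # doubling
                rep(0, 4), rep(1, 4)),           # zero mean in arm b
              nrow = 3, byrow = TRUE,
              dimnames = list(c("PC 34:1", "PC 36:2", "PC 38:4"), NULL))
  m <- toy_quant(x, arms = rep(c("CONTROL", "CORT"), each = 4),
                 unit = "molpct")
  r <- fit_contrasts(m, default_contrasts()[1, ])
  expect_equal(r$estimate[1], 0)
  expect_equal(r$log2fc[1], 0)
  expect_equal(r$log2fc[2], 1)
  expect_false(r$included[3])                    # no detection in arm b
  expect_true(is.na(r$log2fc[3]))
  # zero mean with inclusion satisfied: flagged undefined, no pseudo-count
  x2 <- matrix(c(0, 0, 1, 0, 2, 2, 2, 2), nrow = 1,
               dimnames = list("PC 34:1", NULL))
  r2 <- fit_contrasts(toy_quant(x2, arms = rep(c("CONTROL", "CORT"),
                                               each = 4), unit = "molpct"),
                      default_contrasts()[1, ])
  expect_true(r2$included)
  expect_false(is.na(r2$log2fc))  # both means positive here
})

test_that("degenerate zero-variance contrasts are flagged", {
  x <- matrix(c(rep(1, 4), rep(1, 4)), nrow = 1,
              dimnames = list("PC 34:1", NULL))
  r <- fit_contrasts(toy_quant(x, arms = rep(c("CONTROL", "CORT"), each = 4),
                               unit = "molpct"),
                     default_contrasts()[1, ])
  expect_true(r$degenerate)
  expect_equal(r$p, 1)
  x2 <- matrix(c(rep(1, 4), rep(2, 4)), nrow = 1,
               dimnames = list("PC 34:1", NULL))
  r2 <- fit_contrasts(toy_quant(x2, arms = rep(c("CONTROL", "CORT"), each = 4),
                                unit = "molpct"),
                      default_contrasts()[1, ])
  expect_true(r2$degenerate)
  expect_equal(r2$p, 0)
})

test_that("BH adjustment matches the hand step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.07), 0.07)
  set.seed(31)
  for (rep in 1:30) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    m <- length(p)
    ord <- order(p)
    expected <- numeric(m)
    running <- Inf
    for (i in rev(seq_len(m))) {
      running <- min(running, p[ord[i]] * m / i)
      expected[ord[i]] <- min(running, 1)
    }
    expect_equal(q, expected, tolerance = 1e-12)
    # permutation invariance and monotonicity in p
    perm <- sample(m)
    expect_equal(bh_fdr(p[perm]), q[perm], tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
  }
})

test_that("FDR families are per contrast and per tissue", {
  set.seed(37)
  sim <- simulate_study(sim_config(seed = 5, tissues = "hippocampus",
                                   n_species = list(hippocampus = 60),
                                   effects = "none"))
  m <- to_molpct(apply_lod(sim$quant$hippocampus))
  r <- fit_contrasts(m)
  for (cn in unique(r$contrast)) {
    rc <- r[r$contrast == cn & r$included, ]
    expect_equal(rc$fdr, bh_fdr(rc$p), tolerance = 1e-12)
  }
})

test_that("volcano and QQ tables carry the documented transforms", {
  x <- matrix(rlnorm(40, 1, 0.2), nrow = 5,
              dimnames = list(species_names_for(5), NULL))
  m <- toy_quant(x, arms = rep(c("CONTROL", "CORT"), each = 4),
                 unit = "molpct")
  r <- fit_contrasts(m, default_contrasts()[1, ])
  v <- volcano_table(r)
  expect_equal(v$neglog10_p, -log10(r$p))
  expect_equal(v$significant, r$fdr < 0.05)
  expect_equal(-log10(0.05), 1.301, tolerance = 1e-3)
  q <- qq_table(r)
  expect_equal(q$expected_neglog10, -log10((1:5 - 0.5) / 5))
  expect_equal(q$observed_neglog10, sort(-log10(r$p), decreasing = TRUE))
})

test_that("null contrasts give near-uniform p (QQ close to the diagonal)", {
  sim <- simulate_study(sim_config(seed = 7, tissues = "hippocampus",
                                   n_species = list(hippocampus = 300),
                                   effects = "none", lod_quantile = 0))
  m <- to_molpct(sim$quant$hippocampus)
  r <- fit_contrasts(m, default_contrasts()[1, ])
  q <- qq_table(r)
  expect_lt(abs(mean(q$observed_neglog10 - q$expected_neglog10)), 0.15)
  expect_gt(ks.test(r$p, "punif")$p.value, 0.001)
})

test_that("injected log2fc = 1 effects are detected at high power", {
  cfg <- sim_config(seed = 9, tissues = "hippocampus",
                    n_species = list(hippocampus = 200), effects = "none")
  set.seed(9)
  target <- sample(cfg$catalogs$hippocampus$species, 30)
  cfg2 <- sim_config(seed = 9, tissues = "hippocampus",
                     n_species = list(hippocampus = 200),
                     effects = tibble::tibble(
                       tissue = "hippocampus", arm = "CORT_ZE180",
                       log2fc = 1, species = list(target), label = "spike"))
  sim <- simulate_study(cfg2)
  r <- fit_contrasts(to_molpct(apply_lod(sim$quant$hippocampus)))
  rc <- r[r$contrast == "ZE180+CORT_vs_CORT", ]
  hit <- rc$fdr[match(target, rc$species)] < 0.05
  expect_gte(mean(hit, na.rm = TRUE), 0.8)
})
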