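test_that("genotype-class rule uses the 15-sample boundary inclusively", {
  calls <- c(rep(0L, 100), rep(1L, 200), rep(2L, 100))
  expect_equal(genotype_class(calls)$class, "three_genotype")
  calls2 <- c(rep(1L, 250), rep(2L, 200))
  expect_equal(genotype_class(calls2)$class, "two_genotype")
  calls3 <- c(rep(0L, 14), rep(1L, 250), rep(2L, 200))
  expect_equal(genotype_class(calls3)$class, "two_genotype")   # 14 < 15
  calls4 <- c(rep(0L, 15), rep(1L, 250), rep(2L, 200))
  expect_equal(genotype_class(calls4)$class, "three_genotype") # exactly 15
  expect_error(genotype_class(rep(1L, 30)), "one genotype class")
})

test_that("d/a regression recovers noiseless class means exactly", {
  g <- rep(c(0L, 1L, 2L), each = 40)
  # class means (0, 1, 2): purely additive
  de <- da_effects(c(0, 1, 2)[g + 1], g)
  expect_equal(de$a, 1, tolerance = 1e-10)
  expect_equal(de$d, 0, tolerance = 1e-10)
  expect_equal(de$class, "additive")
  # class means (0, 1.5, 2): a = 1, d = 0.5 -> partial dominance
  de2 <- da_effects(c(0, 1.5, 2)[g + 1], g)
  expect_equal(de2$a, 1, tolerance = 1e-10)
  expect_equal(de2$d, 0.5, tolerance = 1e-10)
  expect_equal(de2$d_over_a, 0.5, tolerance = 1e-10)
  expect_equal(de2$class, "partial_dominance")
  # class means (0, 2, 1): a = 0.5, d = 1.5 -> overdominance
  de3 <- da_effects(c(0, 2, 1)[g + 1], g)
  expect_equal(de3$a, 0.5, tolerance = 1e-10)
  expect_equal(de3$d, 1.5, tolerance = 1e-10)
  expect_equal(de3$class, "overdominance")
})

test_that("stuber bins have exactly the printed boundaries", {
  grid <- c(0, 0.1, 0.19999, 0.2, 0.5, 0.8, 0.80001, 1.2, 1.20001, 3)
  expected <- c("additive", "additive", "additive", "partial_dominance",
                "partial_dominance", "partial_dominance", "dominance",
                "dominance", "overdominance", "overdominance")
  for (i in seq_along(grid)) {
    g <- rep(c(0L, 1L, 2L), each = 30)
    y <- c(0, 1 + grid[i], 2)[g + 1]  # a = 1, d = grid[i]
    expect_equal(da_effects(y, g)$class, expected[i], label = paste("d/a =", grid[i]))
    # negative ratios bin by magnitude
    yn <- c(0, 1 - grid[i], 2)[g + 1]
    expect_equal(da_effects(yn, g)$class, expected[i])
  }
})

test_that("d/a recovery is unbiased with noise and tightens as 1/sqrt(n)", {
  rmse <- vapply(c(200, 800), function(n) {
    err <- vapply(1:30, function(s) {
      withr::with_seed(s * 1000 + n, {
        g <- sample(0:2, n, replace = TRUE)
        y <- g + 0.5 * (g == 1) + rnorm(n, sd = 0.5)
        da_effects(y, g)$d_over_a - 0.5
      })
    }, numeric(1))
    expect_lt(abs(mean(err)), 0.05)
    sqrt(mean(err^2))
  }, numeric(1))
  expect_lt(rmse[2], rmse[1])
})

test_that("zero additive effect with a real dominance signal is overdominance", {
  g <- rep(c(0L, 1L, 2L), each = 50)
  y <- c(0, 1, 0)[g + 1] + withr::with_seed(3, rnorm(150, sd = 0.1))
  de <- da_effects(y, g)
  expect_true(is.na(de$d_over_a) || abs(de$d_over_a) > 1.2)
  expect_equal(de$class, "overdominance")
})

test_that("superiority classification respects the favorable direction", {
  g <- c(rep(1L, 30), rep(0L, 30))
  y <- c(rep(10, 30), rep(8, 30))
  expect_equal(superiority_class(y, g, "higher")$class, "hetero_superior")
  expect_equal(superiority_class(y, g, "lower")$class, "homo_superior")
  y2 <- c(rep(8, 30), rep(10, 30))
  expect_equal(superiority_class(y2, g, "higher")$class, "homo_superior")
  expect_warning(out <- superiority_class(rep(1, 60), g), "tie")
  expect_equal(out$class, "homo_superior")
})

test_that("variance explained matches lm and the AIC path drops collinear leads", {
  set.seed(12)
  n <- 400
  g1 <- rbinom(n, 2, 0.5)
  y <- 0.7 * g1
  expect_equal(variance_explained(y, g1), 1, tolerance = 1e-10)
  g0 <- rbinom(n, 2, 0.5)
  yn <- rnorm(n)
  expect_lt(variance_explained(yn, g0), 0.02)
  # two collinear leads: AIC keeps one, joint R2 unchanged
  y2 <- 0.5 * g1 + rnorm(n, sd = 0.5)
  G <- cbind(q1 = g1, q2 = g1, q3 = g0)
  out <- variance_explained(y2, G, multi = TRUE)
  expect_lte(length(out$kept), 2L)
  solo <- summary(lm(y2 ~ g1))$r.squared
  expect_equal(out$r_squared, solo, tolerance = 0.01)
})

test_that("superior-allele accounting traces parental origin", {
  cfg <- small_sim_config(seed = 51, qtl_specs = list(
    qtl_spec(1, 4e6, a = 0.2, d = 1, fixed_in = "maternal")
  ))
  p <- simulate_parents(cfg)
  acct <- superior_allele_accounting(p$qtl_markers, p$geno, p$groups, p$design,
                                     superior_allele = "a")
  expect_equal(acct$freq_maternal, 0)
  expect_gt(acct$freq_paternal, 0)
  expect_equal(acct$source, "male_only")
  expect_equal(acct$maternal_derived_frac, 0)  # all superior copies paternal
  # brute-force enumeration over the cross table
  hap <- p$geno$calls[, p$qtl_markers] / 2
  n_sup <- sum(hap[p$design$maternal]) + sum(hap[p$design$paternal])
  expect_equal(acct$n_superior_copies, as.integer(n_sup))
  expect_equal(acct$freq_f1, n_sup / (2 * nrow(p$design)))
  # the major allele, fixed in mothers, is female+male -> both
  acct2 <- superior_allele_accounting(p$qtl_markers, p$geno, p$groups, p$design,
                                      superior_allele = "A")
  expect_equal(acct2$source, "both")
  expect_equal(acct2$freq_maternal, 1)
})

test_that("superior-allele ratios are invariant to sample order", {
  cfg <- small_sim_config(seed = 52, qtl_specs = list(qtl_spec(1, 4e6, a = 1)))
  p <- simulate_parents(cfg)
  perm <- withr::with_seed(4, sample(nrow(p$geno$calls)))
  geno_perm <- geno_matrix(p$geno$calls[perm, ], p$geno$map)
  a <- superior_allele_accounting(p$qtl_markers, p$geno, p$groups, p$design, "a")
  b <- superior_allele_accounting(p$qtl_markers, geno_perm, p$groups, p$design, "a")
  expect_identical(a, b)
})

test_that("a maternal-fixed heterozygote-advantage QTL shows the expected signature", {
  # two-genotype, hetero-superior, superior copies all paternal-derived
  hits <- 0
  for (s in 1:15) {
    cfg <- sim_config(n_maternal = 8, n_paternal_families = 2, lines_per_family = 7,
                      n_chromosomes = 2, markers_per_chromosome = 100,
                      chrom_length = 8e6, h2_polygenic = 0, residual_sd = 0.5,
                      n_replicates = 2, seed = 600 + s,
                      qtl_specs = list(qtl_spec(1, 4e6, a = 0.3, d = 1,
                                                fixed_in = "maternal")))
    sm <- simulate_diallel(cfg)
    d <- derive_heterosis(sm$traits, sm$design, env = "E1")
    y <- setNames(d$f1$F1, d$f1$f1)
    prof <- qtl_profile(sm$qtl_markers, y, sm$f1_geno, sm$parents, sm$groups,
                        sm$design, direction = "higher")
    if (prof$class == "two_genotype" && prof$superiority == "hetero_superior" &&
        prof$contribution_source == "male_only" && prof$maternal_derived_frac < 0.5) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 14)
})
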