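# shared structured panel for engine tests
engine_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- engine_sim_config(seed = 40, qtl_specs = list(
        qtl_spec(2, 12e6, a = 1, d = 0, freq = 0.4)
      ))
      s <- simulate_diallel(cfg)
      K <- suppressWarnings(kinship(s$f1_geno))
      d <- derive_heterosis(s$traits, s$design, env = "E1")
      y <- setNames(d$f1$F1, d$f1$f1)[rownames(s$f1_geno$calls)]
      cache <<- list(sim = s, K = K, y = y)
    }
    cache
  }
})

test_that("permutation threshold is seed-deterministic and monotone in fdr", {
  pan <- engine_panel()
  y <- withr::with_seed(1, rnorm(length(pan$y)))
  a <- permutation_threshold(y, pan$sim$f1_geno, pan$K, n_perm = 60, fdr = 0.05, seed = 4)
  b <- permutation_threshold(y, pan$sim$f1_geno, pan$K, n_perm = 60, fdr = 0.05, seed = 4)
  expect_identical(a$threshold, b$threshold)
  strict <- permutation_threshold(y, pan$sim$f1_geno, pan$K, n_perm = 60, fdr = 0.01, seed = 4)
  expect_lte(strict$threshold, a$threshold)
  # ~fdr of the permutation minima fall below the threshold
  expect_lte(mean(a$min_p < a$threshold), 0.05)
  expect_gte(mean(a$min_p <= a$threshold), 0.03)
})

test_that("forward selection finds a strong QTL first and stops on null traits", {
  pan <- engine_panel()
  thr <- 1e-4
  hits <- forward_select(normalize_phenotype(pan$y), pan$sim$f1_geno, K = pan$K,
                         threshold = thr)
  expect_gt(nrow(hits), 0)
  truth <- pan$sim$truth$qtl
  lead <- pan$sim$f1_geno$map[match(hits$marker[1], pan$sim$f1_geno$map$marker), ]
  expect_equal(lead$chrom, truth$chrom)
  expect_lt(abs(lead$pos - truth$pos), 5e5)

  empty <- 0
  for (s in 1:20) {
    yn <- withr::with_seed(100 + s, rnorm(length(pan$y)))
    h <- forward_select(yn, pan$sim$f1_geno, K = pan$K, threshold = thr)
    if (nrow(h) == 0) empty <- empty + 1
  }
  expect_gte(empty, 19)
})

test_that("two unlinked QTLs are both selected within two steps", {
  cfg <- engine_sim_config(seed = 41, qtl_specs = list(
    qtl_spec(1, 12e6, a = 1.2, d = 0),
    qtl_spec(4, 12e6, a = 1.2, d = 0)
  ))
  s <- simulate_diallel(cfg)
  K <- suppressWarnings(kinship(s$f1_geno))
  d <- derive_heterosis(s$traits, s$design, env = "E1")
  y <- normalize_phenotype(setNames(d$f1$F1, d$f1$f1)[rownames(s$f1_geno$calls)])
  hits <- forward_select(y, s$f1_geno, K = K, threshold = 1e-3, max_steps = 3)
  expect_gte(nrow(hits), 2L)
  expect_setequal(hits$marker[1:2], s$truth$qtl$marker)
})

test_that("a deterministic single-SNP trait reaches RMIP 100 at that SNP", {
  pan <- engine_panel()
  g <- pan$sim$f1_geno$calls[, pan$sim$qtl_markers]
  y <- as.numeric(g) + 0.01 * withr::with_seed(7, rnorm(length(g)))
  names(y) <- rownames(pan$sim$f1_geno$calls)
  res <- resample_rmip(y, pan$sim$f1_geno, pan$K, models = "additive",
                       n_resamples = 25, n_perm = 60, seed = 2)
  expect_equal(res$rmip$rmip[res$rmip$marker == pan$sim$qtl_markers], 100)
})

test_that("RMIP is invariant to marker and sample order", {
  pan <- engine_panel()
  geno <- pan$sim$f1_geno
  y <- normalize_phenotype(pan$y)
  res <- resample_rmip(y, geno, pan$K, models = "additive",
                       n_resamples = 20, seed = 3, threshold = 1e-4)
  # marker order: geno_matrix re-sorts by position, so shuffle then rebuild
  shuf <- withr::with_seed(5, sample(ncol(geno$calls)))
  geno2 <- geno_matrix(geno$calls[, shuf], geno$map[shuf, ])
  res2 <- resample_rmip(y, geno2, pan$K, models = "additive",
                        n_resamples = 20, seed = 3, threshold = 1e-4)
  r1 <- setNames(res$rmip$rmip, res$rmip$marker)
  r2 <- setNames(res2$rmip$rmip, res2$rmip$marker)
  expect_equal(r1[sort(names(r1))], r2[sort(names(r2))])
})

test_that("with one full-sample resample the engine matches plain forward selection", {
  set.seed(44)
  n <- 200
  G <- matrix(rbinom(n * 300, 2, 0.4), n, 300)
  rownames(G) <- paste0("s", 1:n)
  geno <- toy_geno(G)
  y <- G[, 57] * 0.8 + rnorm(n)
  names(y) <- rownames(G)
  res <- resample_rmip(y, geno, diag(n), models = "additive", n_resamples = 1,
                       subsample_frac = 1, seed = 1, threshold = 1e-5,
                       rmip_threshold = 5)
  included <- res$rmip$marker[res$rmip$rmip == 100]
  # independent plain forward selection with lm()
  sel <- c(); Xc <- matrix(1, n, 1)
  repeat {
    ps <- vapply(seq_len(ncol(G)), function(j) {
      if (j %in% sel) return(1)
      cf <- summary(lm(y ~ Xc - 1 + G[, j]))$coefficients
      if (rownames(cf)[nrow(cf)] != "G[, j]") return(1)
      cf[nrow(cf), "Pr(>|t|)"]
    }, numeric(1))
    j <- which.min(ps)
    if (ps[j] >= 1e-5) break
    sel <- c(sel, j); Xc <- cbind(Xc, G[, j])
  }
  expect_setequal(included, paste0("m", sel))
})

test_that("an overdominant QTL is found by the overdominance coding, not additive", {
  wins <- 0
  for (s in 1:5) {
    cfg <- engine_sim_config(seed = 500 + s, qtl_specs = list(
      qtl_spec(3, 10e6, a = 0, d = 1.2, freq = 0.5)
    ))
    sm <- simulate_diallel(cfg)
    K <- suppressWarnings(kinship(sm$f1_geno))
    d <- derive_heterosis(sm$traits, sm$design, env = "E1")
    y <- normalize_phenotype(setNames(d$f1$F1, d$f1$f1)[rownames(sm$f1_geno$calls)])
    res <- resample_rmip(y, sm$f1_geno, K, models = c("additive", "overdominance"),
                         n_resamples = 25, n_perm = 60, seed = s)
    if (max(res$rmip$overdominance) >= max(res$rmip$additive)) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("covariate rerun absorbs signals mediated by the F1 phenotype", {
  pan <- engine_panel()
  y_f1 <- normalize_phenotype(pan$y)
  res_f1 <- resample_rmip(y_f1, pan$sim$f1_geno, pan$K, models = "additive",
                          n_resamples = 25, n_perm = 60, seed = 6)
  expect_gt(nrow(res_f1$selected), 0)
  # derived phenotype = F1 minus a constant: the covariate absorbs everything
  y_derived <- pan$y - 3
  rerun <- covariate_rerun(y_derived, pan$sim$f1_geno, pan$K, covariate = pan$y,
                           previous = res_f1, models = "additive",
                           n_resamples = 25, n_perm = 60, seed = 6)
  expect_equal(nrow(rerun$result$selected), 0L)
  expect_setequal(rerun$disappeared, res_f1$selected$marker)
  # determinism of the disappearance set
  rerun2 <- covariate_rerun(y_derived, pan$sim$f1_geno, pan$K, covariate = pan$y,
                            previous = res_f1, models = "additive",
                            n_resamples = 25, n_perm = 60, seed = 6)
  expect_identical(rerun$disappeared, rerun2$disappeared)
})
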