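test_that("marker filters apply sequentially with inclusive thresholds", {
  # 20 markers x 10 samples: 4 high-missing; among survivors, 3 high-het
  set.seed(1)
  calls <- matrix(0L, 10, 20)
  calls[, 1:4] <- NA_integer_                  # missing rate 1 > 0.2
  calls[1:3, 5:7] <- 1L                        # het rate 0.3 > 0.15
  calls[1, 8] <- 1L                            # het rate 0.1 <= 0.15, kept
  calls[1:2, 9] <- NA_integer_                 # missing 0.2 boundary, kept
  rownames(calls) <- paste0("s", 1:10)
  g <- toy_geno(calls)
  f <- filter_markers(g, max_missing = 0.2, max_het = 0.15)
  expect_equal(ncol(f$calls), 13L)
  expect_equal(attr(f, "filter_counts"),
               c(removed_missing = 4L, removed_het = 3L))
  # idempotent
  f2 <- filter_markers(f, 0.2, 0.15)
  expect_identical(f2$calls, f$calls)
})

test_that("het rate exactly at the threshold is retained", {
  calls <- matrix(0L, 20, 2, dimnames = list(paste0("s", 1:20), NULL))
  calls[1:3, 1] <- 1L   # exactly 0.15
  calls[1:4, 2] <- 1L   # 0.20 > 0.15
  f <- filter_markers(toy_geno(calls), max_missing = 0.2, max_het = 0.15)
  expect_equal(f$map$marker, "m1")
})

test_that("MAF and polymorphism filters match brute-force allele counts", {
  set.seed(2)
  calls <- matrix(sample(c(0L, 1L, 2L), 120, replace = TRUE, prob = c(0.7, 0.1, 0.2)),
                  10, 12, dimnames = list(paste0("s", 1:10), NULL))
  calls[, 1] <- 0L  # monomorphic
  g <- toy_geno(calls)
  p <- polymorphic_filter(g)
  expect_false("m1" %in% p$map$marker)
  f <- maf(g)
  brute <- apply(calls, 2, function(col) {
    fr <- sum(col) / (2 * length(col)); min(fr, 1 - fr)
  })
  expect_equal(unname(f), unname(brute))
  kept <- maf_filter(g, 0.05)
  expect_setequal(kept$map$marker, g$map$marker[brute >= 0.05])
})

test_that("MAF exactly 0.05 is retained", {
  # 10 samples: one het = allele freq 1/20 = 0.05
  calls <- matrix(0L, 10, 2, dimnames = list(paste0("s", 1:10), NULL))
  calls[1, 1] <- 1L
  calls[1, 2] <- 2L  # freq 0.1
  g <- maf_filter(toy_geno(calls), 0.05)
  expect_setequal(g$map$marker, c("m1", "m2"))
})

test_that("knn imputation takes the neighbour mode and never edits observed calls", {
  calls <- rbind(
    s1 = c(0L, NA, 2L, 0L),
    s2 = c(0L, 0L, 2L, 0L),   # identical to s1 elsewhere
    s3 = c(0L, 0L, 2L, 2L),
    s4 = c(2L, 2L, 0L, 2L)
  )
  g <- toy_geno(calls)
  imp <- knn_impute(g, k = 1)
  expect_equal(imp$calls["s1", "m2"], 0L)
  expect_identical(imp$calls[!is.na(calls)], calls[!is.na(calls)])
  # k = 3 majority over {0, 0, 2} -> 0
  imp3 <- knn_impute(g, k = 3)
  expect_equal(imp3$calls["s1", "m2"], 0L)
  expect_error(knn_impute(toy_geno(rbind(s1 = c(NA_integer_, NA_integer_),
                                         s2 = c(0L, 1L)))),
               "no observed genotype")
})

test_that("masking a complete matrix recovers calls above the majority baseline", {
  p <- simulate_parents(small_sim_config(seed = 21))
  truth <- p$geno
  set.seed(33)
  mask <- matrix(runif(length(truth$calls)) < 0.05, nrow(truth$calls))
  masked <- truth$calls
  masked[mask] <- NA_integer_
  g <- geno_matrix(masked, truth$map)
  imp <- knn_impute(g, k = 5)
  acc <- mean(imp$calls[mask] == truth$calls[mask], na.rm = TRUE)
  # majority-class baseline: always impute the per-marker modal call
  modal <- apply(truth$calls, 2, function(col) as.integer(names(which.max(table(col)))))
  base <- mean(matrix(modal, nrow(truth$calls), ncol(truth$calls), byrow = TRUE)[mask] ==
                 truth$calls[mask])
  expect_gt(acc, base)
  expect_gt(acc, 0.8)
})

test_that("combine_f1 implements the inbred-parent union rules", {
  parents <- toy_geno(rbind(mom = c(0L, 0L, 2L, 1L, 0L),
                            dad = c(2L, 0L, 2L, 0L, NA)))
  design <- cross_design("kid", "mom", "dad")
  f1 <- combine_f1(parents, design)
  expect_equal(unname(f1$calls["kid", ]), c(1L, 0L, 2L, NA, NA))
  bad <- cross_design("kid2", "mom", "nodad")
  expect_error(combine_f1(parents, bad), "kid2")
})

test_that("F1 heterozygosity equals the parental mismatch fraction exactly", {
  p <- simulate_parents(small_sim_config(seed = 22))
  f1 <- combine_f1(p$geno, p$design)
  het <- heterozygosity(f1)
  mismatch <- vapply(seq_len(nrow(p$design)), function(i) {
    mean(p$geno$calls[p$design$maternal[i], ] != p$geno$calls[p$design$paternal[i], ])
  }, numeric(1))
  expect_equal(unname(het[p$design$f1]), mismatch, tolerance = 1e-12)
})

test_that("heterozygosity handles all-het, all-hom and windows", {
  calls <- rbind(allhet = rep(1L, 6), allhom = rep(0L, 6))
  g <- toy_geno(calls, pos = c(1e3, 2e3, 3e3, 1.2e5, 1.3e5, 2.5e5))
  h <- heterozygosity(g)
  expect_equal(unname(h), c(1, 0))
  hw <- heterozygosity(g, window = 1e5)
  expect_equal(nrow(hw$per_window), 3L)
  expect_equal(hw$per_window$het, c(0.5, 0.5, 0.5))
  expect_equal(hw$per_window$start, c(1, 100001, 200001))
})

test_that("duplicate samples have maximal kinship and identical PCA scores", {
  p <- simulate_parents(small_sim_config(seed = 23))
  calls <- p$geno$calls
  calls <- rbind(calls, dup = calls[1, ])
  g <- geno_matrix(calls, p$geno$map)
  K <- suppressWarnings(kinship(g))
  i <- 1; dup <- nrow(calls)
  expect_equal(K[i, dup], K[i, i], tolerance = 1e-5)
  expect_gte(min(diag(K)) + 1e-8, mean(K[upper.tri(K)]))
  sc <- suppressWarnings(geno_pca(g, 4))
  expect_equal(sc[i, ], sc[dup, ], tolerance = 1e-5)
})

test_that("PC1-2 of the F1 panel recover paternal family labels", {
  skip_if_not_installed("mclust")
  cfg <- engine_sim_config(seed = 24)
  p <- simulate_parents(cfg)
  f1 <- combine_f1(p$geno, p$design)
  sc <- suppressWarnings(geno_pca(f1, 2))
  fam <- p$families[p$design$paternal[match(rownames(f1$calls), p$design$f1)]]
  km <- withr::with_seed(1, stats::kmeans(sc, centers = 3, nstart = 25))
  expect_gt(mclust::adjustedRandIndex(km$cluster, fam), 0.9)
})

test_that("PCA scores reconstruct the GRM increasingly well with k", {
  p <- simulate_parents(small_sim_config(seed = 25))
  f1 <- combine_f1(p$geno, p$design)
  K <- suppressWarnings(kinship(f1))
  res <- vapply(c(2, 5, 10), function(k) {
    sc <- suppressWarnings(geno_pca(f1, k))
    norm(K - tcrossprod(sc), "F")
  }, numeric(1))
  expect_true(all(diff(res) < 1e-8))
})

test_that("maf_by_group profiles equal direct per-group counting", {
  cfg <- small_sim_config(seed = 26, qtl_specs = list(
    qtl_spec(1, 4e6, a = 1, d = 0, fixed_in = "maternal")
  ))
  p <- simulate_parents(cfg)
  prof <- maf_by_group(p$geno, p$groups, around = p$qtl_markers, flank = 2e6)
  focal_mat <- prof[prof$group == "maternal" & prof$offset == 0, ]
  expect_equal(focal_mat$maf, 0)
  # direct recount for one random marker/group
  row <- prof[prof$group == "paternal", ][5, ]
  ids <- names(p$groups)[p$groups == "paternal"]
  fr <- sum(p$geno$calls[ids, row$marker]) / (2 * length(ids))
  expect_equal(row$maf, min(fr, 1 - fr))
})
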