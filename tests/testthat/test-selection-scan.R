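mk_hap_geno <- function(hap, pos = NULL) {
  # haplotypes (0/1) as inbred lines: dosage = 2 * allele
  calls <- 2L * hap
  rownames(calls) <- paste0("p", seq_len(nrow(hap)))
  toy_geno(calls, pos = pos %||% seq_len(ncol(hap)) * 1000L)
}

test_that("windowed D equals the site-by-site closed-form oracle to 1e-10", {
  for (s in 1:5) {
    hap <- withr::with_seed(s, matrix(rbinom(6 * 15, 1, runif(15, 0.1, 0.9)),
                                      6, 15, byrow = TRUE))
    g <- mk_hap_geno(hap)
    scan <- tajimas_d_scan(g, window = 2e4, step = 2e4, group = "x")
    expect_equal(scan$tajimas_d[1], oracle_tajima_d(hap), tolerance = 1e-10)
  }
  # larger panel
  hap <- withr::with_seed(99, matrix(rbinom(10 * 50, 1, 0.4), 10, 50))
  g <- mk_hap_geno(hap)
  scan <- tajimas_d_scan(g, window = 1e5, step = 1e5, group = "x")
  expect_equal(scan$tajimas_d[1], oracle_tajima_d(hap), tolerance = 1e-10)
})

test_that("D is undefined below 3 segregating sites and for tiny groups", {
  hap <- matrix(0L, 6, 10); hap[1, 1] <- 1L; hap[2, 5] <- 1L  # S = 2
  g <- mk_hap_geno(hap)
  scan <- tajimas_d_scan(g, window = 2e4, step = 2e4)
  expect_true(is.na(scan$tajimas_d[1]))
  expect_equal(scan$S[1], 2L)
  small <- mk_hap_geno(matrix(rbinom(30, 1, 0.5), 3, 10))
  expect_error(tajimas_d_scan(small), "at least 4 haplotypes")
})

test_that("D is invariant to haplotype order and allele-label swaps", {
  hap <- withr::with_seed(7, matrix(rbinom(8 * 30, 1, 0.3), 8, 30))
  g <- mk_hap_geno(hap)
  d0 <- tajimas_d_scan(g, window = 1e5, step = 1e5)$tajimas_d[1]
  perm <- mk_hap_geno(hap[sample(8), ])
  expect_equal(tajimas_d_scan(perm, window = 1e5, step = 1e5)$tajimas_d[1], d0)
  flip <- hap; flip[, c(3, 7, 20)] <- 1L - flip[, c(3, 7, 20)]
  expect_equal(tajimas_d_scan(mk_hap_geno(flip), window = 1e5, step = 1e5)$tajimas_d[1],
               d0, tolerance = 1e-12)
})

test_that("residual heterozygous parental calls are excluded with a warning", {
  hap <- withr::with_seed(8, matrix(rbinom(6 * 20, 1, 0.5), 6, 20))
  g <- mk_hap_geno(hap)
  g$calls[1, 2] <- 1L
  expect_warning(scan <- tajimas_d_scan(g, window = 1e5, step = 1e5), "heterozygous")
  expect_false(is.na(scan$tajimas_d[1]))
})

test_that("window tiling covers interior positions size/step times", {
  hap <- withr::with_seed(9, matrix(rbinom(8 * 200, 1, 0.5), 8, 200))
  g <- mk_hap_geno(hap, pos = sort(sample.int(1e6, 200)))
  scan <- tajimas_d_scan(g, window = 1e5, step = 2e4)
  interior <- 5e5
  covering <- sum(scan$start <= interior & scan$end > interior)
  expect_equal(covering, 5L)  # 100 kb / 20 kb
})

test_that("low_d_regions matches hand enumeration and merges adjacency", {
  scan <- data.frame(
    chrom = "1", start = seq(1, by = 2e4, length.out = 20),
    end = seq(1, by = 2e4, length.out = 20) + 2e4,
    n_sites = 10, S = 10, pi = 1,
    tajimas_d = c(2, 1, 0.5, 1, -3, -3, 1, 1, 1, 1,
                  1, 1, -2.9, 1, 1, 1, 1, 1, 1, NA),
    group = "maternal", terminal = FALSE
  )
  regions <- low_d_regions(scan, percentile = 15)
  # cutoff = 15th percentile of the 19 defined values (~-0.87): the two
  # contiguous lowest windows merge, the third lowest forms its own region
  expect_equal(nrow(regions), 2L)
  expect_equal(regions$start[1], scan$start[5])
  expect_equal(regions$end[1], scan$end[6])
  expect_equal(regions$start[2], scan$start[13])
  all_r <- low_d_regions(scan, percentile = 100)
  expect_equal(nrow(all_r), 1L)  # everything defined merges into one run
  min_r <- low_d_regions(scan, percentile = 0)
  expect_equal(min_r$min_d, min(scan$tajimas_d, na.rm = TRUE))
})

test_that("QTL overlap uses half-open intervals", {
  regions <- data.frame(chrom = "1", start = 100, end = 200,
                        group = "maternal", min_d = -2)
  qtls <- data.frame(chrom = c("1", "1", "1", "2"),
                     start = c(150, 50, 200, 150), end = c(160, 100, 250, 160))
  out <- qtl_overlap(qtls, regions)
  expect_equal(out$overlap_maternal, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(attr(out, "counts")[["maternal"]], 1L)
})

test_that("random toy intervals match brute-force pairwise intersection", {
  set.seed(13)
  regions <- data.frame(chrom = sample(c("1", "2"), 15, TRUE),
                        start = sample.int(1e4, 15) * 10)
  regions$end <- regions$start + sample.int(500, 15) * 10
  regions$group <- "paternal"; regions$min_d <- -1
  qtls <- data.frame(chrom = sample(c("1", "2"), 25, TRUE),
                     start = sample.int(1e4, 25) * 10)
  qtls$end <- qtls$start + sample.int(300, 25) * 10
  out <- qtl_overlap(qtls, regions)
  brute <- vapply(seq_len(nrow(qtls)), function(i) {
    any(vapply(seq_len(nrow(regions)), function(r) {
      regions$chrom[r] == qtls$chrom[i] &&
        qtls$start[i] < regions$end[r] && regions$start[r] < qtls$end[i]
    }, logical(1)))
  }, logical(1))
  expect_equal(out$overlap_paternal, brute)
})

test_that("a near-fixed maternal sweep depresses maternal D at the locus", {
  lower <- 0
  for (s in 1:12) {
    cfg <- sim_config(n_maternal = 10, n_paternal_families = 2, lines_per_family = 6,
                      n_chromosomes = 1, markers_per_chromosome = 150,
                      chrom_length = 3e6, h2_polygenic = 0, residual_sd = 0.5,
                      seed = 700 + s,
                      qtl_specs = list(qtl_spec(1, 1.5e6, a = 1, fixed_in = "maternal")))
    p <- simulate_parents(cfg)
    mat <- geno_subset(p$geno, samples = names(p$groups)[p$groups == "maternal"])
    pat <- geno_subset(p$geno, samples = names(p$groups)[p$groups == "paternal"])
    sc_m <- tajimas_d_scan(mat, window = 4e5, step = 1e5, group = "maternal")
    sc_p <- tajimas_d_scan(pat, window = 4e5, step = 1e5, group = "paternal")
    at <- function(sc) mean(sc$tajimas_d[sc$start <= 1.5e6 & sc$end > 1.5e6], na.rm = TRUE)
    if (is.finite(at(sc_m)) && is.finite(at(sc_p)) && at(sc_m) < at(sc_p)) lower <- lower + 1
  }
  expect_gte(lower, 9)
})
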