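# Shared fixtures: all simulated in code, sized for fast unit tests.

small_sim_config <- function(seed = 1L, qtl_specs = list(), ...) {
  sim_config(
    n_maternal = 6L, n_paternal_families = 2L, lines_per_family = 5L,
    n_chromosomes = 2L, markers_per_chromosome = 120L, chrom_length = 8e6,
    qtl_specs = qtl_specs, h2_polygenic = 0, residual_sd = 0.5,
    n_replicates = 2L, seed = seed, ...
  )
}

# ~300 F1s x 2000 markers: the scaled engine configuration
engine_sim_config <- function(seed = 1L, qtl_specs = list(), ...) {
  sim_config(
    n_maternal = 10L, n_paternal_families = 3L, lines_per_family = 10L,
    n_chromosomes = 5L, markers_per_chromosome = 400L, chrom_length = 25e6,
    qtl_specs = qtl_specs, h2_polygenic = 0.2, residual_sd = 1,
    n_replicates = 3L, seed = seed, ...
  )
}

# hand-buildable genotype matrix from a calls matrix
toy_geno <- function(calls, chrom = NULL, pos = NULL) {
  m <- ncol(calls)
  if (is.null(rownames(calls))) rownames(calls) <- paste0("s", seq_len(nrow(calls)))
  geno_matrix(calls, data.frame(
    marker = paste0("m", seq_len(m)),
    chrom = chrom %||% rep("1", m),
    pos = pos %||% (seq_len(m) * 1000L)
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# independent closed-form Tajima's D (site-by-site brute force; complete data)
oracle_tajima_d <- function(hap) {
  n <- nrow(hap)
  k <- colSums(hap)
  seg <- k > 0 & k < n
  S <- sum(seg)
  if (S < 3) return(NA_real_)
  # pi by explicit pairwise comparison
  pi <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) pi <- pi + sum(hap[i, seg] != hap[j, seg])
  }
  pi <- pi / choose(n, 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# independent OLS score test (via lm residualization and correlation)
oracle_ols_score_p <- function(y, g, X = NULL) {
  if (is.null(X)) X <- matrix(1, length(y), 1)
  ry <- stats::resid(stats::lm(y ~ X - 1))
  rg <- stats::resid(stats::lm(g ~ X - 1))
  if (stats::sd(rg) == 0) return(1)
  stat <- length(y) * stats::cor(ry, rg)^2
  stats::pchisq(stat, 1, lower.tail = FALSE)
}
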