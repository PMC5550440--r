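#' Permutation-based genome-wide significance threshold
#'
#' Permutes the phenotype against the genotypes (kinship is left in place, so
#' the permutation breaks all structure), runs a genome-wide score scan per
#' permutation, and collects the genome-wide minimum p-value. The threshold
#' is the largest permutation minimum whose empirical genome-wide p-value
#' (rank / n_perm) stays below `fdr`; under a pure-noise trait, ~`fdr` of the
#' permutation minima then fall below the threshold.
#'
#' @param y phenotype vector.
#' @param geno `geno_matrix` (complete calls).
#' @param K kinship matrix over the same samples.
#' @param model inheritance coding (see [recode_model()]).
#' @param n_perm number of permutations (>= 50 recommended; paper-scale 300).
#' @param fdr target false discovery rate (default 0.05).
#' @param X optional covariates kept fixed (unpermuted).
#' @param seed integer seed for the permutation draws.
#' @return list with `threshold` and `min_p` (per-permutation minima).
#' @export
permutation_threshold <- function(y, geno, K, model = "additive", n_perm = 100L,
                                  fdr = 0.05, X = NULL, seed = 1L) {
  if (n_perm < 50L) warnf("n_perm < 50 gives an unstable threshold")
  G <- recode_model(geno$calls, model)
  fit0 <- polygenic_fit(y, K = K, X = X)
  eig <- list(vectors = fit0$U, values = fit0$lambda)
  Gt <- crossprod(fit0$U, G)
  Gt2 <- Gt * Gt
  min_p <- numeric(n_perm)
  with_seed(child_seed(seed, 97L), {
    for (b in seq_len(n_perm)) {
      yp <- y[sample.int(length(y))]
      fitp <- polygenic_fit(yp, eig = eig, X = X)
      sc <- score_scan(fitp, Gt, Gt2)
      min_p[b] <- min(sc$p)
    }
  })
  s <- sort(min_p)
  ok <- which(seq_len(n_perm) / n_perm < fdr)
  threshold <- if (length(ok) > 0) s[max(ok)] else fdr / ncol(G)
  list(threshold = threshold, min_p = min_p)
}

#' Forward-selection mixed-model association scan
#'
#' Iterates a genome-wide kinship-corrected score scan; while the best
#' p-value beats `threshold`, the winning marker (in its recoded form) is
#' added as a fixed covariate and the scan repeats. Covariates collinear with
#' the existing set are dropped with a warning.
#'
#' @param y phenotype vector.
#' @param geno `geno_matrix`.
#' @param K kinship matrix (or `eig`, a precomputed eigendecomposition).
#' @param model inheritance coding.
#' @param threshold genome-wide p-value threshold from
#'   [permutation_threshold()].
#' @param max_steps cap on selected markers (default 20).
#' @param X optional fixed covariates.
#' @param eig optional precomputed `eigen(K)`.
#' @param Gt optional precomputed rotated coded marker matrix `U'G`.
#' @return data.frame (marker, model, step, p, stat), zero rows if nothing
#'   passes.
#' @export
forward_select <- function(y, geno, K = NULL, model = "additive", threshold,
                           max_steps = 20L, X = NULL, eig = NULL, Gt = NULL) {
  fit <- polygenic_fit(y, K = K, X = X, eig = eig)
  eig <- list(vectors = fit$U, values = fit$lambda)
  if (is.null(Gt)) Gt <- crossprod(fit$U, recode_model(geno$calls, model))
  Gt2 <- Gt * Gt
  sel <- integer(0)
  X_cov <- if (is.null(X)) NULL else as.matrix(X)
  out <- list()
  for (step in seq_len(max_steps)) {
    sc <- score_scan(fit, Gt, Gt2)
    if (length(sel) > 0) sc$p[sel] <- 1  # never reselect
    j <- which.min(sc$p)
    if (sc$p[j] >= threshold) break
    g_raw <- recode_model(geno$calls[, j], model)
    if (qr(cbind(1, X_cov, g_raw))$rank < 2L + NCOL(X_cov) * !is.null(X_cov)) {
      warnf("marker %s collinear with selected covariates; dropped", geno$map$marker[j])
      sc$p[j] <- 1
      sel <- c(sel, j)
      next
    }
    X_cov <- cbind(X_cov, g_raw)
    sel <- c(sel, j)
    out[[length(out) + 1L]] <- data.frame(
      marker = geno$map$marker[j], model = model, step = step,
      p = sc$p[j], stat = sc$stat[j], stringsAsFactors = FALSE
    )
    # each round is a fresh mixed-model GWAS with the selected markers as
    # fixed covariates: variance components are re-estimated so the polygenic
    # term no longer absorbs the effect just transferred to the fixed part
    fit <- polygenic_fit(y, eig = eig, X = X_cov)
  }
  if (length(out) == 0) {
    return(data.frame(marker = character(0), model = character(0),
                      step = integer(0), p = numeric(0), stat = numeric(0)))
  }
  do.call(rbind, out)
}

#' Forward-selection resampling GWAS with RMIP aggregation
#'
#' The engine: draw `n_resamples` subsamples of `subsample_frac` of the F1s
#' without replacement; on each subsample and under each inheritance coding,
#' re-estimate the polygenic variance components (kinship is computed once on
#' all samples and subset) and run [forward_select()] at a per-trait
#' permutation threshold. The resample model inclusion probability of a
#' marker under a model is `RMIP = 100 * inclusion count / n_resamples`; the
#' per-marker RMIP used for reporting is the maximum over models. Markers at
#' `RMIP >= rmip_threshold` (default 5) are reported as significant.
#'
#' The threshold is calibrated on the permutation null of the reporting
#' statistic itself: for each of `n_perm` permuted traits the engine finds
#' the smallest p-value threshold at which any marker (under any model) would
#' reach the reporting RMIP across the actual subsample draws — i.e. the
#' `count_min`-th smallest subsample p-value of that marker, minimized over
#' markers, where `count_min = ceiling(rmip_threshold/100 * n_resamples)`.
#' The selection threshold is then the largest such permutation value whose
#' empirical rank stays below `fdr`, so a null trait produces a reported
#' marker in about `fdr` of runs. A single-scan threshold (a marker's chance
#' of winning one genome-wide scan) does not control this quantity: markers
#' marginally above it cross in a few of the strongly correlated 80%
#' subsamples far more often than `fdr`. Per permutation, the minimizing
#' marker is searched among its top 10 full-data markers. With one resample
#' at `subsample_frac = 1` the statistic reduces to the per-permutation
#' genome-wide minimum p, i.e. the classic single-scan threshold.
#'
#' Each resample draws its subsample from a counter-based child seed of
#' `seed`, so any single resample is reproducible in isolation.
#'
#' @inheritParams permutation_threshold
#' @param models character vector of inheritance codings.
#' @param n_resamples number of resamples (paper-scale 300; scaled runs use
#'   50).
#' @param subsample_frac fraction of samples per resample (default 0.8).
#' @param rmip_threshold reporting threshold on the 0-100 RMIP scale.
#' @param max_steps forward-selection cap per scan.
#' @param threshold optionally, a precomputed p-value threshold (skips the
#'   permutation calibration; e.g. the single-scan
#'   [permutation_threshold()]).
#' @return object of class `rmip_result`: `rmip` (data.frame marker, chrom,
#'   pos, one column per model, rmip = max over models), `selected`
#'   (significant markers with best single-scan p and model), `threshold`,
#'   and the run settings.
#' @export
resample_rmip <- function(y, geno, K, models = c("additive", "dominance",
                                                 "recessive", "overdominance"),
                          n_resamples = 300L, subsample_frac = 0.8,
                          n_perm = 300L, fdr = 0.05, rmip_threshold = 5,
                          X = NULL, max_steps = 20L, seed = 1L,
                          threshold = NULL) {
  if (length(models) == 0) stopf("at least one inheritance model is required")
  if (!(subsample_frac > 0 && subsample_frac <= 1)) stopf("subsample_frac must be in (0, 1]")
  if (n_resamples < 20L && n_resamples > 1L) warnf("fewer than 20 resamples gives unstable RMIP values")
  n <- length(y)
  M <- ncol(geno$calls)
  recoded <- lapply(models, function(m) recode_model(geno$calls, m))
  names(recoded) <- models
  n_sub <- max(2L, floor(subsample_frac * n))
  idx_list <- lapply(seq_len(n_resamples), function(r)
    with_seed(child_seed(seed, r), sort(sample.int(n, n_sub))))
  eig_list <- lapply(idx_list, function(idx) {
    e <- eigen(K[idx, idx], symmetric = TRUE)
    e$values <- pmax(e$values, 1e-6)
    e
  })
  if (is.null(threshold)) {
    threshold <- calibrate_rmip_threshold(
      y, recoded, K, idx_list, eig_list, X = X, n_perm = n_perm, fdr = fdr,
      count_min = max(1L, ceiling(rmip_threshold / 100 * n_resamples)),
      seed = seed
    )
  }
  counts <- matrix(0L, M, length(models), dimnames = list(geno$map$marker, models))
  best_p <- matrix(Inf, M, length(models), dimnames = list(geno$map$marker, models))
  for (r in seq_len(n_resamples)) {
    idx <- idx_list[[r]]
    eig <- eig_list[[r]]
    ysub <- y[idx]
    Xsub <- if (is.null(X)) NULL else as.matrix(X)[idx, , drop = FALSE]
    gsub <- geno_subset(geno, samples = idx)
    for (m in models) {
      Gt <- crossprod(eig$vectors, recoded[[m]][idx, , drop = FALSE])
      hits <- forward_select(ysub, gsub, model = m, threshold = threshold,
                             max_steps = max_steps, X = Xsub, eig = eig, Gt = Gt)
      if (nrow(hits) > 0) {
        jj <- match(hits$marker, geno$map$marker)
        counts[jj, m] <- counts[jj, m] + 1L
        best_p[jj, m] <- pmin(best_p[jj, m], hits$p)
      }
    }
  }
  rmip_m <- 100 * counts / n_resamples
  rmip <- data.frame(marker = geno$map$marker, chrom = geno$map$chrom,
                     pos = geno$map$pos, stringsAsFactors = FALSE)
  for (m in models) rmip[[m]] <- rmip_m[, m]
  rmip$rmip <- apply(rmip_m, 1L, max)
  rmip$best_model <- models[apply(rmip_m, 1L, which.max)]
  sig <- rmip$rmip >= rmip_threshold
  selected <- rmip[sig, , drop = FALSE]
  if (nrow(selected) > 0) {
    selected$p <- vapply(seq_len(nrow(selected)), function(i) {
      min(best_p[match(selected$marker[i], geno$map$marker), ])
    }, numeric(1))
  } else {
    selected$p <- numeric(0)
  }
  rownames(rmip) <- rownames(selected) <- NULL
  structure(list(
    rmip = rmip, selected = selected, threshold = threshold, models = models,
    n_resamples = n_resamples, subsample_frac = subsample_frac,
    rmip_threshold = rmip_threshold, seed = seed
  ), class = "rmip_result")
}

# Permutation calibration of the resampling engine's selection threshold.
# For each permuted trait: full-data scans (all models) rank the markers;
# for the top `n_top` markers the subsample p-values are computed on every
# resample draw, and the permutation's statistic is the count_min-th smallest
# subsample p (the threshold at which that marker would reach the reporting
# RMIP), minimized over the top markers and models. The returned threshold is
# the largest statistic whose empirical rank / n_perm stays below fdr.
calibrate_rmip_threshold <- function(y, recoded, K, idx_list, eig_list, X,
                                     n_perm, fdr, count_min, seed,
                                     n_top = 10L) {
  n <- length(y)
  R <- length(idx_list)
  count_min <- min(count_min, R)
  eig_full <- eigen(K, symmetric = TRUE)
  eig_full$values <- pmax(eig_full$values, 1e-6)
  Gt_full <- lapply(recoded, function(G) crossprod(eig_full$vectors, G))
  Gt2_full <- lapply(Gt_full, function(Gt) Gt * Gt)
  y_perm <- with_seed(child_seed(seed, 97L), {
    vapply(seq_len(n_perm), function(b) y[sample.int(n)], numeric(n))
  })
  # per permutation: markers worth tracking (indices into columns)
  top_sets <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    fitb <- polygenic_fit(y_perm[, b], eig = eig_full, X = X, tol = 1e-3)
    pmin_models <- NULL
    for (m in seq_along(recoded)) {
      sc <- score_scan(fitb, Gt_full[[m]], Gt2_full[[m]])
      pmin_models <- if (is.null(pmin_models)) sc$p else pmin(pmin_models, sc$p)
    }
    top_sets[[b]] <- order(pmin_models)[seq_len(min(n_top, length(pmin_models)))]
  }
  if (count_min == 1L && R == 1L && length(idx_list[[1]]) == n) {
    # degenerate single full-sample "resample": classic single-scan threshold
    stats <- vapply(seq_len(n_perm), function(b) {
      fitb <- polygenic_fit(y_perm[, b], eig = eig_full, X = X)
      min(vapply(seq_along(recoded), function(m)
        min(score_scan(fitb, Gt_full[[m]], Gt2_full[[m]])$p), numeric(1)))
    }, numeric(1))
  } else {
    track <- sort(unique(unlist(top_sets)))
    # p_store[[b]]: R x |top_sets[[b]]| matrix of min-over-model p-values
    p_store <- lapply(top_sets, function(ts) matrix(NA_real_, R, length(ts)))
    for (r in seq_len(R)) {
      idx <- idx_list[[r]]
      eig <- eig_list[[r]]
      Xsub <- if (is.null(X)) NULL else as.matrix(X)[idx, , drop = FALSE]
      Gt_tr <- lapply(recoded, function(G)
        crossprod(eig$vectors, G[idx, track, drop = FALSE]))
      for (b in seq_len(n_perm)) {
        fitb <- polygenic_fit(y_perm[idx, b], eig = eig, X = Xsub, tol = 1e-3)
        cols <- match(top_sets[[b]], track)
        pb <- NULL
        for (m in seq_along(recoded)) {
          Gt_b <- Gt_tr[[m]][, cols, drop = FALSE]
          sc <- score_scan(fitb, Gt_b)
          pb <- if (is.null(pb)) sc$p else pmin(pb, sc$p)
        }
        p_store[[b]][r, ] <- pb
      }
    }
    stats <- vapply(seq_len(n_perm), function(b) {
      min(apply(p_store[[b]], 2L, function(p) sort(p)[count_min]))
    }, numeric(1))
  }
  s <- sort(stats)
  ok <- which(seq_len(n_perm) / n_perm < fdr)
  if (length(ok) > 0) s[max(ok)] else fdr / ncol(recoded[[1]])
}

#' @export
print.rmip_result <- function(x, ...) {
  cat(sprintf(
    "rmip_result: %d resamples x %d model(s); p threshold %.3g; %d marker(s) at RMIP >= %g\n",
    x$n_resamples, length(x$models), x$threshold, nrow(x$selected), x$rmip_threshold
  ))
  invisible(x)
}

#' Re-run a derived-phenotype GWAS with the F1 phenotype as covariate
#'
#' Pleiotropy analysis: repeats [resample_rmip()] for a derived phenotype
#' (BPaV or SCA) with the matching original F1 phenotype as a fixed
#' covariate, and reports which previously significant markers disappear —
#' signals absorbed by the covariate reflect loci that act on the derived
#' phenotype through the F1 phenotype itself (mediated pleiotropy).
#'
#' @param y derived phenotype vector.
#' @param covariate matching F1 phenotype vector (same sample order).
#' @param previous an `rmip_result` from the covariate-free run.
#' @inheritParams resample_rmip
#' @param ... passed on to [resample_rmip()].
#' @return list with `result` (the new `rmip_result`), `persisting` and
#'   `disappeared` marker ids relative to `previous`.
#' @export
covariate_rerun <- function(y, geno, K, covariate, previous = NULL, X = NULL, ...) {
  if (length(covariate) != length(y)) stopf("covariate must align with the phenotype")
  Xc <- cbind(X, covariate = covariate)
  res <- resample_rmip(y, geno, K, X = Xc, ...)
  persisting <- disappeared <- character(0)
  if (!is.null(previous)) {
    old <- previous$selected$marker
    persisting <- intersect(old, res$selected$marker)
    disappeared <- setdiff(old, res$selected$marker)
  }
  list(result = res, persisting = persisting, disappeared = disappeared)
}
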