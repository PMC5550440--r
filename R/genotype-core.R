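#' Sequential marker quality filters
#'
#' Removes markers whose missing rate exceeds `max_missing`, then — among the
#' survivors — markers whose heterozygous-call rate exceeds `max_het`. Both
#' thresholds are inclusive (a marker exactly at the threshold is retained),
#' and the two steps are applied in that order so per-step removal counts are
#' meaningful.
#'
#' @param geno a [geno_matrix()].
#' @param max_missing maximum tolerated fraction of missing calls (default 0.2).
#' @param max_het maximum tolerated fraction of heterozygous calls (default 0.15).
#' @return the filtered `geno_matrix`, with attribute `filter_counts` giving
#'   the number of markers removed at each step.
#' @export
filter_markers <- function(geno, max_missing = 0.2, max_het = 0.15) {
  assert_fraction(max_missing, "max_missing")
  assert_fraction(max_het, "max_het")
  miss <- colMeans(is.na(geno$calls))
  keep1 <- miss <= max_missing
  g1 <- geno_subset(geno, markers = which(keep1))
  het <- colMeans(g1$calls == 1L, na.rm = TRUE)
  het[is.nan(het)] <- 0
  keep2 <- het <= max_het
  out <- geno_subset(g1, markers = which(keep2))
  if (ncol(out$calls) == 0L) warnf("no markers survive the quality filters")
  attr(out, "filter_counts") <- c(
    removed_missing = sum(!keep1),
    removed_het = sum(keep1) - sum(keep2)
  )
  out
}

#' Minor allele frequency per marker
#'
#' @param geno a `geno_matrix`.
#' @param samples optional sample subset over which to count alleles.
#' @return numeric vector of per-marker MAF (folded to be <= 0.5).
#' @export
maf <- function(geno, samples = NULL) {
  calls <- if (is.null(samples)) geno$calls else geno$calls[samples, , drop = FALSE]
  n_obs <- colSums(!is.na(calls))
  freq <- colSums(calls, na.rm = TRUE) / (2 * n_obs)
  freq[n_obs == 0L] <- NA_real_
  pmin(freq, 1 - freq)
}

#' Remove markers monomorphic in a sample set
#'
#' @param geno a `geno_matrix`.
#' @param samples optional sample subset (e.g. the parents) on which
#'   polymorphism is judged; calls of all samples are kept for survivors.
#' @return filtered `geno_matrix`.
#' @export
polymorphic_filter <- function(geno, samples = NULL) {
  calls <- if (is.null(samples)) geno$calls else geno$calls[samples, , drop = FALSE]
  poly <- apply(calls, 2L, function(g) length(unique(g[!is.na(g)])) > 1L)
  geno_subset(geno, markers = which(poly))
}

#' Filter markers by minor allele frequency
#'
#' @param geno a `geno_matrix`.
#' @param min_maf inclusive lower bound (default 0.05).
#' @param samples optional sample subset on which MAF is computed.
#' @return filtered `geno_matrix`.
#' @export
maf_filter <- function(geno, min_maf = 0.05, samples = NULL) {
  assert_fraction(min_maf, "min_maf")
  f <- maf(geno, samples)
  geno_subset(geno, markers = which(!is.na(f) & f >= min_maf))
}

#' K-nearest-neighbour genotype imputation
#'
#' Each missing call is replaced by the most frequent call among the `k`
#' nearest reference samples, with distance the mean absolute call difference
#' over markers observed in both samples. Observed calls are never changed.
#' Ties in neighbour ranking are broken by reference sample order; ties in the
#' mode by the smaller call code. Both rules are deterministic.
#'
#' @param geno `geno_matrix` with missing calls to fill.
#' @param reference_panel `geno_matrix` over the same markers used as donor
#'   pool; defaults to `geno` itself.
#' @param k number of neighbours (default 5).
#' @return imputed `geno_matrix`.
#' @export
knn_impute <- function(geno, reference_panel = NULL, k = 5L) {
  if (k < 1L) stopf("`k` must be >= 1")
  ref <- reference_panel %||% geno
  if (!identical(ref$map$marker, geno$map$marker)) stopf("reference panel must share the marker set")
  calls <- geno$calls
  refc <- ref$calls
  all_missing <- rowSums(!is.na(calls)) == 0L
  if (any(all_missing)) {
    stopf("sample(s) with no observed genotype: %s",
          paste(rownames(calls)[all_missing], collapse = ", "))
  }
  self_panel <- identical(ref, geno) || is.null(reference_panel)
  for (i in which(rowSums(is.na(calls)) > 0L)) {
    g <- calls[i, ]
    d <- vapply(seq_len(nrow(refc)), function(r) {
      shared <- !is.na(g) & !is.na(refc[r, ])
      if (!any(shared)) return(Inf)
      mean(abs(g[shared] - refc[r, shared]))
    }, numeric(1))
    if (self_panel) d[i] <- Inf  # never use a sample as its own donor
    nb <- order(d)[seq_len(min(k, sum(is.finite(d))))]
    miss <- which(is.na(g))
    for (j in miss) {
      donor <- refc[nb, j]
      donor <- donor[!is.na(donor)]
      if (length(donor) == 0L) next
      tab <- table(donor)
      calls[i, j] <- as.integer(names(tab)[which.max(tab)])
    }
  }
  geno_matrix(calls, geno$map)
}

#' Assemble F1 genotypes from inbred parents
#'
#' The F1 inherits one allele from each parent: two identical homozygotes
#' give that homozygote, two different homozygotes give a heterozygote, and a
#' heterozygous or missing parental call propagates as a missing F1 call
#' (parents are declared inbred, so residual heterozygosity is not trusted).
#'
#' @param geno_parents `geno_matrix` holding all parents of the design.
#' @param design a [cross_design()].
#' @return `geno_matrix` of F1 calls over the same markers.
#' @export
combine_f1 <- function(geno_parents, design) {
  ids <- sample_ids(geno_parents)
  absent <- setdiff(c(design$maternal, design$paternal), ids)
  if (length(absent) > 0) {
    bad <- design[design$maternal %in% absent | design$paternal %in% absent, ]
    stopf("parents missing from genotypes for cross(es): %s",
          paste(utils::head(bad$f1, 5), collapse = ", "))
  }
  mat <- geno_parents$calls[design$maternal, , drop = FALSE]
  pat <- geno_parents$calls[design$paternal, , drop = FALSE]
  # both parents observed and homozygous: F1 dosage is the parental mean
  # (0+0 -> 0, 2+2 -> 2, 0+2 -> 1); anything else is not trusted.
  ok <- !is.na(mat) & !is.na(pat) & mat != 1L & pat != 1L
  f1 <- matrix(NA_integer_, nrow(mat), ncol(mat))
  f1[ok] <- (mat[ok] + pat[ok]) %/% 2L
  rownames(f1) <- design$f1
  geno_matrix(f1, geno_parents$map)
}

#' Per-sample heterozygosity, overall or in windows
#'
#' @param geno a `geno_matrix`.
#' @param window window size in bp for non-overlapping genomic windows, or
#'   `NULL` for genome-wide values only.
#' @return if `window` is `NULL`, a named numeric vector (fraction of
#'   non-missing calls that are heterozygous). Otherwise a list with
#'   `per_sample` and a data.frame `per_window` (chrom, start, end, het =
#'   mean per-sample heterozygosity in the window).
#' @export
heterozygosity <- function(geno, window = NULL) {
  het <- rowSums(geno$calls == 1L, na.rm = TRUE) / rowSums(!is.na(geno$calls))
  if (is.null(window)) return(het)
  if (window <= 0) stopf("`window` must be positive")
  map <- geno$map
  win_id <- paste(map$chrom, (map$pos - 1L) %/% window)
  groups <- split(seq_len(nrow(map)), win_id)
  per_window <- do.call(rbind, lapply(groups, function(idx) {
    sub <- geno$calls[, idx, drop = FALSE]
    h <- rowSums(sub == 1L, na.rm = TRUE) / pmax(rowSums(!is.na(sub)), 1L)
    w0 <- (map$pos[idx[1]] - 1L) %/% window
    data.frame(
      chrom = map$chrom[idx[1]],
      start = w0 * window + 1L, end = (w0 + 1L) * window,
      n_markers = length(idx), het = mean(h)
    )
  }))
  per_window <- per_window[order(match(per_window$chrom, unique(map$chrom)), per_window$start), ]
  rownames(per_window) <- NULL
  list(per_sample = het, per_window = per_window)
}

#' Realized-relationship (kinship) matrix
#'
#' VanRaden-style frequency-standardized GRM: with dosage matrix `M` and
#' per-marker allele frequency `p`, `K = Z Z' / (2 * sum(p(1-p)))` where
#' `Z = M - 2p`. Monomorphic markers carry no information and are skipped
#' with a warning. The result is bent to be positive semi-definite by
#' flooring eigenvalues at 1e-6 when needed.
#'
#' @param geno `geno_matrix` with no missing calls.
#' @return symmetric sample-by-sample matrix of class `matrix`.
#' @export
kinship <- function(geno) {
  calls <- geno$calls
  if (anyNA(calls)) stopf("kinship requires complete genotypes; impute first")
  p <- colMeans(calls) / 2
  keep <- p > 0 & p < 1
  if (!all(keep)) warnf("skipping %d monomorphic marker(s) in kinship", sum(!keep))
  Z <- sweep(calls[, keep, drop = FALSE], 2L, 2 * p[keep])
  K <- tcrossprod(Z) / (2 * sum(p[keep] * (1 - p[keep])))
  ev <- eigen(K, symmetric = TRUE)
  if (min(ev$values) < 0) {
    K <- ev$vectors %*% (pmax(ev$values, 1e-6) * t(ev$vectors))
    dimnames(K) <- list(rownames(calls), rownames(calls))
  }
  K
}

#' Principal components of the genotype matrix
#'
#' Scores are the leading eigenvectors of the realized-relationship matrix
#' scaled by the square-root eigenvalues, so `scores %*% t(scores)`
#' approaches the GRM as components are added. Deterministic up to sign.
#'
#' @param geno `geno_matrix` with no missing calls.
#' @param n_components number of PCs to return.
#' @return matrix of sample scores (samples x components).
#' @export
geno_pca <- function(geno, n_components = 10L) {
  K <- kinship(geno)
  ev <- eigen(K, symmetric = TRUE)
  k <- min(n_components, ncol(K))
  sc <- ev$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(pmax(ev$values[seq_len(k)], 0)), k)
  rownames(sc) <- rownames(K)
  colnames(sc) <- paste0("PC", seq_len(k))
  attr(sc, "values") <- ev$values
  sc
}

#' MAF profile per parental group around a focal marker
#'
#' @param geno parental `geno_matrix`.
#' @param groups named character vector or factor: group label per sample.
#' @param around focal marker id.
#' @param flank half-window in bp either side of the focal marker.
#' @return data.frame (marker, chrom, pos, offset, group, maf).
#' @export
maf_by_group <- function(geno, groups, around, flank = 1e6) {
  j <- match(around, geno$map$marker)
  if (is.na(j)) stopf("marker %s not found", around)
  groups <- groups[sample_ids(geno)]
  if (anyNA(groups)) stopf("every sample needs a group label")
  map <- geno$map
  sel <- which(map$chrom == map$chrom[j] & abs(map$pos - map$pos[j]) <= flank)
  out <- lapply(unique(groups), function(g) {
    ids <- sample_ids(geno)[groups == g]
    if (length(ids) == 0L) stopf("group %s is empty", g)
    data.frame(
      marker = map$marker[sel], chrom = map$chrom[sel], pos = map$pos[sel],
      offset = map$pos[sel] - map$pos[j], group = g,
      maf = maf(geno_subset(geno, markers = sel), samples = ids)
    )
  })
  do.call(rbind, out)
}
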