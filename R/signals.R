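#' Merge significant SNPs into association signals
#'
#' Single-linkage chaining: two same-chromosome markers belong to the same
#' signal when they lie within `max_distance` of each other AND their
#' genotype vectors are correlated (regression R-squared `>= min_r2`); the
#' final membership is the transitive closure of that relation. The lead SNP
#' of a signal is the member with the highest RMIP; ties go to the smaller
#' single-scan p-value, then to the lower position.
#'
#' @param selected data.frame with columns marker, chrom, pos, rmip and
#'   optionally p (e.g. `$selected` of an `rmip_result`).
#' @param geno `geno_matrix` providing the genotype vectors (F1 panel).
#' @param max_distance chaining distance in bp (default 800 kb).
#' @param min_r2 minimum pairwise genotype R-squared (default 0.2).
#' @return data.frame (signal, chrom, start, end, lead_marker, lead_pos,
#'   lead_rmip, n_members, members).
#' @export
merge_signals <- function(selected, geno, max_distance = 8e5, min_r2 = 0.2) {
  if (nrow(selected) == 0) {
    return(data.frame(signal = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      lead_marker = character(0), lead_pos = integer(0),
                      lead_rmip = numeric(0), n_members = integer(0),
                      members = character(0)))
  }
  sel <- selected[order(match(selected$chrom, unique(geno$map$chrom)), selected$pos), ]
  n <- nrow(sel)
  comp <- seq_len(n)
  calls <- geno$calls[, sel$marker, drop = FALSE]
  for (i in seq_len(n - 1)[n > 1]) {
    for (j in seq((i + 1), n)) {
      if (sel$chrom[i] != sel$chrom[j]) next
      if (abs(sel$pos[i] - sel$pos[j]) >= max_distance) next
      r2 <- suppressWarnings(stats::cor(calls[, i], calls[, j],
                                        use = "complete.obs"))^2
      if (is.na(r2) || r2 < min_r2) next
      old <- comp[j]; new <- comp[i]
      comp[comp == old] <- new
    }
  }
  groups <- split(seq_len(n), comp)
  out <- lapply(seq_along(groups), function(k) {
    idx <- groups[[k]]
    s <- sel[idx, , drop = FALSE]
    ord <- order(-s$rmip,
                 if (!is.null(s$p)) s$p else rep(0, nrow(s)),
                 s$pos)
    lead <- s[ord[1], ]
    data.frame(signal = k, chrom = lead$chrom, start = min(s$pos),
               end = max(s$pos), lead_marker = lead$marker,
               lead_pos = lead$pos, lead_rmip = lead$rmip,
               n_members = nrow(s),
               members = paste(s$marker, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(match(out$chrom, unique(geno$map$chrom)), out$start), ]
  out$signal <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# D-prime point estimate and likelihood-based confidence interval for a pair
# of biallelic sites given phased haplotypes (0/1 vectors, no missing).
# CI bounds follow the Haploview convention: normalized likelihood over a
# |D'| grid; lower bound = largest grid value with <= 5% of mass below it,
# upper = smallest with <= 5% above.
dprime_ci <- function(h1, h2, grid = seq(0, 1, by = 0.005)) {
  ok <- !is.na(h1) & !is.na(h2)
  h1 <- h1[ok]; h2 <- h2[ok]
  n <- length(h1)
  p <- mean(h1); q <- mean(h2)
  if (p %in% c(0, 1) || q %in% c(0, 1)) return(NULL)  # uninformative pair
  n11 <- sum(h1 == 1 & h2 == 1)
  n10 <- sum(h1 == 1 & h2 == 0)
  n01 <- sum(h1 == 0 & h2 == 1)
  n00 <- n - n11 - n10 - n01
  d_obs <- n11 / n - p * q
  sgn <- if (d_obs >= 0) 1 else -1
  dmax <- if (sgn > 0) min(p * (1 - q), (1 - p) * q) else min(p * q, (1 - p) * (1 - q))
  if (dmax <= 0) return(NULL)
  ll <- vapply(grid, function(dp) {
    D <- sgn * dp * dmax
    f11 <- max(p * q + D, 1e-12)
    f10 <- max(p * (1 - q) - D, 1e-12)
    f01 <- max((1 - p) * q - D, 1e-12)
    f00 <- max((1 - p) * (1 - q) + D, 1e-12)
    n11 * log(f11) + n10 * log(f10) + n01 * log(f01) + n00 * log(f00)
  }, numeric(1))
  lik <- exp(ll - max(ll))
  cum <- cumsum(lik) / sum(lik)
  lo_i <- which(cum <= 0.05)
  lo <- if (length(lo_i) > 0) grid[max(lo_i) + 1L] else grid[1]
  hi_i <- which(cum >= 0.95)
  hi <- if (length(hi_i) > 0) grid[min(hi_i)] else grid[length(grid)]
  list(dprime = abs(d_obs) / dmax, lower = lo, upper = hi)
}

#' Haplotype-block QTL interval around a lead SNP
#'
#' Gabriel-style block built from pairwise D' confidence intervals on the
#' (trivially phased) inbred parental haplotypes. A pair is in strong LD when
#' its CI bounds reach `[0.70, 0.98]`; a pair is strong recombination
#' evidence when its CI upper bound is below 0.90; other pairs are
#' uninformative. A candidate interval is a block when its outermost pair is
#' strong LD and at least 95% of its informative pairs are strong LD. The QTL
#' range is the widest such contiguous interval containing the lead SNP
#' within `max_flank` markers either side; if none exists the interval
#' degenerates to the lead SNP position.
#'
#' @param lead_marker marker id of the lead SNP.
#' @param parental_geno `geno_matrix` of the inbred parents.
#' @param max_flank search radius in markers (default 25).
#' @param strong_lo,strong_hi CI bounds defining strong LD.
#' @param min_strong_frac minimum fraction of informative pairs in strong LD.
#' @return list (chrom, start, end, n_markers, degenerate).
#' @export
hapblock_interval <- function(lead_marker, parental_geno, max_flank = 25L,
                              strong_lo = 0.70, strong_hi = 0.98,
                              min_strong_frac = 0.95) {
  map <- parental_geno$map
  j <- match(lead_marker, map$marker)
  if (is.na(j)) stopf("lead marker %s not in parental genotypes", lead_marker)
  hap <- parental_geno$calls / 2          # inbred lines: one haplotype each
  hap[parental_geno$calls == 1L] <- NA    # residual hets are not trusted
  degenerate <- list(chrom = map$chrom[j], start = map$pos[j], end = map$pos[j],
                     n_markers = 1L, degenerate = TRUE)
  if (length(unique(stats::na.omit(hap[, j]))) < 2L) {
    warnf("lead marker %s monomorphic in parents; degenerate interval", lead_marker)
    return(degenerate)
  }
  on_chr <- which(map$chrom == map$chrom[j])
  lo <- max(min(on_chr), j - max_flank)
  hi <- min(max(on_chr), j + max_flank)
  idx <- lo:hi
  k <- length(idx)
  ci <- array(NA_real_, c(k, k, 2))
  for (aa in seq_len(k - 1)) {
    for (bb in seq((aa + 1), k)) {
      res <- dprime_ci(hap[, idx[aa]], hap[, idx[bb]])
      if (!is.null(res)) ci[aa, bb, ] <- c(res$lower, res$upper)
    }
  }
  pair_class <- function(aa, bb) {
    lohi <- ci[aa, bb, ]
    if (anyNA(lohi)) return("noninformative")
    if (lohi[1] >= strong_lo && lohi[2] >= strong_hi) return("strong")
    if (lohi[2] < 0.90) return("recomb")
    "noninformative"
  }
  jloc <- j - lo + 1L
  best <- NULL
  for (s in seq_len(jloc)) {
    for (e in seq(jloc, k)) {
      if (e == s) next
      if (pair_class(s, e) != "strong") next
      cls <- unlist(lapply(seq(s, e - 1), function(aa)
        vapply(seq(aa + 1, e), function(bb) pair_class(aa, bb), character(1))))
      inf <- cls[cls != "noninformative"]
      if (length(inf) == 0) next
      if (mean(inf == "strong") >= min_strong_frac) {
        if (is.null(best) || (e - s) > (best[2] - best[1])) best <- c(s, e)
      }
    }
  }
  if (is.null(best)) return(degenerate)
  list(chrom = map$chrom[j], start = map$pos[idx[best[1]]],
       end = map$pos[idx[best[2]]], n_markers = best[2] - best[1] + 1L,
       degenerate = FALSE)
}
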