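tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# D for one set of sites: per-site observed haplotype counts n_i and minor
# counts k_i. pi and S use per-site n; the variance constants use the rounded
# mean per-site n (exact for complete data).
tajima_d_sites <- function(n_obs, k_minor) {
  seg <- k_minor > 0 & k_minor < n_obs
  S <- sum(seg)
  if (S < 3L) return(list(D = NA_real_, S = S, pi = NA_real_))
  n_i <- n_obs[seg]
  k_i <- k_minor[seg]
  pi <- sum(k_i * (n_i - k_i) / choose(n_i, 2))
  n_eff <- round(mean(n_i))
  if (n_eff < 4L) return(list(D = NA_real_, S = S, pi = pi))
  cst <- tajima_constants(n_eff)
  theta_w <- S / cst$a1
  denom <- sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  list(D = (pi - theta_w) / denom, S = S, pi = pi)
}

#' Sliding-window Tajima's D over one parental group
#'
#' Inbred lines contribute one haplotype each (residual heterozygous calls
#' are excluded per site with a warning). Per window of `window` bp advanced
#' by `step` bp: `S` = segregating sites, `pi` = mean pairwise difference,
#' `theta_W = S / a1`, and `D = (pi - theta_W) / sqrt(e1*S + e2*S*(S-1))`
#' with the standard Tajima (1989) constants for the window's sample size.
#' D is undefined (NA) when `S < 3` or fewer than 4 haplotypes carry data;
#' sites with fewer than 4 non-missing haplotypes are skipped. Terminal
#' windows shorter than `window` are retained and flagged.
#'
#' @param geno parental `geno_matrix` restricted to one group (use
#'   [geno_subset()]), all lines inbred.
#' @param window window size in bp (default 240 kb).
#' @param step step size in bp (default 20 kb).
#' @param group label recorded in the output.
#' @return data.frame (chrom, start, end, n_sites, S, pi, tajimas_d, group,
#'   terminal).
#' @export
tajimas_d_scan <- function(geno, window = 240e3, step = 20e3, group = NA_character_) {
  if (nrow(geno$calls) < 4L) stopf("need at least 4 haplotypes (lines) in the group")
  calls <- geno$calls
  if (any(calls == 1L, na.rm = TRUE)) {
    warnf("residual heterozygous parental call(s) excluded per site")
    calls[calls == 1L] <- NA_integer_
  }
  hap <- calls %/% 2L
  n_obs <- colSums(!is.na(hap))
  k_min <- colSums(hap == 1L, na.rm = TRUE)
  # fold so k is the minor count per site (D is label-invariant either way;
  # folding keeps k*(n-k) intact)
  map <- geno$map
  out <- list()
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    pos <- map$pos[idx]
    chr_end <- max(pos)
    starts <- seq(1, max(chr_end - 1, 1), by = step)
    for (s in starts) {
      e <- s + window
      in_win <- idx[pos >= s & pos < e]
      usable <- in_win[n_obs[in_win] >= 4L]
      td <- tajima_d_sites(n_obs[usable], k_min[usable])
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = s, end = e, n_sites = length(usable),
        S = td$S, pi = td$pi, tajimas_d = td$D, group = group,
        terminal = e > chr_end + 1, stringsAsFactors = FALSE
      )
      if (e > chr_end) break
    }
  }
  do.call(rbind, out)
}

#' Low-diversity (low Tajima's D) regions
#'
#' Windows with a defined D at or below the given percentile of the scan's D
#' distribution, merged when overlapping or book-ended.
#'
#' @param scan output of [tajimas_d_scan()].
#' @param percentile percentile cutoff in (0, 100] (default 10).
#' @return data.frame (chrom, start, end, group, min_d).
#' @export
low_d_regions <- function(scan, percentile = 10) {
  if (nrow(scan) == 0) stopf("empty scan")
  defined <- scan[!is.na(scan$tajimas_d), , drop = FALSE]
  if (nrow(defined) == 0) return(defined[, c("chrom", "start", "end", "group")])
  cutoff <- stats::quantile(defined$tajimas_d, percentile / 100, names = FALSE)
  hits <- defined[defined$tajimas_d <= cutoff, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      group = character(0), min_d = numeric(0)))
  }
  hits <- hits[order(match(hits$chrom, unique(scan$chrom)), hits$start), ]
  merged <- list()
  cur <- hits[1, ]
  cur_min <- cur$tajimas_d
  flush <- function(cur, cur_min) data.frame(
    chrom = cur$chrom, start = cur$start, end = cur$end, group = cur$group,
    min_d = cur_min, stringsAsFactors = FALSE
  )
  if (nrow(hits) > 1) {
    for (i in 2:nrow(hits)) {
      h <- hits[i, ]
      if (h$chrom == cur$chrom && h$start <= cur$end) {
        cur$end <- max(cur$end, h$end)
        cur_min <- min(cur_min, h$tajimas_d)
      } else {
        merged[[length(merged) + 1L]] <- flush(cur, cur_min)
        cur <- h
        cur_min <- h$tajimas_d
      }
    }
  }
  merged[[length(merged) + 1L]] <- flush(cur, cur_min)
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

#' Overlap of QTL intervals with low-diversity regions
#'
#' Half-open interval intersection: a QTL `[qs, qe)` overlaps a region
#' `[rs, re)` iff `qs < re && rs < qe`. A QTL ending exactly where a region
#' starts does not overlap.
#'
#' @param qtls data.frame with columns chrom, start, end (one row per QTL).
#' @param regions output of [low_d_regions()] (may hold several groups).
#' @return `qtls` with one logical column `overlap_<group>` per group plus a
#'   summary attribute `counts`.
#' @export
qtl_overlap <- function(qtls, regions) {
  groups <- unique(regions$group)
  out <- qtls
  for (g in groups) {
    rg <- regions[regions$group == g, , drop = FALSE]
    out[[paste0("overlap_", g)]] <- vapply(seq_len(nrow(qtls)), function(i) {
      any(rg$chrom == qtls$chrom[i] & qtls$start[i] < rg$end & rg$start < qtls$end[i])
    }, logical(1))
  }
  attr(out, "counts") <- vapply(groups, function(g)
    sum(out[[paste0("overlap_", g)]]), integer(1))
  out
}
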