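#' Seed number per panicle from yield components
#'
#' `SNPP = GYPP / (PN * TGW / 1000)`: grain yield per plant divided by panicle
#' number times per-grain weight. `TGW` is a 1000-grain weight in grams, so it
#' is divided by 1000 to give the weight of a single grain; without that
#' scaling the seed counts come out three orders of magnitude too small.
#' A zero or missing divisor yields `NA`.
#'
#' @param gypp grain yield per plant (g).
#' @param pn panicle number per plant.
#' @param tgw 1000-grain weight (g).
#' @return seed number per panicle (numeric vector).
#' @export
snpp <- function(gypp, pn, tgw) {
  out <- gypp / (pn * tgw / 1000)
  bad <- !is.na(pn) & !is.na(tgw) & (pn <= 0 | tgw <= 0)
  if (any(bad)) {
    warnf("%d record(s) with non-positive PN or TGW flagged as NA", sum(bad))
    out[bad] <- NA_real_
  }
  out
}

#' Better-paternal and mid-parent heterosis values
#'
#' `BPaV = F1 - Pat` compares each hybrid to its (fertile) paternal line —
#' the breeding-relevant contrast when the maternal line is male-sterile.
#' `MPV = F1 - (Pat + Mat) / 2` is classical mid-parent heterosis. A missing
#' parental value propagates to a missing derived value.
#'
#' @param f1 F1 phenotype value(s).
#' @param pat paternal line value(s), matched to each F1.
#' @param mat maternal line value(s), matched to each F1.
#' @return numeric vector.
#' @export
bpav <- function(f1, pat) f1 - pat

#' @rdname bpav
#' @export
mpv <- function(f1, pat, mat) f1 - (pat + mat) / 2

#' General and specific combining abilities of a diallel
#'
#' Method-of-moments decomposition on cross means: with `ybar_ij` the mean
#' phenotype of the cross (i, j), `ybar..` the unweighted grand mean over
#' observed crosses, and `ybar_i.` the mean over crosses involving parent i,
#' `GCA_i = ybar_i. - ybar..` and
#' `SCA_ij = ybar_ij - ybar.. - GCA_mat - GCA_pat`.
#' On a complete balanced diallel the GCAs of each parental group sum to zero
#' and every row/column of SCA sums to zero.
#'
#' @param values named numeric vector of per-F1 phenotype values (replicates
#'   already averaged within sample and environment), names = F1 ids.
#' @param design a [cross_design()] covering those F1 ids.
#' @return list with `sca` (data.frame f1, maternal, paternal, value, sca),
#'   `gca` (data.frame parent, group, gca, n_crosses) and `grand_mean`.
#' @export
gca_sca <- function(values, design) {
  d <- design[match(names(values), design$f1), , drop = FALSE]
  if (anyNA(d$f1)) stopf("value(s) for F1 id(s) absent from the design")
  ok <- !is.na(values)
  d <- d[ok, , drop = FALSE]
  v <- values[ok]
  grand <- mean(v)
  gca_mat <- tapply(v, d$maternal, mean) - grand
  gca_pat <- tapply(v, d$paternal, mean) - grand
  n_mat <- table(d$maternal)
  n_pat <- table(d$paternal)
  if (any(c(n_mat, n_pat) < 2L)) {
    warnf("parent(s) with a single cross: GCA estimated from one cross mean")
  }
  zero <- setdiff(unique(c(design$maternal, design$paternal)), c(d$maternal, d$paternal))
  if (length(zero) > 0) stopf("parent(s) with zero observed crosses: %s",
                              paste(zero, collapse = ", "))
  sca <- v - grand - gca_mat[d$maternal] - gca_pat[d$paternal]
  list(
    sca = data.frame(f1 = d$f1, maternal = d$maternal, paternal = d$paternal,
                     value = unname(v), sca = unname(sca), stringsAsFactors = FALSE),
    gca = data.frame(
      parent = c(names(gca_mat), names(gca_pat)),
      group = c(rep("maternal", length(gca_mat)), rep("paternal", length(gca_pat))),
      gca = unname(c(gca_mat, gca_pat)),
      n_crosses = as.integer(c(n_mat[names(gca_mat)], n_pat[names(gca_pat)])),
      stringsAsFactors = FALSE
    ),
    grand_mean = grand
  )
}

#' Rank-based inverse-normal transform
#'
#' Gaussianizes a phenotype by mapping average ranks through the normal
#' quantile function with the Blom offset: `qnorm((rank - 3/8) / (n + 1/4))`.
#' Monotone and distribution-free; ties share their average rank; `NA`s are
#' preserved in place.
#'
#' @param values numeric vector (>= 20 non-missing values required).
#' @return transformed vector of the same length.
#' @export
normalize_phenotype <- function(values) {
  obs <- !is.na(values)
  n <- sum(obs)
  if (n < 20L) stopf("need at least 20 non-missing values, got %d", n)
  if (stats::sd(values[obs]) == 0) stopf("constant phenotype cannot be normalized")
  r <- rank(values[obs], ties.method = "average")
  out <- values
  out[obs] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Yield-component correlations and variance explained
#'
#' Pairwise Pearson correlations between grain yield and its component
#' traits, plus the single-predictor regression R-squared of yield on each
#' component (identical to the squared correlation; reported for the usual
#' summary-table layout).
#'
#' @param traits data.frame of per-sample trait values, one column per trait.
#' @param yield name of the yield column (default `"GYPP"`).
#' @return data.frame (component, r, r_squared).
#' @export
yield_component_regression <- function(traits, yield = "GYPP") {
  if (!yield %in% names(traits)) stopf("column %s not found", yield)
  comps <- setdiff(names(traits)[vapply(traits, is.numeric, logical(1))], yield)
  out <- lapply(comps, function(cn) {
    ok <- stats::complete.cases(traits[[yield]], traits[[cn]])
    fit <- stats::lm(traits[[yield]][ok] ~ traits[[cn]][ok])
    data.frame(component = cn,
               r = stats::cor(traits[[yield]][ok], traits[[cn]][ok]),
               r_squared = summary(fit)$r.squared, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Average replicates and derive heterosis phenotypes per trait
#'
#' Averages plot replicates within sample x environment, then attaches, per
#' F1 and trait: the F1 value, BPaV, MPV (when maternal values exist) and SCA,
#' plus per-parent GCA. Environments are never pooled.
#'
#' @param traits long-format table (columns sample, role, env, rep, trait,
#'   value) as produced by [simulate_f1_phenotypes()].
#' @param design a [cross_design()].
#' @param env environment id to derive for.
#' @param normalize if `TRUE`, each derived phenotype column (F1, BPaV, MPV,
#'   SCA) is independently rank-inverse-normal transformed.
#' @return list with `f1` (data.frame f1, maternal, paternal, trait, F1,
#'   BPaV, MPV, SCA) and `gca`.
#' @export
derive_heterosis <- function(traits, design, env = NULL, normalize = FALSE) {
  if (!is.null(env)) traits <- traits[traits$env == env, , drop = FALSE]
  if (length(unique(traits$env)) > 1L) stopf("multiple environments; pass `env`")
  agg <- stats::aggregate(value ~ sample + role + trait, traits, mean)
  out_f1 <- list(); out_gca <- list()
  for (tr in unique(agg$trait)) {
    a <- agg[agg$trait == tr, ]
    val <- stats::setNames(a$value, a$sample)
    f1v <- val[design$f1]
    patv <- val[design$paternal]
    matv <- val[design$maternal]
    cc <- gca_sca(stats::setNames(unname(f1v), design$f1), design)
    res <- data.frame(
      f1 = design$f1, maternal = design$maternal, paternal = design$paternal,
      trait = tr, F1 = unname(f1v), BPaV = unname(bpav(f1v, patv)),
      MPV = unname(mpv(f1v, patv, matv)),
      SCA = cc$sca$sca[match(design$f1, cc$sca$f1)],
      stringsAsFactors = FALSE
    )
    if (normalize) {
      for (col in c("F1", "BPaV", "MPV", "SCA")) {
        if (sum(!is.na(res[[col]])) >= 20L && stats::sd(res[[col]], na.rm = TRUE) > 0) {
          res[[col]] <- normalize_phenotype(res[[col]])
        }
      }
    }
    out_f1[[tr]] <- res
    g <- cc$gca; g$trait <- tr
    out_gca[[tr]] <- g
  }
  list(f1 = do.call(rbind, c(out_f1, list(make.row.names = FALSE))),
       gca = do.call(rbind, c(out_gca, list(make.row.names = FALSE))))
}
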