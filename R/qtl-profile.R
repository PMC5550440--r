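#' Genotype-class structure of a QTL in the F1 panel
#'
#' F1s are split by their call at the lead SNP. A QTL is `three_genotype`
#' only when all three classes (hom-major, het, hom-minor) each hold at least
#' `min_class_n` F1s with a non-missing call (default 15); otherwise it is
#' `two_genotype`. A locus with a single observed class is not a QTL.
#'
#' @param lead_calls integer vector of F1 calls (0/1/2, NA allowed) at the
#'   lead SNP.
#' @param min_class_n minimum class size (default 15).
#' @return list (class, counts) where counts is named c(`0`,`1`,`2`).
#' @export
genotype_class <- function(lead_calls, min_class_n = 15L) {
  if (min_class_n < 1L) stopf("min_class_n must be >= 1")
  counts <- table(factor(lead_calls, levels = 0:2))
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (sum(counts > 0L) < 2L) stopf("only one genotype class present: not a QTL")
  cls <- if (all(counts >= min_class_n)) "three_genotype" else "two_genotype"
  list(class = cls, counts = counts)
}

stuber_class <- function(d_over_a) {
  # round at 1e-9 so a ratio that is exactly a bin boundary up to floating
  # error lands in the printed bin
  r <- round(abs(d_over_a), 9)
  if (is.na(r)) return(NA_character_)
  if (r < 0.2) "additive"
  else if (r <= 0.8) "partial_dominance"
  else if (r <= 1.2) "dominance"
  else "overdominance"
}

#' Joint additive + dominance effects at a QTL
#'
#' Fits `y ~ covariates + x_add + x_dom` with `x_add` the 0/1/2 dosage and
#' `x_dom` the 0/1/0 heterozygote indicator, so `a` is half the homozygote
#' mean difference (minor homozygote high) and `d` the heterozygote deviation
#' from the homozygote midpoint. The degree of dominance is binned by the
#' Stuber criteria on `|d/a|`: additive `[0, 0.2)`, partial dominance
#' `[0.2, 0.8]`, dominance `(0.8, 1.2]`, overdominance `> 1.2`; the signed
#' ratio is reported alongside.
#'
#' @param y phenotype vector.
#' @param lead_calls F1 calls at the lead SNP (0/1/2).
#' @param covariates optional covariate matrix, typically the top 10 genomic
#'   PCs.
#' @return list (a, d, d_over_a, class, p_a, p_d, n).
#' @export
da_effects <- function(y, lead_calls, covariates = NULL) {
  ok <- !is.na(y) & !is.na(lead_calls)
  y <- y[ok]; g <- lead_calls[ok]
  if (length(unique(g)) < 3L) stopf("all three genotype classes are required to fit d and a")
  x_add <- as.numeric(g)
  x_dom <- as.numeric(g == 1L)
  X <- if (is.null(covariates)) NULL else as.matrix(covariates)[ok, , drop = FALSE]
  fit <- if (is.null(X)) stats::lm(y ~ x_add + x_dom) else stats::lm(y ~ X + x_add + x_dom)
  cf <- summary(fit)$coefficients
  a <- cf["x_add", "Estimate"]
  d <- cf["x_dom", "Estimate"]
  if (abs(a) < 1e-8) {
    p_d <- cf["x_dom", "Pr(>|t|)"]
    cls <- if (!is.na(p_d) && p_d < 0.05) "overdominance" else "unclassified"
    return(list(a = a, d = d, d_over_a = NA_real_, class = cls,
                p_a = cf["x_add", "Pr(>|t|)"], p_d = p_d, n = length(y)))
  }
  ratio <- d / a
  list(a = a, d = d, d_over_a = ratio, class = stuber_class(ratio),
       p_a = cf["x_add", "Pr(>|t|)"], p_d = cf["x_dom", "Pr(>|t|)"],
       n = length(y))
}

#' Heterozygote vs homozygote superiority at a two-genotype QTL
#'
#' Compares the mean phenotype of heterozygous F1s against the observed
#' homozygote class. `hetero_superior` when the heterozygote mean is on the
#' favorable side (`direction = "higher"` for yield-type traits, `"lower"`
#' for traits like heading date); an exact tie is called `homo_superior`
#' (conservative) and flagged.
#'
#' @param y phenotype vector.
#' @param lead_calls F1 calls at the lead SNP.
#' @param direction favorable direction, `"higher"` or `"lower"`.
#' @return list (class, het_mean, hom_mean, hom_call, tie).
#' @export
superiority_class <- function(y, lead_calls, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  ok <- !is.na(y) & !is.na(lead_calls)
  y <- y[ok]; g <- lead_calls[ok]
  if (!any(g == 1L)) stopf("no heterozygotes at this locus")
  hom_counts <- c(`0` = sum(g == 0L), `2` = sum(g == 2L))
  if (all(hom_counts == 0L)) stopf("no homozygote class at this locus")
  # under the minimum-class-size rule a handful of calls of the rarer
  # homozygote may remain; the comparison uses the dominant homozygote class
  homs <- if (hom_counts[["0"]] >= hom_counts[["2"]]) 0L else 2L
  het_mean <- mean(y[g == 1L])
  hom_mean <- mean(y[g == homs])
  delta <- het_mean - hom_mean
  if (direction == "lower") delta <- -delta
  tie <- delta == 0
  cls <- if (delta > 0) "hetero_superior" else "homo_superior"
  if (tie) warnf("exact tie between classes; calling homo_superior")
  list(class = cls, het_mean = het_mean, hom_mean = hom_mean,
       hom_call = as.integer(homs), tie = tie)
}

#' Phenotypic variance explained by QTL lead SNPs
#'
#' Single QTL: R-squared of the phenotype regressed on the lead-SNP dosage.
#' Multiple QTLs: the phenotype is first residualized on the top genomic PCs
#' (family effects), then AIC-based forward-backward selection over the lead
#' SNPs retains a non-redundant subset, and the joint R-squared on the
#' residualized phenotype is reported.
#'
#' @param y phenotype vector.
#' @param lead_geno matrix of lead-SNP dosages (samples x QTLs) or a vector
#'   for one QTL.
#' @param pc_covariates optional PC score matrix for the multi-QTL path.
#' @param multi if `TRUE`, run the multi-QTL AIC path.
#' @return single: a numeric R-squared. Multi: list (r_squared, kept).
#' @export
variance_explained <- function(y, lead_geno, pc_covariates = NULL, multi = FALSE) {
  G <- as.matrix(lead_geno)
  ok <- stats::complete.cases(y, G)
  y <- y[ok]; G <- G[ok, , drop = FALSE]
  if (length(y) < ncol(G) + 10L) stopf("too few samples (%d) for %d predictors", length(y), ncol(G))
  if (!multi) {
    if (ncol(G) != 1L) stopf("single-QTL mode expects one lead SNP")
    return(summary(stats::lm(y ~ G))$r.squared)
  }
  if (!is.null(pc_covariates)) {
    P <- as.matrix(pc_covariates)[ok, , drop = FALSE]
    y <- stats::resid(stats::lm(y ~ P))
  }
  dat <- data.frame(y = y, G)
  snp_names <- names(dat)[-1]
  full <- stats::lm(stats::reformulate(snp_names, "y"), data = dat)
  sel <- stats::step(stats::lm(y ~ 1, data = dat),
                     scope = list(lower = ~1, upper = stats::formula(full)),
                     direction = "both", trace = 0)
  kept <- attr(stats::terms(sel), "term.labels")
  list(r_squared = summary(sel)$r.squared, kept = kept)
}

#' Superior-allele provenance accounting at a QTL
#'
#' Given the superior allele (minor `"a"` or major `"A"`), measures its
#' frequency among maternal lines, paternal lines and F1 allele copies, and
#' assigns every F1 superior copy a parental origin (unambiguous with inbred
#' parents: the maternal copy is the maternal line's allele, the paternal
#' copy the paternal line's). Contribution source is `female_only` /
#' `male_only` / `both` according to which parental group carries any
#' superior copy.
#'
#' @param marker lead SNP id.
#' @param parental_geno parental `geno_matrix`.
#' @param groups named group labels (`"maternal"`/`"paternal"`) per parent.
#' @param design a [cross_design()].
#' @param superior_allele `"a"` (minor) or `"A"` (major).
#' @return list (superior_allele, freq_maternal, freq_paternal, freq_f1,
#'   source, maternal_derived_frac, n_superior_copies).
#' @export
superior_allele_accounting <- function(marker, parental_geno, groups, design,
                                       superior_allele = c("a", "A")) {
  superior_allele <- match.arg(superior_allele)
  j <- match(marker, parental_geno$map$marker)
  if (is.na(j)) stopf("marker %s not in parental genotypes", marker)
  calls <- parental_geno$calls[, j]
  if (any(calls == 1L, na.rm = TRUE)) warnf("residual heterozygous parental call(s) at %s excluded", marker)
  hap <- ifelse(calls == 1L, NA_integer_, calls %/% 2L)  # minor-allele carrier per line
  if (superior_allele == "A") hap <- 1L - hap
  g <- groups[names(calls)]
  freq_m <- mean(hap[g == "maternal"], na.rm = TRUE)
  freq_p <- mean(hap[g == "paternal"], na.rm = TRUE)
  if (is.nan(freq_m) || is.nan(freq_p)) stopf("empty parental group at %s", marker)
  if (freq_m == 0 && freq_p == 0) stopf("superior allele absent from both parental groups")
  mat_copy <- hap[design$maternal]
  pat_copy <- hap[design$paternal]
  n_sup <- sum(mat_copy, na.rm = TRUE) + sum(pat_copy, na.rm = TRUE)
  freq_f1 <- n_sup / (sum(!is.na(mat_copy)) + sum(!is.na(pat_copy)))
  source <- if (freq_m > 0 && freq_p > 0) "both"
            else if (freq_m > 0) "female_only" else "male_only"
  list(
    superior_allele = superior_allele,
    freq_maternal = freq_m, freq_paternal = freq_p, freq_f1 = freq_f1,
    source = source,
    maternal_derived_frac = if (n_sup > 0) sum(mat_copy, na.rm = TRUE) / n_sup else NA_real_,
    n_superior_copies = as.integer(n_sup)
  )
}

#' Full QTL profile for one lead SNP and phenotype
#'
#' Bundles [genotype_class()], [da_effects()] or [superiority_class()]
#' (depending on class), [variance_explained()] and
#' [superior_allele_accounting()] into the per-QTL report row.
#'
#' @param marker lead SNP id.
#' @param y named phenotype vector (names = F1 ids).
#' @param f1_geno F1 `geno_matrix`.
#' @param parental_geno parental `geno_matrix`.
#' @param groups parental group labels.
#' @param design a [cross_design()].
#' @param pc_covariates optional PC matrix for the d/a regression.
#' @param direction favorable phenotype direction.
#' @param min_class_n minimum class size for the three-genotype call.
#' @return one-row data.frame of QTL profile fields.
#' @export
qtl_profile <- function(marker, y, f1_geno, parental_geno, groups, design,
                        pc_covariates = NULL, direction = "higher",
                        min_class_n = 15L) {
  j <- match(marker, f1_geno$map$marker)
  if (is.na(j)) stopf("marker %s not in F1 genotypes", marker)
  calls <- f1_geno$calls[names(y), j]
  gc <- genotype_class(calls, min_class_n = min_class_n)
  a <- d <- ratio <- NA_real_
  stuber <- superiority <- NA_character_
  if (gc$class == "three_genotype") {
    de <- da_effects(y, calls, covariates = pc_covariates)
    a <- de$a; d <- de$d; ratio <- de$d_over_a; stuber <- de$class
    ok <- !is.na(y) & !is.na(calls)
    hi_minor <- mean(y[ok][calls[ok] == 2L]) >= mean(y[ok][calls[ok] == 0L])
    favorable_minor <- if (direction == "higher") hi_minor else !hi_minor
    superior <- if (favorable_minor) "a" else "A"
  } else {
    sup <- superiority_class(y, calls, direction = direction)
    superiority <- sup$class
    # hetero-superior: the allele absent from the observed homozygote class;
    # homo-superior: the allele of that homozygote class
    hom_minor <- sup$hom_call == 2L
    superior <- if (superiority == "hetero_superior") {
      if (hom_minor) "A" else "a"
    } else {
      if (hom_minor) "a" else "A"
    }
  }
  ve <- variance_explained(y, as.numeric(calls))
  acct <- superior_allele_accounting(marker, parental_geno, groups, design,
                                     superior_allele = superior)
  data.frame(
    marker = marker, class = gc$class,
    n_AA = gc$counts[["0"]], n_Aa = gc$counts[["1"]], n_aa = gc$counts[["2"]],
    a = a, d = d, d_over_a = ratio, stuber_class = stuber,
    superiority = superiority, variance_explained = ve,
    superior_allele = acct$superior_allele,
    superior_freq_maternal = acct$freq_maternal,
    superior_freq_paternal = acct$freq_paternal,
    superior_freq_f1 = acct$freq_f1, contribution_source = acct$source,
    maternal_derived_frac = acct$maternal_derived_frac,
    stringsAsFactors = FALSE
  )
}
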