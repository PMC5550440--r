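#' Simulation configuration for a partial-diallel hybrid population
#'
#' Defaults mirror the structure of a two-line hybrid rice diallel: 14
#' male-sterile (maternal) lines drawn from a narrow founder pool, 3
#' recombinant-inbred (RIL) paternal families of 13 restorer lines each
#' (39 paternal lines, 546 F1s), and ~27k biallelic markers spread evenly
#' over 12 chromosomes of 30 Mb.
#'
#' @param n_maternal number of maternal (male-sterile) lines.
#' @param n_paternal_families number of paternal RIL families.
#' @param lines_per_family lines per paternal family (recycled to
#'   `n_paternal_families`).
#' @param n_chromosomes,markers_per_chromosome,chrom_length genome layout;
#'   `chrom_length` in bp.
#' @param qtl_specs list of [qtl_spec()] entries.
#' @param h2_polygenic fraction of trait variance assigned to a kinship-driven
#'   polygenic term (in `[0, 1)`).
#' @param residual_sd per-replicate residual standard deviation (trait units).
#' @param n_replicates plot replicates per line.
#' @param crossovers_per_chrom mean crossovers per chromosome in one collapsed
#'   mosaic draw (Poisson); inbred-line mosaics absorb several selfing
#'   generations into a single draw.
#' @param n_maternal_founders size of the maternal founder haplotype pool.
#' @param maternal_divergence standard deviation of the logit-scale shift
#'   applied to maternal founder allele frequencies. The shift is directed
#'   toward the nearer allele-frequency extreme, emulating the intense
#'   selection and narrow ancestry of male-sterile pools: it creates elevated
#'   between-group divergence while driving maternal minor-allele frequencies
#'   down, which keeps expected F1 heterozygosity near the 17-28% range seen
#'   in two-line hybrid panels.
#' @param sweep_bp half-width (bp) of the swept tract laid down around a QTL
#'   with `fixed_in != "none"`: within it the fixed group keeps only
#'   low-frequency escape variation, the hitchhiking footprint of a selective
#'   sweep.
#' @param sweep_escape per-call probability that a tract site keeps its
#'   pre-sweep allele (residual low-frequency variation).
#' @param seed integer master seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_maternal = 14L,
                       n_paternal_families = 3L,
                       lines_per_family = 13L,
                       n_chromosomes = 12L,
                       markers_per_chromosome = 2240L,
                       chrom_length = 30e6,
                       qtl_specs = list(),
                       h2_polygenic = 0.3,
                       residual_sd = 1,
                       n_replicates = 3L,
                       crossovers_per_chrom = 2,
                       n_maternal_founders = 3L,
                       maternal_divergence = 2,
                       sweep_bp = 150e3,
                       sweep_escape = 0.08,
                       seed = 1L) {
  lines_per_family <- rep_len(as.integer(lines_per_family), n_paternal_families)
  if (n_maternal < 1L || n_paternal_families < 1L || any(lines_per_family < 1L)) {
    stopf("configuration error: at least one line per group is required")
  }
  if (n_chromosomes < 1L || markers_per_chromosome < 1L) {
    stopf("configuration error: zero markers")
  }
  assert_fraction(h2_polygenic, "h2_polygenic")
  if (h2_polygenic >= 1) stopf("h2_polygenic must be < 1")
  cfg <- list(
    n_maternal = as.integer(n_maternal),
    n_paternal_families = as.integer(n_paternal_families),
    lines_per_family = lines_per_family,
    n_chromosomes = as.integer(n_chromosomes),
    markers_per_chromosome = as.integer(markers_per_chromosome),
    chrom_length = chrom_length,
    qtl_specs = qtl_specs,
    h2_polygenic = h2_polygenic,
    residual_sd = residual_sd,
    n_replicates = as.integer(n_replicates),
    crossovers_per_chrom = crossovers_per_chrom,
    n_maternal_founders = as.integer(n_maternal_founders),
    maternal_divergence = maternal_divergence,
    sweep_bp = sweep_bp,
    sweep_escape = sweep_escape,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' QTL specification for the simulator
#'
#' Effects follow the standard F2 parametrization on minor-allele dosage
#' `x` in \{0, 1, 2\}: genetic value `a * x + d * [x == 1]`, so `a` is half
#' the difference between homozygote means and `d` the heterozygote deviation
#' from the homozygote midpoint. `a >= 0` by convention (the sign lives in
#' the allele labels).
#'
#' @param chromosome chromosome index (1-based).
#' @param position bp position; snapped to the nearest marker with a warning
#'   if no marker sits exactly there.
#' @param a additive effect (trait units, `>= 0`).
#' @param d dominance effect (trait units, any sign).
#' @param fixed_in `"none"`, `"maternal"` or `"paternal"`: force one parental
#'   group to be monomorphic (homozygous major) at the locus.
#' @param freq founder minor-allele frequency at the locus in the
#'   non-fixed group(s).
#' @return a list of class `qtl_spec`.
#' @export
qtl_spec <- function(chromosome, position, a = 0, d = 0,
                     fixed_in = c("none", "maternal", "paternal"), freq = 0.5) {
  if (a < 0) stopf("`a` must be >= 0; absorb the sign into allele labels")
  fixed_in <- match.arg(fixed_in)
  structure(list(chromosome = as.integer(chromosome), position = position,
                 a = a, d = d, fixed_in = fixed_in, freq = freq),
            class = "qtl_spec")
}

#' Full-factorial cross design for a simulated diallel
#'
#' @param maternal_ids,paternal_ids parental line ids.
#' @param families family label per paternal line.
#' @return a [cross_design()] with one F1 per (maternal, paternal) pair.
#' @export
make_cross_design <- function(maternal_ids, paternal_ids, families) {
  grid <- expand.grid(maternal = maternal_ids, paternal = paternal_ids,
                      stringsAsFactors = FALSE)
  fam <- families[match(grid$paternal, paternal_ids)]
  cross_design(
    f1 = paste0("F1_", grid$maternal, "_x_", grid$paternal),
    maternal = grid$maternal, paternal = grid$paternal, family = fam
  )
}

# one inbred mosaic chromosome: founder haplotypes (rows) recombined by a
# Poisson crossover process; returns founder index per marker
mosaic_chrom <- function(n_markers, pos, chrom_len, founders, rate) {
  n_x <- stats::rpois(1L, rate)
  breaks <- sort(stats::runif(n_x, 0, chrom_len))
  seg <- findInterval(pos, breaks) + 1L
  pick <- sample(founders, n_x + 1L, replace = TRUE)
  pick[seg]
}

#' Simulate inbred parental genotypes for a partial diallel
#'
#' Paternal lines form `n_paternal_families` RIL families, each a recombinant
#' mosaic of two family-specific founder haplotypes. Maternal lines are
#' mosaics over a small shared founder pool whose allele frequencies are
#' shifted on the logit scale relative to the paternal founders, giving the
#' two groups the elevated divergence typical of male-sterile vs restorer
#' breeding pools. All parents are fully homozygous. Founder minor-allele
#' frequencies are Beta(0.5, 0.5) truncated to [0.05, 0.95].
#'
#' @param config a [sim_config()].
#' @return list with `geno` (parental [geno_matrix()]), `groups` (named
#'   vector, `"maternal"`/`"paternal"`), `families` (named vector, RIL family
#'   of each paternal line), `design` (full-factorial [cross_design()]) and
#'   `qtl_markers` (marker id per QTL spec).
#' @export
simulate_parents <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 1L), {
    n_chr <- config$n_chromosomes
    m_chr <- config$markers_per_chromosome
    map <- do.call(rbind, lapply(seq_len(n_chr), function(cc) {
      pos <- sort(sample.int(config$chrom_length, m_chr))
      data.frame(marker = sprintf("S%02d_%07d", cc, pos),
                 chrom = as.character(cc), pos = pos)
    }))
    M <- nrow(map)

    # founder allele frequencies
    fr <- stats::rbeta(M, 0.5, 0.5)
    fr <- pmin(pmax(fr, 0.05), 0.95)
    shift <- abs(stats::rnorm(M, 0, config$maternal_divergence))
    toward_extreme <- ifelse(fr < 0.5, -1, 1)
    fr_mat <- stats::plogis(stats::qlogis(fr) + toward_extreme * shift)

    qtl_idx <- integer(length(config$qtl_specs))
    for (q in seq_along(config$qtl_specs)) {
      qs <- config$qtl_specs[[q]]
      on_chr <- which(map$chrom == as.character(qs$chromosome))
      if (length(on_chr) == 0L) stopf("QTL %d: no markers on chromosome %s", q, qs$chromosome)
      j <- on_chr[which.min(abs(map$pos[on_chr] - qs$position))]
      if (map$pos[j] != qs$position) {
        warnf("QTL %d: no marker at %s:%d; using nearest marker %s",
              q, qs$chromosome, as.integer(qs$position), map$marker[j])
      }
      qtl_idx[q] <- j
    }

    # paternal founders: 2 haplotypes per family at paternal frequencies
    pat_ids <- character(0); pat_fam <- character(0)
    hap_rows <- list()
    chr_index <- split(seq_len(M), map$chrom)[unique(map$chrom)]
    for (f in seq_len(config$n_paternal_families)) {
      fam_name <- paste0("FAM", f)
      founders <- matrix(stats::rbinom(2L * M, 1L, rep(fr, each = 2L)), nrow = 2L)
      # QTLs are planted to segregate within every non-fixed paternal family
      # (the two RIL founders carry opposite alleles); a randomly drawn QTL
      # frequency would confound the locus with family structure and make
      # engine power a lottery over founder draws rather than a property of
      # the method
      for (q in seq_along(config$qtl_specs)) {
        founders[, qtl_idx[q]] <-
          if (config$qtl_specs[[q]]$fixed_in == "paternal") c(0L, 0L) else c(0L, 1L)
      }
      for (l in seq_len(config$lines_per_family[f])) {
        hap <- integer(M)
        for (ci in seq_along(chr_index)) {
          idx <- chr_index[[ci]]
          pick <- mosaic_chrom(length(idx), map$pos[idx], config$chrom_length,
                               1:2, config$crossovers_per_chrom)
          hap[idx] <- founders[cbind(pick, idx)]
        }
        id <- sprintf("P%d_%02d", f, l)
        pat_ids <- c(pat_ids, id); pat_fam <- c(pat_fam, fam_name)
        hap_rows[[id]] <- hap
      }
    }

    # maternal founder pool at shifted frequencies
    nf <- config$n_maternal_founders
    mat_founders <- matrix(stats::rbinom(nf * M, 1L, rep(fr_mat, each = nf)), nrow = nf)
    for (q in seq_along(config$qtl_specs)) {
      qs <- config$qtl_specs[[q]]
      if (qs$fixed_in == "maternal") {
        mat_founders[, qtl_idx[q]] <- 0L
      } else {
        # deterministic carrier count keeps the locus polymorphic in the
        # maternal pool at approximately `freq`
        k <- min(max(round(qs$freq * nf), 1L), nf - 1L)
        mat_founders[, qtl_idx[q]] <- rep(c(1L, 0L), c(k, nf - k))
      }
    }
    mat_ids <- sprintf("M%02d", seq_len(config$n_maternal))
    for (id in mat_ids) {
      hap <- integer(M)
      for (ci in seq_along(chr_index)) {
        idx <- chr_index[[ci]]
        pick <- mosaic_chrom(length(idx), map$pos[idx], config$chrom_length,
                             seq_len(nf), config$crossovers_per_chrom)
        hap[idx] <- mat_founders[cbind(pick, idx)]
      }
      hap_rows[[id]] <- hap
    }

    calls <- 2L * do.call(rbind, hap_rows)  # inbred: dosage twice the haplotype
    # enforce fixation exactly (mosaic draws already honour founder fixation)
    # and lay down the post-sweep pattern around a fixed locus: the swept
    # group keeps only low-frequency escape variation in a tract around the
    # locus, the footprint a selective sweep leaves (and what a Tajima's D
    # scan is meant to detect)
    for (q in seq_along(config$qtl_specs)) {
      qs <- config$qtl_specs[[q]]
      if (qs$fixed_in == "none") next
      ids <- if (qs$fixed_in == "maternal") mat_ids else pat_ids
      j <- qtl_idx[q]
      calls[ids, j] <- 0L
      tract <- which(map$chrom == map$chrom[j] &
                       abs(map$pos - map$pos[j]) <= config$sweep_bp)
      tract <- setdiff(tract, j)
      if (length(tract) > 0) {
        orig <- calls[ids, tract, drop = FALSE]
        keep <- matrix(stats::runif(length(orig)) < config$sweep_escape,
                       nrow(orig), ncol(orig))
        calls[ids, tract] <- ifelse(keep, orig, 0L)
      }
    }
    geno <- geno_matrix(calls, map)
    groups <- stats::setNames(
      c(rep("paternal", length(pat_ids)), rep("maternal", length(mat_ids))),
      c(pat_ids, mat_ids)
    )
    families <- stats::setNames(pat_fam, pat_ids)
    design <- make_cross_design(mat_ids, pat_ids, pat_fam)
    # marker order may change inside geno_matrix (positions sorted); remap
    qtl_markers <- map$marker[qtl_idx]
    list(geno = geno, groups = groups, families = families, design = design,
         qtl_markers = qtl_markers)
  })
}

#' Simulate F1 (and parental) phenotypes for one trait
#'
#' Phenotype model per individual: `mu + sum_q a_q * x_q + d_q * [x_q == 1]`
#' plus a polygenic term drawn from `N(0, sigma_g^2 K)` on the F1 kinship
#' (variance set by `h2_polygenic` relative to total variance) and an
#' independent `N(0, residual_sd^2)` draw per replicate. Parental phenotypes
#' come from the same model (no heterozygotes, so no dominance deviations;
#' polygenic term drawn on the parental kinship).
#'
#' @param parents output of [simulate_parents()].
#' @param config the same [sim_config()].
#' @param trait trait name used in the output table.
#' @param mu grand mean.
#' @return list with `traits` (long-format data.frame: sample, role, env,
#'   rep, trait, value), `f1_geno` (F1 [geno_matrix()]) and `truth` (ground
#'   truth: per-QTL marker, a, d, d/a, expected class means, per-sample
#'   genetic values).
#' @export
simulate_f1_phenotypes <- function(parents, config, trait = "trait", mu = 0) {
  f1_geno <- combine_f1(parents$geno, parents$design)
  qtl <- config$qtl_specs
  qidx <- match(parents$qtl_markers, f1_geno$map$marker)

  genetic_value <- function(calls) {
    gv <- rep(mu, nrow(calls))
    for (q in seq_along(qtl)) {
      x <- calls[, qidx[q]]
      gv <- gv + qtl[[q]]$a * x + qtl[[q]]$d * (x == 1L)
    }
    gv
  }

  with_seed(child_seed(config$seed, 2L), {
    gv_f1 <- genetic_value(f1_geno$calls)
    gv_par <- genetic_value(parents$geno$calls)
    sg2 <- 0
    if (config$h2_polygenic > 0) {
      base_var <- stats::var(gv_f1) + config$residual_sd^2
      sg2 <- config$h2_polygenic / (1 - config$h2_polygenic) * max(base_var, 1e-12)
      Kf <- kinship(f1_geno)
      Kp <- kinship(parents$geno)
      gv_f1 <- gv_f1 + drop(crossprod(chol_psd(Kf), stats::rnorm(nrow(Kf)))) * sqrt(sg2)
      gv_par <- gv_par + drop(crossprod(chol_psd(Kp), stats::rnorm(nrow(Kp)))) * sqrt(sg2)
    }
    nrep <- config$n_replicates
    make_rows <- function(ids, gv, role) {
      do.call(rbind, lapply(seq_len(nrep), function(r) {
        data.frame(sample = ids, role = role, env = "E1", rep = r, trait = trait,
                   value = gv + stats::rnorm(length(gv), 0, config$residual_sd),
                   stringsAsFactors = FALSE)
      }))
    }
    roles <- ifelse(parents$groups[sample_ids(parents$geno)] == "maternal",
                    "maternal", "paternal")
    traits <- rbind(
      make_rows(sample_ids(f1_geno), gv_f1, "F1"),
      make_rows(sample_ids(parents$geno), gv_par, roles)
    )
    truth <- list(
      qtl = data.frame(
        marker = parents$qtl_markers,
        chrom = f1_geno$map$chrom[qidx], pos = f1_geno$map$pos[qidx],
        a = vapply(qtl, `[[`, numeric(1), "a"),
        d = vapply(qtl, `[[`, numeric(1), "d"),
        d_over_a = vapply(qtl, function(q) if (q$a == 0) NA_real_ else q$d / q$a, numeric(1)),
        fixed_in = vapply(qtl, `[[`, character(1), "fixed_in"),
        stringsAsFactors = FALSE
      ),
      genetic_values_f1 = stats::setNames(gv_f1, sample_ids(f1_geno)),
      sigma_g2 = sg2, seed = config$seed
    )
    list(traits = traits, f1_geno = f1_geno, truth = truth)
  })
}

# upper-triangular factor of a PSD matrix, tolerating tiny negative eigenvalues
chol_psd <- function(K) {
  out <- tryCatch(chol(K), error = function(e) NULL)
  if (!is.null(out)) return(out)
  ev <- eigen(K, symmetric = TRUE)
  chol(ev$vectors %*% (pmax(ev$values, 1e-8) * t(ev$vectors)))
}

#' Simulate a complete diallel dataset in one call
#'
#' Convenience wrapper: [simulate_parents()] then [simulate_f1_phenotypes()].
#'
#' @inheritParams simulate_f1_phenotypes
#' @param config a [sim_config()].
#' @return list with `parents`, `f1_geno`, `traits`, `truth`, `design`,
#'   `groups`, `families`.
#' @export
simulate_diallel <- function(config, trait = "trait", mu = 0) {
  parents <- simulate_parents(config)
  ph <- simulate_f1_phenotypes(parents, config, trait = trait, mu = mu)
  list(parents = parents$geno, f1_geno = ph$f1_geno, traits = ph$traits,
       truth = ph$truth, design = parents$design, groups = parents$groups,
       families = parents$families, qtl_markers = parents$qtl_markers)
}

#' Write a simulated dataset to disk
#'
#' Genotypes as PED/MAP and plain-text VCF, phenotypes as TSV, ground truth
#' as JSON.
#'
#' @param sim output of [simulate_diallel()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ped_map(sim$parents, file.path(dir, "parents"))
  write_vcf_geno(sim$parents, file.path(dir, "parents.vcf"))
  write_vcf_geno(sim$f1_geno, file.path(dir, "f1.vcf"))
  utils::write.table(sim$traits, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(sim$design), file.path(dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$genetic_values_f1 <- as.list(truth$genetic_values_f1)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
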