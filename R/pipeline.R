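#' Default pipeline configuration
#'
#' Assembles the full configuration for [run_pipeline()]: simulator settings
#' (a [sim_config()]), QC thresholds (missing rate 0.2, heterozygous rate
#' 0.15, MAF 0.05), GWAS engine settings (four inheritance codings, 300
#' resamples at 80%, 300 permutations at FDR 0.05, RMIP threshold 5, 800-kb /
#' r-squared 0.2 signal merging) and the selection-scan layout (240-kb
#' windows, 20-kb step, 10th percentile). Every entry can be overridden.
#'
#' @param sim a [sim_config()].
#' @param seed master seed; every stage derives its own child seeds from it.
#' @param categories GWAS phenotype categories to run.
#' @param ... overrides for qc/gwas/scan entries (see defaults in the source).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), seed = sim$seed,
                            categories = c("F1", "BPaV", "SCA"), ...) {
  cfg <- list(
    sim = sim, seed = as.integer(seed), categories = categories,
    qc = list(max_missing = 0.2, max_het = 0.15, min_maf = 0.05),
    gwas = list(models = c("additive", "dominance", "recessive", "overdominance"),
                n_resamples = 300L, subsample_frac = 0.8, n_perm = 300L,
                fdr = 0.05, rmip_threshold = 5, max_steps = 20L,
                merge_distance = 8e5, merge_min_r2 = 0.2, normalize = TRUE),
    scan = list(window = 240e3, step = 20e3, percentile = 10),
    characterize = list(min_class_n = 15L, direction = "higher", n_pcs = 10L)
  )
  dots <- list(...)
  for (section in intersect(names(dots), names(cfg))) {
    cfg[[section]] <- utils::modifyList(cfg[[section]], dots[[section]])
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror [pipeline_config()]
#'   sections (`sim`, `seed`, `categories`, `qc`, `gwas`, `scan`,
#'   `characterize`).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$qtl_specs)) {
    sim_args$qtl_specs <- lapply(sim_args$qtl_specs, function(q) do.call(qtl_spec, q))
  }
  sim <- do.call(sim_config, sim_args)
  extra <- y[setdiff(names(y), c("sim", "seed", "categories"))]
  do.call(pipeline_config, c(
    list(sim = sim, seed = y$seed %||% sim$seed,
         categories = y$categories %||% c("F1", "BPaV", "SCA")),
    extra
  ))
}

stage_paths <- function(out_dir) list(
  sim = file.path(out_dir, "01_sim"),
  qc = file.path(out_dir, "02_qc"),
  derive = file.path(out_dir, "03_derive"),
  gwas = file.path(out_dir, "04_gwas"),
  characterize = file.path(out_dir, "05_characterize"),
  scan = file.path(out_dir, "06_scan"),
  report = file.path(out_dir, "report.tsv"),
  manifest = file.path(out_dir, "manifest.json")
)

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

log_stage <- function(stage, seed, msg, quiet) {
  if (!quiet) message(sprintf("[%s] seed=%d %s", stage, seed, msg))
}

#' Run the full heterosis-dissection pipeline
#'
#' Stages, in dependency order: `simulate` (diallel population with known
#' QTLs) -> `qc` (marker filters, polymorphism on parents, F1 assembly, MAF
#' filter) -> `derive` (replicate averaging, BPaV/MPV/SCA/GCA) -> `gwas`
#' (resampling RMIP scan per category, signal merging) -> `characterize`
#' (QTL profiles, hapblock intervals) -> `scan` (Tajima's D per parental
#' group, low-D regions, QTL overlap) -> `report`. Each stage writes its
#' outputs under a numbered directory in `out_dir`; with `resume = TRUE`
#' stages whose outputs already exist are reloaded instead of recomputed,
#' and a deleted intermediate is rebuilt from the stages before it. All
#' randomness derives from `config$seed`, so a rerun reproduces every output
#' bit-identically.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @param out_dir output directory.
#' @param resume reuse existing stage outputs (default TRUE).
#' @param quiet suppress per-stage log lines.
#' @return list with the run manifest and in-memory results of every stage.
#' @export
run_pipeline <- function(config, out_dir, resume = TRUE, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- stage_paths(out_dir)
  seed <- config$seed
  t_start <- Sys.time()

  run_stage <- function(name, outputs, compute, load) {
    done <- resume && all(file.exists(outputs))
    t0 <- Sys.time()
    if (done) {
      log_stage(name, seed, "resumed from disk", quiet)
      return(load())
    }
    tryCatch(compute(), error = function(e) {
      sums <- tools::md5sum(Filter(file.exists, outputs))
      stopf("stage '%s' failed: %s (inputs: %s)", name, conditionMessage(e),
            paste(names(sums), sums, sep = "=", collapse = "; "))
    })
    log_stage(name, seed, sprintf("done in %.1fs", as.numeric(Sys.time() - t0, units = "secs")), quiet)
    # downstream stages always consume what is on disk, so a resumed run sees
    # exactly the same inputs (including text-roundtrip precision) as this one
    load()
  }

  # -- simulate ---------------------------------------------------------------
  sim_files <- file.path(pth$sim, c("parents.ped", "parents.map", "f1.ped",
                                    "f1.map", "phenotypes.tsv", "design.tsv",
                                    "ground_truth.json"))
  sim <- run_stage("simulate", sim_files, compute = function() {
    s <- simulate_diallel(config$sim)
    dir.create(pth$sim, showWarnings = FALSE, recursive = TRUE)
    write_ped_map(s$parents, file.path(pth$sim, "parents"))
    write_ped_map(s$f1_geno, file.path(pth$sim, "f1"))
    write_vcf_geno(s$parents, file.path(pth$sim, "parents.vcf"))
    write_tsv(s$traits, file.path(pth$sim, "phenotypes.tsv"))
    write_tsv(cbind(as.data.frame(s$design),
                    group_maternal = "maternal", group_paternal = "paternal"),
              file.path(pth$sim, "design.tsv"))
    truth <- s$truth
    truth$genetic_values_f1 <- NULL
    jsonlite::write_json(c(truth, list(qtl_markers = s$qtl_markers)),
                         file.path(pth$sim, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    s
  }, load = function() {
    parents <- read_ped_map(file.path(pth$sim, "parents"))
    d <- utils::read.table(file.path(pth$sim, "design.tsv"), header = TRUE,
                           sep = "\t", colClasses = "character")
    design <- cross_design(d$f1, d$maternal, d$paternal, d$family)
    gt <- jsonlite::read_json(file.path(pth$sim, "ground_truth.json"),
                              simplifyVector = TRUE)
    gt$qtl <- as.data.frame(gt$qtl, stringsAsFactors = FALSE)
    groups <- stats::setNames(
      ifelse(sample_ids(parents) %in% design$maternal, "maternal", "paternal"),
      sample_ids(parents))
    list(parents = parents,
         f1_geno = read_ped_map(file.path(pth$sim, "f1")),
         traits = utils::read.table(file.path(pth$sim, "phenotypes.tsv"),
                                    header = TRUE, sep = "\t"),
         design = design, groups = groups,
         truth = gt, qtl_markers = gt$qtl_markers)
  })

  # -- qc ----------------------------------------------------------------------
  qc_files <- file.path(pth$qc, c("parents_qc.ped", "parents_qc.map",
                                  "f1_qc.ped", "f1_qc.map", "qc_counts.json"))
  qc <- run_stage("qc", qc_files, compute = function() {
    dir.create(pth$qc, showWarnings = FALSE, recursive = TRUE)
    par_f <- filter_markers(sim$parents, config$qc$max_missing, config$qc$max_het)
    counts <- attr(par_f, "filter_counts")
    par_f <- polymorphic_filter(par_f)
    if (anyNA(par_f$calls)) par_f <- knn_impute(par_f)
    f1 <- combine_f1(par_f, sim$design)
    f1 <- maf_filter(f1, config$qc$min_maf)
    par_f <- geno_subset(par_f, markers = f1$map$marker)
    write_ped_map(par_f, file.path(pth$qc, "parents_qc"))
    write_ped_map(f1, file.path(pth$qc, "f1_qc"))
    jsonlite::write_json(
      list(removed_missing = counts[["removed_missing"]],
           removed_het = counts[["removed_het"]],
           n_markers_final = ncol(f1$calls)),
      file.path(pth$qc, "qc_counts.json"), auto_unbox = TRUE)
    list(parents = par_f, f1 = f1)
  }, load = function() {
    list(parents = read_ped_map(file.path(pth$qc, "parents_qc")),
         f1 = read_ped_map(file.path(pth$qc, "f1_qc")))
  })

  # -- derive ------------------------------------------------------------------
  derive_files <- file.path(pth$derive, c("derived.tsv", "gca.tsv"))
  derived <- run_stage("derive", derive_files, compute = function() {
    dir.create(pth$derive, showWarnings = FALSE, recursive = TRUE)
    d <- derive_heterosis(sim$traits, sim$design, env = "E1",
                          normalize = FALSE)
    write_tsv(d$f1, file.path(pth$derive, "derived.tsv"))
    write_tsv(d$gca, file.path(pth$derive, "gca.tsv"))
    d
  }, load = function() {
    list(f1 = utils::read.table(file.path(pth$derive, "derived.tsv"),
                                header = TRUE, sep = "\t"),
         gca = utils::read.table(file.path(pth$derive, "gca.tsv"),
                                 header = TRUE, sep = "\t"))
  })

  # -- gwas --------------------------------------------------------------------
  gwas_files <- c(file.path(pth$gwas, paste0("rmip_", config$categories, ".tsv")),
                  file.path(pth$gwas, "signals.tsv"),
                  file.path(pth$gwas, "signals.bed"),
                  file.path(pth$gwas, "run_settings.json"))
  gwas <- run_stage("gwas", gwas_files, compute = function() {
    dir.create(pth$gwas, showWarnings = FALSE, recursive = TRUE)
    f1 <- qc$f1
    K <- kinship(f1)
    signals_all <- list()
    thresholds <- list()
    results <- list()
    for (cat in config$categories) {
      df <- derived$f1[derived$f1$trait == derived$f1$trait[1], ]
      y <- stats::setNames(df[[cat]], df$f1)
      y <- y[sample_ids(f1)]
      keep <- !is.na(y)
      yv <- y[keep]
      if (config$gwas$normalize) yv <- normalize_phenotype(yv)
      gsub <- geno_subset(f1, samples = which(keep))
      Ksub <- K[keep, keep]
      res <- resample_rmip(
        yv, gsub, Ksub, models = config$gwas$models,
        n_resamples = config$gwas$n_resamples,
        subsample_frac = config$gwas$subsample_frac,
        n_perm = config$gwas$n_perm, fdr = config$gwas$fdr,
        rmip_threshold = config$gwas$rmip_threshold,
        max_steps = config$gwas$max_steps,
        seed = child_seed(seed, match(cat, config$categories) * 101L)
      )
      write_tsv(res$rmip, file.path(pth$gwas, paste0("rmip_", cat, ".tsv")))
      sg <- merge_signals(res$selected, gsub,
                          max_distance = config$gwas$merge_distance,
                          min_r2 = config$gwas$merge_min_r2)
      if (nrow(sg) > 0) sg <- cbind(category = cat, sg)
      signals_all[[cat]] <- sg
      thresholds[[cat]] <- res$threshold
      results[[cat]] <- res
    }
    signals <- do.call(rbind, signals_all[vapply(signals_all, nrow, 1L) > 0])
    if (is.null(signals)) {
      signals <- data.frame(category = character(0), signal = integer(0),
                            chrom = character(0), start = integer(0),
                            end = integer(0), lead_marker = character(0),
                            lead_pos = integer(0), lead_rmip = numeric(0),
                            n_members = integer(0), members = character(0))
    }
    rownames(signals) <- NULL
    write_tsv(signals, file.path(pth$gwas, "signals.tsv"))
    bed <- signals[, c("chrom", "start", "end", "lead_marker")]
    bed$start <- pmax(bed$start - 1L, 0L)   # BED is 0-based half-open
    utils::write.table(bed, file.path(pth$gwas, "signals.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(list(thresholds = thresholds,
                              settings = config$gwas),
                         file.path(pth$gwas, "run_settings.json"),
                         auto_unbox = TRUE, digits = NA)
    list(signals = signals, thresholds = thresholds, results = results)
  }, load = function() {
    sg <- utils::read.table(file.path(pth$gwas, "signals.tsv"), header = TRUE,
                            sep = "\t", colClasses = list(chrom = "character"))
    list(signals = sg,
         thresholds = jsonlite::read_json(
           file.path(pth$gwas, "run_settings.json"), simplifyVector = TRUE)$thresholds,
         results = NULL)
  })

  # -- characterize ------------------------------------------------------------
  chr_files <- file.path(pth$characterize, c("qtl_report.tsv", "qtl.bed"))
  qtls <- run_stage("characterize", chr_files, compute = function() {
    dir.create(pth$characterize, showWarnings = FALSE, recursive = TRUE)
    sg <- gwas$signals
    rows <- list()
    if (nrow(sg) > 0) {
      pcs <- geno_pca(qc$f1, n_components = config$characterize$n_pcs)
      df <- derived$f1[derived$f1$trait == derived$f1$trait[1], ]
      for (i in seq_len(nrow(sg))) {
        cat <- sg$category[i]
        y <- stats::setNames(df[[cat]], df$f1)
        y <- y[!is.na(y)]
        prof <- qtl_profile(
          sg$lead_marker[i], y, qc$f1, qc$parents, sim$groups, sim$design,
          pc_covariates = pcs[names(y), , drop = FALSE],
          direction = config$characterize$direction,
          min_class_n = config$characterize$min_class_n
        )
        hb <- hapblock_interval(sg$lead_marker[i], qc$parents)
        rows[[i]] <- cbind(category = cat, signal = sg$signal[i], prof,
                           qtl_chrom = hb$chrom, qtl_start = hb$start,
                           qtl_end = hb$end, hapblock_degenerate = hb$degenerate)
      }
    }
    rep_df <- if (length(rows) > 0) do.call(rbind, rows) else data.frame()
    write_tsv(rep_df, file.path(pth$characterize, "qtl_report.tsv"))
    if (nrow(rep_df) > 0) {
      bed <- data.frame(rep_df$qtl_chrom, pmax(rep_df$qtl_start - 1L, 0L),
                        rep_df$qtl_end, rep_df$marker)
    } else bed <- data.frame()
    utils::write.table(bed, file.path(pth$characterize, "qtl.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    rep_df
  }, load = function() {
    p <- file.path(pth$characterize, "qtl_report.tsv")
    if (file.size(p) > 1) {
      utils::read.table(p, header = TRUE, sep = "\t",
                        colClasses = list(qtl_chrom = "character"))
    } else data.frame()
  })

  # -- scan --------------------------------------------------------------------
  scan_files <- file.path(pth$scan, c("tajima_maternal.tsv", "tajima_paternal.tsv",
                                      "low_d_regions.tsv"))
  scan <- run_stage("scan", scan_files, compute = function() {
    dir.create(pth$scan, showWarnings = FALSE, recursive = TRUE)
    scans <- lapply(c("maternal", "paternal"), function(g) {
      ids <- names(sim$groups)[sim$groups == g]
      tajimas_d_scan(geno_subset(qc$parents, samples = ids),
                     window = config$scan$window, step = config$scan$step,
                     group = g)
    })
    write_tsv(scans[[1]], file.path(pth$scan, "tajima_maternal.tsv"))
    write_tsv(scans[[2]], file.path(pth$scan, "tajima_paternal.tsv"))
    regions <- do.call(rbind, lapply(scans, low_d_regions,
                                     percentile = config$scan$percentile))
    write_tsv(regions, file.path(pth$scan, "low_d_regions.tsv"))
    list(scans = scans, regions = regions)
  }, load = function() {
    list(scans = list(
      utils::read.table(file.path(pth$scan, "tajima_maternal.tsv"), header = TRUE,
                        sep = "\t", colClasses = list(chrom = "character")),
      utils::read.table(file.path(pth$scan, "tajima_paternal.tsv"), header = TRUE,
                        sep = "\t", colClasses = list(chrom = "character"))),
      regions = utils::read.table(file.path(pth$scan, "low_d_regions.tsv"),
                                  header = TRUE, sep = "\t",
                                  colClasses = list(chrom = "character")))
  })

  # -- report ------------------------------------------------------------------
  rep <- pipeline_report(qtls, scan$regions)
  write_tsv(rep, pth$report)

  out_files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  out_files <- setdiff(out_files, pth$manifest)
  manifest <- list(
    package_version = as.character(utils::packageVersion("hetgwas")),
    seed = seed,
    config = unclass_deep(config),
    thresholds = gwas$thresholds,
    checksums = as.list(tools::md5sum(sort(out_files))),
    elapsed_s = round(as.numeric(Sys.time() - t_start, units = "secs"), 2)
  )
  jsonlite::write_json(manifest, pth$manifest, auto_unbox = TRUE, digits = NA)
  log_stage("run", seed, sprintf("complete; %d output file(s)", length(out_files)), quiet)
  invisible(list(manifest = manifest, sim = sim, qc = qc, derived = derived,
                 gwas = gwas, qtls = qtls, scan = scan, report = rep,
                 out_dir = out_dir))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Summary report of a pipeline run
#'
#' Tallies per GWAS category: QTL count, mean and total variance explained by
#' lead SNPs, the large-effect fraction (lead SNP explaining more than 10% of
#' the phenotype variance), two-/three-genotype and superiority counts, and
#' overlap counts with low-diversity regions per parental group.
#'
#' @param qtl_report the per-QTL data.frame from the characterize stage.
#' @param regions low-D regions from the scan stage.
#' @return data.frame, one row per category (all-zero when no QTLs).
#' @export
pipeline_report <- function(qtl_report, regions = NULL) {
  if (is.null(qtl_report) || nrow(qtl_report) == 0) {
    return(data.frame(category = "none", n_qtl = 0L, mean_ve = 0,
                      large_effect_frac = 0, n_three_genotype = 0L,
                      n_two_genotype = 0L, n_hetero_superior = 0L,
                      n_homo_superior = 0L, n_overlap_maternal = 0L,
                      n_overlap_paternal = 0L))
  }
  ov <- NULL
  if (!is.null(regions) && nrow(regions) > 0) {
    q <- data.frame(chrom = as.character(qtl_report$qtl_chrom),
                    start = qtl_report$qtl_start, end = qtl_report$qtl_end + 1)
    ov <- qtl_overlap(q, regions)
  }
  out <- lapply(split(seq_len(nrow(qtl_report)), qtl_report$category), function(idx) {
    r <- qtl_report[idx, ]
    data.frame(
      category = r$category[1],
      n_qtl = nrow(r),
      mean_ve = mean(r$variance_explained),
      large_effect_frac = mean(r$variance_explained > 0.10),
      n_three_genotype = sum(r$class == "three_genotype"),
      n_two_genotype = sum(r$class == "two_genotype"),
      n_hetero_superior = sum(r$superiority == "hetero_superior", na.rm = TRUE),
      n_homo_superior = sum(r$superiority == "homo_superior", na.rm = TRUE),
      n_overlap_maternal = if (!is.null(ov) && "overlap_maternal" %in% names(ov))
        sum(ov$overlap_maternal[idx]) else 0L,
      n_overlap_paternal = if (!is.null(ov) && "overlap_paternal" %in% names(ov))
        sum(ov$overlap_paternal[idx]) else 0L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
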