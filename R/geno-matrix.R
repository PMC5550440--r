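#' Genotype matrix container
#'
#' A light container for biallelic SNP calls. Calls are coded as minor-allele
#' dosage: 0 = homozygous major, 1 = heterozygous, 2 = homozygous minor,
#' `NA` = missing. Rows are samples, columns are markers. The marker map
#' carries 1-based physical coordinates, strictly increasing within each
#' chromosome.
#'
#' @param calls integer matrix (samples x markers) with values in
#'   \{0, 1, 2, NA\}; rownames are sample ids.
#' @param map data.frame with columns `marker`, `chrom`, `pos` and optionally
#'   `allele_major`, `allele_minor`.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, map) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls))) stopf("`calls` must have sample ids as rownames")
  if (!all(c("marker", "chrom", "pos") %in% names(map))) {
    stopf("`map` needs columns marker, chrom, pos")
  }
  if (nrow(map) != ncol(calls)) stopf("map rows (%d) != call columns (%d)", nrow(map), ncol(calls))
  bad <- stats::na.omit(unique(as.vector(calls)))
  if (length(setdiff(bad, 0:2)) > 0) stopf("calls must be 0, 1, 2 or NA")
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  map$marker <- as.character(map$marker)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (is.null(map$allele_major)) map$allele_major <- "A"
  if (is.null(map$allele_minor)) map$allele_minor <- "G"
  o <- order(match(map$chrom, unique(map$chrom)), map$pos)
  if (!identical(o, seq_len(nrow(map)))) {
    map <- map[o, , drop = FALSE]
    calls <- calls[, o, drop = FALSE]
  }
  if (!all(vapply(split(map$pos, map$chrom), function(p) all(diff(p) > 0), logical(1)))) {
    stopf("marker positions must be strictly increasing within a chromosome")
  }
  colnames(calls) <- map$marker
  rownames(map) <- NULL
  structure(list(calls = calls, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "geno_matrix: %d samples x %d markers on %d chromosome(s); %.2f%% missing\n",
    nrow(x$calls), ncol(x$calls), length(unique(x$map$chrom)),
    100 * mean(is.na(x$calls))
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix
#'
#' @param x a `geno_matrix`.
#' @param samples sample ids or indices (missing = keep all).
#' @param markers marker ids or logical/integer index over markers.
#' @return a `geno_matrix`.
#' @export
geno_subset <- function(x, samples = NULL, markers = NULL) {
  calls <- x$calls
  map <- x$map
  if (!is.null(samples)) calls <- calls[samples, , drop = FALSE]
  if (!is.null(markers)) {
    if (is.character(markers)) markers <- match(markers, map$marker)
    calls <- calls[, markers, drop = FALSE]
    map <- map[markers, , drop = FALSE]
    rownames(map) <- NULL
  }
  structure(list(calls = calls, map = map), class = "geno_matrix")
}

sample_ids <- function(x) rownames(x$calls)

#' Bind two genotype matrices over the same marker set
#' @param x,y `geno_matrix` objects sharing an identical map.
#' @return a `geno_matrix` with the samples of both.
#' @export
geno_rbind <- function(x, y) {
  if (!identical(x$map$marker, y$map$marker)) stopf("marker sets differ")
  geno_matrix(rbind(x$calls, y$calls), x$map)
}

# ---- I/O -------------------------------------------------------------------

#' Write genotypes as PLINK PED/MAP text files
#'
#' @param geno a `geno_matrix`.
#' @param prefix path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return invisibly, the two file paths.
#' @export
write_ped_map <- function(geno, prefix) {
  map <- geno$map
  utils::write.table(
    data.frame(map$chrom, map$marker, 0, map$pos),
    paste0(prefix, ".map"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  a1 <- map$allele_major
  a2 <- map$allele_minor
  n <- nrow(geno$calls)
  lines <- character(n)
  for (i in seq_len(n)) {
    g <- geno$calls[i, ]
    al1 <- ifelse(is.na(g), "0", ifelse(g == 2L, a2, a1))
    al2 <- ifelse(is.na(g), "0", ifelse(g >= 1L, a2, a1))
    id <- rownames(geno$calls)[i]
    lines[i] <- paste(c(id, id, "0", "0", "0", "-9", rbind(al1, al2)), collapse = " ")
  }
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}

#' Read genotypes from PLINK PED/MAP text files
#'
#' Minor allele is defined by frequency in the file (ties broken by allele
#' order of first appearance).
#'
#' @param prefix path prefix as in [write_ped_map()].
#' @return a `geno_matrix`.
#' @export
read_ped_map <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"),
    col.names = c("chrom", "marker", "cm", "pos"),
    colClasses = c("character", "character", "NULL", "integer")
  )
  ped <- utils::read.table(paste0(prefix, ".ped"), colClasses = "character")
  ids <- ped[[2]]
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  m <- nrow(map)
  calls <- matrix(NA_integer_, nrow(ped), m, dimnames = list(ids, map$marker))
  amaj <- amin <- character(m)
  for (j in seq_len(m)) {
    a1 <- al[, 2L * j - 1L]
    a2 <- al[, 2L * j]
    obs <- c(a1, a2)
    obs <- obs[obs != "0"]
    lev <- sort(unique(obs))  # deterministic tie-break at MAF 0.5
    if (length(lev) > 2) stopf("marker %s is not biallelic", map$marker[j])
    cnt <- table(factor(obs, levels = lev))
    major <- lev[which.max(cnt)]
    minor <- if (length(lev) == 2) setdiff(lev, major) else major
    g <- (a1 == minor) + (a2 == minor)
    g[a1 == "0" | a2 == "0"] <- NA_integer_
    calls[, j] <- as.integer(g)
    amaj[j] <- major
    amin[j] <- if (length(lev) == 2) minor else "."
  }
  map$allele_major <- amaj
  map$allele_minor <- amin
  geno_matrix(calls, map)
}

#' Write genotypes as a plain-text VCF
#'
#' Minimal VCFv4.2 with GT fields; parents and hybrids are written unphased.
#'
#' @param geno a `geno_matrix`.
#' @param path output `.vcf` path.
#' @return invisibly, `path`.
#' @export
write_vcf_geno <- function(geno, path) {
  map <- geno$map
  gt <- t(geno$calls)
  gt_chr <- matrix("./.", nrow(gt), ncol(gt))
  gt_chr[!is.na(gt) & gt == 0L] <- "0/0"
  gt_chr[!is.na(gt) & gt == 1L] <- "0/1"
  gt_chr[!is.na(gt) & gt == 2L] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hetgwas",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno$calls)), collapse = "\t")
  )
  body <- paste(map$chrom, map$pos, map$marker, map$allele_major,
                map$allele_minor, ".", "PASS", ".", "GT",
                apply(gt_chr, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read biallelic SNP genotypes from a VCF
#'
#' Uses `vcfR` for parsing; REF is taken as the major allele label and ALT as
#' minor, with calls recoded to ALT dosage.
#'
#' @param path a VCF file.
#' @return a `geno_matrix`.
#' @export
read_vcf_geno <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) stopf("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dosage[clean == "0/0"] <- 0L
  dosage[clean %in% c("0/1", "1/0")] <- 1L
  dosage[clean == "1/1"] <- 2L
  map <- data.frame(
    marker = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                    paste0(fix[, "CHROM"], "_", fix[, "POS"]), fix[, "ID"]),
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    allele_major = fix[, "REF"], allele_minor = fix[, "ALT"],
    stringsAsFactors = FALSE
  )
  geno_matrix(t(dosage), map)
}

#' Cross design table
#'
#' @param f1 character vector of F1 ids.
#' @param maternal,paternal parental ids per F1.
#' @param family RIL family label of each paternal line (recycled per F1).
#' @return data.frame of class `cross_design`.
#' @export
cross_design <- function(f1, maternal, paternal, family = NA_character_) {
  if (anyDuplicated(f1)) stopf("duplicate F1 ids")
  if (length(intersect(maternal, paternal)) > 0) {
    stopf("maternal and paternal sets must be disjoint")
  }
  d <- data.frame(
    f1 = as.character(f1), maternal = as.character(maternal),
    paternal = as.character(paternal), family = as.character(family),
    stringsAsFactors = FALSE
  )
  class(d) <- c("cross_design", "data.frame")
  d
}
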