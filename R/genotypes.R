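#' Construct a genotype matrix object
#'
#' Bundles an N x P dosage matrix with variant and sample metadata. Dosages
#' are allele counts: 0/1/2 for diploid genotypes or 0/1 for haplotypes.
#' Population labels partition the samples into slices used by the
#' stability-guided selection layer.
#'
#' @param dosages numeric matrix, N samples x P variants, entries in
#'   \{0,1,2\} (or \{0,1\} for haplotypes).
#' @param variant_ids character vector of P unique variant identifiers.
#' @param positions integer vector of P 1-based base-pair coordinates.
#' @param chrom chromosome name (single string) or length-P vector.
#' @param sample_ids character vector of N sample identifiers.
#' @param population_labels factor or character vector of N population
#'   labels, or `NULL` if no slicing is intended.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variant_ids = NULL, positions = NULL,
                            chrom = "1", sample_ids = NULL,
                            population_labels = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages); p <- ncol(dosages)
  if (n < 1L || p < 1L) stop("dosage matrix must have at least one row and column")
  if (is.null(variant_ids)) variant_ids <- paste0("A", seq_len(p))
  variant_ids <- as.character(variant_ids)
  if (anyDuplicated(variant_ids)) stop("variant_ids must be unique")
  if (length(variant_ids) != p) stop("variant_ids length must equal ncol(dosages)")
  if (is.null(positions)) positions <- seq_len(p)
  if (length(positions) != p) stop("positions length must equal ncol(dosages)")
  if (length(chrom) == 1L) chrom <- rep(chrom, p)
  if (length(chrom) != p) stop("chrom must be length 1 or P")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  if (length(sample_ids) != n) stop("sample_ids length must equal nrow(dosages)")
  if (!is.null(population_labels)) {
    if (length(population_labels) != n)
      stop("population_labels length must equal nrow(dosages)")
    if (anyNA(population_labels)) stop("every sample needs exactly one population label")
    population_labels <- as.character(population_labels)
  }
  bad <- !(dosages %in% c(0, 1, 2)) & !is.na(dosages)
  if (any(bad)) stop("dosage values must be in {0,1,2} (or NA before imputation)")
  structure(list(
    dosages = dosages,
    variant_ids = variant_ids,
    positions = as.numeric(positions),
    chrom = as.character(chrom),
    sample_ids = as.character(sample_ids),
    population_labels = population_labels
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (chr %s)\n",
              nrow(x$dosages), ncol(x$dosages), x$chrom[1]))
  if (!is.null(x$population_labels)) {
    tab <- table(x$population_labels)
    cat("populations:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# subset columns (variants), preserving metadata
subset_variants <- function(geno, keep) {
  genotype_matrix(geno$dosages[, keep, drop = FALSE],
                  variant_ids = geno$variant_ids[keep],
                  positions = geno$positions[keep],
                  chrom = geno$chrom[keep],
                  sample_ids = geno$sample_ids,
                  population_labels = geno$population_labels)
}

# subset rows (samples)
subset_samples <- function(geno, keep) {
  genotype_matrix(geno$dosages[keep, , drop = FALSE],
                  variant_ids = geno$variant_ids,
                  positions = geno$positions,
                  chrom = geno$chrom,
                  sample_ids = geno$sample_ids[keep],
                  population_labels =
                    if (is.null(geno$population_labels)) NULL
                    else geno$population_labels[keep])
}

#' Restrict a locus to the cis window around a TSS
#'
#' Keeps variants whose position lies within `window_bp` of the transcription
#' start site, inclusive on both ends: `|pos - tss| <= window_bp`.
#'
#' @param genotypes a [genotype_matrix].
#' @param tss 1-based TSS coordinate on the same chromosome.
#' @param window_bp half-width of the window in base pairs (default 1 Mb).
#' @return a [genotype_matrix] with the retained variants.
#' @export
cis_window <- function(genotypes, tss, window_bp = 1e6) {
  keep <- abs(genotypes$positions - tss) <= window_bp
  if (!any(keep)) stop("no variants within the cis window (empty input)")
  subset_variants(genotypes, which(keep))
}

#' Read genotype dosages from a VCF or plain TSV file
#'
#' VCF input uses the GT field; phased and unphased genotypes are summed to
#' allele dosages. Multiallelic records keep the first ALT allele (with a
#' warning). Missing genotypes are imputed to the rounded per-variant mean
#' dosage, and the imputation count is reported via a message. TSV input is a
#' samples x variants table with a header row of variant IDs and a first
#' column of sample IDs; optional `#pos` / `#chrom` comment-style rows are
#' not supported — positions default to the column order.
#'
#' @param path path to a `.vcf`/`.vcf.gz` file, or a TSV dosage table.
#' @param region optional `"chrom:start-end"` string (1-based inclusive).
#' @param labels optional named vector or data.frame (sample_id, population)
#'   attaching population labels.
#' @return a [genotype_matrix].
#' @export
read_genotypes <- function(path, region = NULL, labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  is_vcf <- grepl("\\.vcf(\\.gz)?$", path)
  geno <- if (is_vcf) read_genotypes_vcf(path, region) else read_genotypes_tsv(path)
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      lab <- stats::setNames(as.character(labels[[2]]), as.character(labels[[1]]))
    } else lab <- labels
    geno$population_labels <- unname(lab[geno$sample_ids])
    if (anyNA(geno$population_labels)) stop("population label missing for some samples")
  }
  geno
}

read_genotypes_vcf <- function(path, region = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("package 'vcfR' is required to read VCF files")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]; pos <- as.numeric(fix[, "POS"])
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(chrom, ":", pos)[is.na(ids) | ids == "."]
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) warning(sum(multi), " multiallelic record(s): keeping first ALT allele")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  # count only the first ALT allele; any other ALT counts as reference
  dose_one <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    a <- strsplit(g, "[/|]")[[1]]
    if (any(a == ".")) return(NA_real_)
    sum(a == "1")
  }
  dos <- t(apply(gt, 1, function(row) vapply(row, dose_one, numeric(1))))
  samples <- colnames(gt)
  keep <- rep(TRUE, length(pos))
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) stop("region must be 'chrom:start-end'")
    keep <- chrom == m[2] & pos >= as.numeric(m[3]) & pos <= as.numeric(m[4])
    if (!any(keep)) stop("no variants in region (empty input)")
  }
  dos <- dos[keep, , drop = FALSE]
  n_imp <- sum(is.na(dos))
  if (n_imp > 0) {
    message(n_imp, " missing genotype(s) imputed to rounded per-variant mean")
    for (i in seq_len(nrow(dos))) {
      na <- is.na(dos[i, ])
      if (any(na)) dos[i, na] <- round(mean(dos[i, !na]))
    }
  }
  genotype_matrix(t(dos), variant_ids = ids[keep], positions = pos[keep],
                  chrom = chrom[keep], sample_ids = samples)
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, row.names = 1)
  mat <- as.matrix(tab)
  n_imp <- sum(is.na(mat))
  if (n_imp > 0) {
    message(n_imp, " missing genotype(s) imputed to rounded per-variant mean")
    for (j in seq_len(ncol(mat))) {
      na <- is.na(mat[, j])
      if (any(na)) mat[na, j] <- round(mean(mat[!na, j]))
    }
  }
  genotype_matrix(mat, variant_ids = colnames(mat), sample_ids = rownames(tab))
}

#' Read a phenotype vector from a two-column TSV (sample_id, value)
#'
#' @param path TSV path with header.
#' @param sample_ids optional sample ordering to align against.
#' @return a numeric vector named by sample id, with attribute
#'   `residualized = FALSE`.
#' @export
read_phenotype <- function(path, sample_ids = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  y <- stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
  if (!is.null(sample_ids)) {
    if (!all(sample_ids %in% names(y))) stop("phenotype missing for some samples")
    y <- y[sample_ids]
  }
  if (anyNA(y) || any(!is.finite(y))) stop("phenotype values must be finite")
  attr(y, "residualized") <- FALSE
  attr(y, "n_pcs_removed") <- 0L
  y
}

#' Read population labels from a two-column TSV (sample_id, population)
#' @param path TSV path with header.
#' @return named character vector, sample id -> population label.
#' @export
read_labels <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}
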