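#' Simulate block-LD genotypes for a structured cohort
#'
#' Generates an N x P dosage matrix for five labelled subpopulations using a
#' latent-Gaussian copula: within an LD block of `ld_block_size` adjacent
#' variants, each haplotype's latent Gaussians follow an AR(1) process with
#' lag-1 correlation `ld_rho`; blocks are independent. Latents are
#' thresholded at frequency-matched quantiles so each variant's marginal
#' allele frequency is exact per population. Population allele frequencies
#' drift from shared ancestral frequencies by a Balding-Nichols beta
#' perturbation with differentiation parameter `fst_like_drift` (0 = no
#' drift, all populations share the ancestral frequency).
#'
#' Default population sizes (91, 86, 92, 89, 87) correspond to the
#' (TSI, GBR, FIN, CEU, YRI) composition of the GEUVADIS cohort.
#'
#' @param n_per_pop integer vector of 5 subpopulation sizes.
#' @param n_variants number of variants P.
#' @param ld_block_size number of adjacent variants per LD block.
#' @param ld_rho lag-1 latent correlation within a block, in `[0,1)`.
#' @param maf_range interval within (0, 0.5] from which ancestral minor
#'   allele frequencies are drawn uniformly.
#' @param fst_like_drift Balding-Nichols differentiation parameter (>= 0).
#' @param pop_names labels for the five subpopulations.
#' @param spacing_bp base-pair spacing between adjacent variants.
#' @param chrom chromosome name for the synthetic locus.
#' @param start_bp coordinate of the first variant.
#' @param seed RNG seed (integer) for reproducibility.
#' @return a [genotype_matrix] with population labels attached.
#' @export
synth_genotypes <- function(n_per_pop = c(91, 86, 92, 89, 87),
                            n_variants = 100,
                            ld_block_size = 10,
                            ld_rho = 0.9,
                            maf_range = c(0.05, 0.5),
                            fst_like_drift = 0.02,
                            pop_names = c("TSI", "GBR", "FIN", "CEU", "YRI"),
                            spacing_bp = 5000,
                            chrom = "1",
                            start_bp = 1e6,
                            seed = NULL) {
  if (length(n_per_pop) != length(pop_names))
    stop("n_per_pop and pop_names must have equal length")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must be a sub-interval of (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0,1)")
  if (fst_like_drift < 0) stop("fst_like_drift must be nonnegative")
  if (!is.null(seed)) set.seed(as.integer(seed))

  p <- as.integer(n_variants)
  n <- sum(n_per_pop)
  K <- length(n_per_pop)
  anc <- stats::runif(p, maf_range[1], maf_range[2])
  # per-population frequencies: Balding-Nichols Beta(p(1-F)/F, (1-p)(1-F)/F)
  freqs <- matrix(anc, nrow = K, ncol = p, byrow = TRUE)
  if (fst_like_drift > 0) {
    fac <- (1 - fst_like_drift) / fst_like_drift
    for (k in seq_len(K))
      freqs[k, ] <- stats::rbeta(p, anc * fac, (1 - anc) * fac)
    # keep variants polymorphic in expectation
    freqs <- pmin(pmax(freqs, 1e-4), 1 - 1e-4)
  }
  block <- rep(seq_len(ceiling(p / ld_block_size)), each = ld_block_size)[seq_len(p)]
  new_block <- c(TRUE, diff(block) != 0)

  # one AR(1) latent chain per haplotype; restart at block boundaries
  draw_hap <- function(n_hap, pf) {
    z <- matrix(stats::rnorm(n_hap * p), n_hap, p)
    if (ld_rho > 0 && p > 1) {
      s <- sqrt(1 - ld_rho^2)
      for (j in 2:p) if (!new_block[j])
        z[, j] <- ld_rho * z[, j - 1] + s * z[, j]
    }
    # allele present where latent falls below the frequency-matched quantile
    sweep(z, 2, stats::qnorm(pf), "<") * 1
  }
  dos <- matrix(0, n, p)
  labels <- rep(pop_names, times = n_per_pop)
  offset <- 0L
  for (k in seq_len(K)) {
    nk <- n_per_pop[k]
    h1 <- draw_hap(nk, freqs[k, ])
    h2 <- draw_hap(nk, freqs[k, ])
    dos[offset + seq_len(nk), ] <- h1 + h2
    offset <- offset + nk
  }
  genotype_matrix(dos,
                  variant_ids = sprintf("A%d", seq_len(p)),
                  positions = start_bp + (seq_len(p) - 1) * spacing_bp,
                  chrom = chrom,
                  sample_ids = sprintf("%s_%d", labels, seq_len(n)),
                  population_labels = labels)
}

#' Write fine-mapping output tables with a JSON parameter sidecar
#'
#' Serialises a [pics] result or a `finemap_selection` outcome as a TSV with
#' one row per (potential set, variant), plus a `<path>.json` sidecar of run
#' parameters and seed. Plain data.frames (evaluation tables) are written
#' as-is.
#'
#' @param result a `pics`, `finemap_selection`, or data.frame.
#' @param path output TSV path.
#' @param params optional named list recorded in the JSON sidecar.
#' @return the path, invisibly.
#' @export
write_result <- function(result, path, params = NULL) {
  tab <- as.data.frame(result)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- c(list(class = class(result)[1], written = "TSV"),
            if (!is.null(params)) params
            else if (!is.null(attr(result, "params"))) attr(result, "params"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read back a table written by [write_result]
#' @param path TSV path.
#' @return a data.frame; the JSON sidecar (if present) is attached as the
#'   `params` attribute.
#' @export
read_result <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = NA, check.names = FALSE)
  side <- paste0(path, ".json")
  if (file.exists(side))
    attr(tab, "params") <- jsonlite::read_json(side, simplifyVector = TRUE)
  tab
}
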