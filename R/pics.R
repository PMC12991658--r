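#' Parameters for the permutation fine-mapper
#'
#' @param r_threshold LD correlation magnitude defining a lead SNP's
#'   neighbourhood: variants with `cor^2 > r_threshold^2` are included
#'   (default 0.5).
#' @param R number of constrained permutations per focal SNP (default 500).
#' @param C number of potential sets to return (default 3).
#' @param prior per-variant prior causal weights; `NULL` means the uniform
#'   prior 1/P. Weights are normalised to sum to one, so the posterior is
#'   invariant to rescaling the prior by a positive constant.
#' @param seed integer seed; one generator is seeded per [pics] call and
#'   permutations for successive focal SNPs are drawn sequentially from it.
#' @return a list of class `pics_params`.
#' @export
pics_params <- function(r_threshold = 0.5, R = 500, C = 3,
                        prior = NULL, seed = NULL) {
  if (r_threshold <= 0 || r_threshold >= 1) stop("r_threshold must be in (0,1)")
  if (R < 1) stop("R (permutation count) must be >= 1")
  if (C < 1) stop("C (number of potential sets) must be >= 1")
  if (!is.null(prior)) {
    if (any(prior < 0) || sum(prior) <= 0)
      stop("prior entries must be >= 0 with a positive sum")
    prior <- prior / sum(prior)
  }
  structure(list(r_threshold = r_threshold, R = as.integer(R),
                 C = as.integer(C), prior = prior,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "pics_params")
}

#' Marginal association of each variant with the phenotype
#'
#' Squared Pearson correlation between each variant's dosage column and the
#' phenotype. Monomorphic variants get statistic 0. Ranking by r-squared is
#' equivalent to ranking by the simple-regression F statistic.
#'
#' @param genotypes a [genotype_matrix].
#' @param phenotype numeric vector of length N.
#' @return numeric vector of P squared correlations, named by variant id.
#' @export
marginal_assoc <- function(genotypes, phenotype) {
  x <- genotypes$dosages
  if (nrow(x) < 3) stop("need at least 3 samples")
  if (stats::sd(phenotype) == 0) stop("constant phenotype (degenerate input)")
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) stop("no polymorphic variants")
  r <- suppressWarnings(stats::cor(x, phenotype))[, 1]
  r[sds == 0] <- 0
  stats::setNames(r^2, genotypes$variant_ids)
}

#' Pick the lead SNP from association statistics
#'
#' Argmax of the statistic; ties are broken by smallest genomic position,
#' then lexicographically smallest variant id.
#'
#' @param assoc numeric vector of association statistics.
#' @param positions genomic positions for tie-breaking (defaults to index
#'   order).
#' @param variant_ids ids for the final tie-break.
#' @return the index of the lead SNP.
#' @export
lead_snp <- function(assoc, positions = seq_along(assoc),
                     variant_ids = as.character(seq_along(assoc))) {
  if (length(assoc) == 0) stop("empty association vector")
  if (all(assoc == 0)) warning("all association statistics are zero")
  best_index(assoc, positions, variant_ids)
}

# shared argmax-with-tie-rule: max statistic, then min position, then min id
best_index <- function(stat, positions, ids) {
  m <- max(stat)
  cand <- which(stat == m)
  if (length(cand) > 1L) {
    cand <- cand[positions[cand] == min(positions[cand])]
    if (length(cand) > 1L) cand <- cand[order(ids[cand])][1L]
  }
  cand[1L]
}

#' LD neighbourhood of a lead SNP
#'
#' Indices `k` with `cor(A_k, A_lead)^2 > r_threshold^2`; always contains
#' the lead itself.
#'
#' @param genotypes a [genotype_matrix].
#' @param lead lead SNP column index.
#' @param r_threshold correlation magnitude threshold.
#' @return sorted integer vector of neighbourhood indices.
#' @export
neighborhood <- function(genotypes, lead, r_threshold = 0.5) {
  x <- genotypes$dosages
  r <- suppressWarnings(stats::cor(x, x[, lead]))[, 1]
  r[is.na(r)] <- 0
  idx <- which(r^2 > r_threshold^2)
  sort(unique(c(lead, idx)))
}

#' Draw one LD- and association-preserving row permutation
#'
#' Rows are permuted only within strata defined by the focal variant's
#' dosage value, moving as whole units. Consequently the focal column is
#' unchanged as a vector (its association with any fixed phenotype is
#' exactly invariant) and every column-column correlation is exactly
#' preserved.
#'
#' @param genotypes a [genotype_matrix] (or a plain dosage matrix).
#' @param focal focal variant column index.
#' @return an integer permutation `perm` of `1:N`; the permuted matrix is
#'   `dosages[perm, ]`.
#' @export
constrained_permutation <- function(genotypes, focal) {
  x <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages else genotypes
  perm_within_strata(x[, focal])
}

perm_within_strata <- function(focal_col) {
  perm <- seq_along(focal_col)
  for (s in split(perm, focal_col)) {
    if (length(s) > 1L) perm[s] <- s[sample.int(length(s))]
  }
  perm
}

#' Permutation posterior over a lead SNP's neighbourhood
#'
#' For each focal SNP j in the neighbourhood, the probability that the lead
#' emerges as the neighbourhood's strongest association under constrained
#' permutations (rows shuffled within the focal SNP's dosage strata) is
#' estimated over `R` draws, multiplied by the focal SNP's prior, and the
#' vector is normalised to sum to one over the neighbourhood.
#'
#' @param genotypes a [genotype_matrix] for the locus (all columns).
#' @param phenotype numeric phenotype vector.
#' @param lead lead SNP column index.
#' @param params a [pics_params] object.
#' @param nbhd optional precomputed neighbourhood indices.
#' @return a `posterior_vector`: list with `support` (column indices),
#'   `variant_ids`, `probs` (summing to 1), `lead_index`.
#' @export
pics_posterior <- function(genotypes, phenotype, lead,
                           params = pics_params(), nbhd = NULL) {
  if (params$R < 1) stop("R must be >= 1")
  if (is.null(nbhd)) nbhd <- neighborhood(genotypes, lead, params$r_threshold)
  x <- genotypes$dosages
  n <- nrow(x)
  pos <- genotypes$positions[nbhd]
  ids <- genotypes$variant_ids[nbhd]
  lead_in <- match(lead, nbhd)
  prior <- if (is.null(params$prior)) rep(1 / ncol(x), length(nbhd))
           else params$prior[nbhd]

  xs <- scale(x[, nbhd, drop = FALSE])       # columns centered, unit sd
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  ys <- as.numeric(scale(phenotype))
  win <- numeric(length(nbhd))
  for (f in seq_along(nbhd)) {
    strata <- split(seq_len(n), x[, nbhd[f]])
    # permuting y by a within-stratum group element is distributionally
    # identical to permuting the rows of X (the group is inverse-closed)
    yp <- matrix(ys, n, params$R)
    for (s in strata) if (length(s) > 1L)
      for (r in seq_len(params$R)) yp[s, r] <- yp[s[sample.int(length(s))], r]
    r2 <- (crossprod(xs, yp) / (n - 1))^2    # |nbhd| x R squared correlations
    wins <- 0L
    for (r in seq_len(params$R))
      if (best_index(r2[, r], pos, ids) == lead_in) wins <- wins + 1L
    win[f] <- wins / params$R
  }
  w <- win * prior
  if (sum(w) == 0) {
    warning("lead never emerged in any permutation; falling back to prior weights")
    w <- prior
  }
  pv <- posterior_vector(support = nbhd, probs = w / sum(w),
                         variant_ids = ids, lead_index = lead)
  attr(pv, "win_fractions") <- stats::setNames(win, ids)
  pv
}

posterior_vector <- function(support, probs, variant_ids, lead_index) {
  stopifnot(length(support) == length(probs),
            all(probs >= 0), abs(sum(probs) - 1) < 1e-9,
            lead_index %in% support)
  structure(list(support = as.integer(support), probs = as.numeric(probs),
                 variant_ids = as.character(variant_ids),
                 lead_index = as.integer(lead_index)),
            class = "posterior_vector")
}

#' Fit the permutation fine-mapper on a locus
#'
#' Iterates over `C` potential sets: finds the lead SNP among the remaining
#' variants, computes its LD neighbourhood and the constrained-permutation
#' posterior over that neighbourhood, records the normalised posterior
#' vector, then removes the neighbourhood's columns. Stops early (with
#' fewer sets) if the locus is exhausted. Supports of the returned sets are
#' pairwise disjoint by construction.
#'
#' @param genotypes a [genotype_matrix].
#' @param phenotype numeric phenotype vector of length N.
#' @param params a [pics_params] object.
#' @return an object of class `pics`: list with `sets` (posterior vectors
#'   indexed against the input matrix), `params`, `variant_ids`,
#'   `positions`, `n_samples`.
#' @export
pics <- function(genotypes, phenotype, params = pics_params()) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (length(phenotype) != nrow(genotypes$dosages))
    stop("phenotype length must match sample count")
  if (!is.null(params$seed)) set.seed(params$seed)
  p <- ncol(genotypes$dosages)
  remaining <- seq_len(p)
  sets <- list()
  for (cc in seq_len(params$C)) {
    if (length(remaining) == 0L) break
    sub <- subset_variants(genotypes, remaining)
    sds <- apply(sub$dosages, 2, stats::sd)
    if (all(sds == 0)) break
    assoc <- marginal_assoc(sub, phenotype)
    lead_local <- lead_snp(assoc, sub$positions, sub$variant_ids)
    nb_local <- neighborhood(sub, lead_local, params$r_threshold)
    pv <- pics_posterior(sub, phenotype, lead_local,
                         params = restrict_prior(params, remaining, p),
                         nbhd = nb_local)
    # re-express support in original column indices
    pv$support <- remaining[pv$support]
    pv$lead_index <- remaining[pv$lead_index]
    sets[[cc]] <- pv
    remaining <- setdiff(remaining, pv$support)
  }
  if (length(sets) == 0L) stop("no polymorphic variants to fine-map (empty input)")
  structure(list(sets = sets, params = params,
                 variant_ids = genotypes$variant_ids,
                 positions = genotypes$positions,
                 n_samples = nrow(genotypes$dosages),
                 n_variants = p),
            class = "pics")
}

restrict_prior <- function(params, remaining, p_total) {
  if (is.null(params$prior)) return(params)
  params$prior <- params$prior[remaining]
  params
}

#' @export
print.pics <- function(x, ...) {
  cat(sprintf("pics fit: %d potential set(s), %d samples, %d variants\n",
              length(x$sets), x$n_samples, x$n_variants))
  for (cc in seq_along(x$sets)) {
    s <- x$sets[[cc]]
    top <- which.max(s$probs)
    cat(sprintf("  Potential Set %d: lead %s, %d variants in support, max prob %.3f (%s)\n",
                cc, x$variant_ids[s$lead_index], length(s$support),
                s$probs[top], s$variant_ids[top]))
  }
  invisible(x)
}

#' @export
summary.pics <- function(object, ...) {
  df <- as.data.frame(object)
  cat(sprintf("Permutation fine-mapping: C = %d set(s), R = %d permutations, |r| > %.2f\n",
              length(object$sets), object$params$R, object$params$r_threshold))
  print(df, row.names = FALSE)
  invisible(df)
}

#' @export
coef.pics <- function(object, set = 1, ...) {
  s <- object$sets[[set]]
  stats::setNames(s$probs, s$variant_ids)
}

#' @export
as.data.frame.pics <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$sets), function(cc) {
    s <- x$sets[[cc]]
    data.frame(potential_set = cc,
               variant_id = s$variant_ids,
               position = x$positions[s$support],
               prob = s$probs,
               is_lead = s$support == s$lead_index,
               stringsAsFactors = FALSE)
  }))
}
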