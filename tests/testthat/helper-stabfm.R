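# Fixture builders and independent oracles shared across tests.

# small genotype matrix straight from a dosage matrix
gm <- function(dosages, positions = NULL, ids = NULL, labels = NULL) {
  genotype_matrix(dosages,
                  variant_ids = ids,
                  positions = positions,
                  population_labels = labels)
}

# enumerate ALL permutations in the within-strata group of a focal column:
# cartesian product of the per-stratum permutation sets
enumerate_strata_perms <- function(focal_col) {
  n <- length(focal_col)
  perms_of <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  strata <- split(seq_len(n), focal_col)
  grids <- lapply(strata, perms_of)
  combos <- expand.grid(lapply(grids, seq_along))
  lapply(seq_len(nrow(combos)), function(r) {
    perm <- integer(n)
    for (s in seq_along(strata))
      perm[strata[[s]]] <- grids[[s]][[combos[r, s]]]
    perm
  })
}

# exhaustive PICS posterior over a neighbourhood: exact win fraction for
# each focal SNP by enumerating the constrained permutation group
exhaustive_pics_posterior <- function(geno, y, lead, nbhd,
                                      prior = rep(1, length(nbhd))) {
  x <- geno$dosages
  pos <- geno$positions[nbhd]
  ids <- geno$variant_ids[nbhd]
  lead_in <- match(lead, nbhd)
  argmax_tie <- function(stat) {
    m <- max(stat); cand <- which(stat == m)
    if (length(cand) > 1) {
      cand <- cand[pos[cand] == min(pos[cand])]
      if (length(cand) > 1) cand <- cand[order(ids[cand])][1]
    }
    cand[1]
  }
  win <- numeric(length(nbhd))
  for (f in seq_along(nbhd)) {
    perms <- enumerate_strata_perms(x[, nbhd[f]])
    wins <- 0
    for (perm in perms) {
      # permuted rows of X against fixed y == fixed X against y[perm^-1];
      # enumerate the full group so inversion is immaterial
      r2 <- sapply(nbhd, function(k) suppressWarnings(cor(x[perm, k], y))^2)
      r2[is.na(r2)] <- 0
      if (argmax_tie(r2) == lead_in) wins <- wins + 1
    }
    win[f] <- wins / length(perms)
  }
  w <- win * prior
  list(posterior = w / sum(w), win = win)
}

# brute-force two-stage stability rule on plain probability vectors
brute_stable <- function(pooled, slices, positions = seq_along(pooled)) {
  pos <- which(pooled > 0)
  counts <- sapply(pos, function(v)
    1 + sum(sapply(slices, function(s) s[v] > 0)))
  s_c <- pos[counts == max(counts)]
  best <- s_c[order(-pooled[s_c], positions[s_c])][1]
  list(S = sort(s_c), variant = best, prob = pooled[best],
       count = max(counts))
}

# wrap plain numeric vectors as posterior vectors for stable_rule()
as_pv_list <- function(vectors, ids = NULL) {
  lapply(vectors, function(v) {
    if (is.null(ids)) ids <- paste0("A", seq_along(v))
    structure(list(support = seq_along(v), probs = v,
                   variant_ids = ids, lead_index = which.max(v)),
              class = "posterior_vector")
  })
}

# write a tiny VCF fixture; rows = list of per-variant genotype strings
write_vcf_fixture <- function(path, samples, variants) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- vapply(variants, function(v)
    paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
            v$gt), collapse = "\t"), character(1))
  writeLines(c(hdr, rows), path)
  path
}
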