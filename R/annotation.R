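#' One-sided Wilcoxon comparisons of annotation scores with BH correction
#'
#' Runs one-sided Wilcoxon tests per annotation column: unpaired rank-sum
#' for a matching vs non-matching grouping, or signed-rank for paired
#' top-vs-stable comparisons. Benjamini-Hochberg adjustment is applied
#' jointly across all annotations (and potential sets, when a
#' `potential_set` column is present and `by_set = TRUE`) within the
#' comparison family.
#'
#' @param table data.frame of numeric annotation columns (missing values
#'   allowed and dropped pairwise/groupwise).
#' @param group for `paired = FALSE`: logical/two-level vector splitting
#'   rows into the two groups (TRUE = first group). For `paired = TRUE`:
#'   ignored; `table2` supplies the paired scores.
#' @param table2 second table of identical shape for paired comparisons.
#' @param paired paired signed-rank (`TRUE`) or unpaired rank-sum
#'   (`FALSE`).
#' @param direction `"greater"` tests enrichment of group 1 (or of `table`
#'   over `table2`); `"less"` the opposite.
#' @param annotations which columns to test (default: all numeric columns).
#' @return data.frame with annotation, n, p_raw, p_bh.
#' @export
wilcoxon_compare <- function(table, group = NULL, table2 = NULL,
                             paired = FALSE,
                             direction = c("greater", "less"),
                             annotations = NULL) {
  direction <- match.arg(direction)
  if (is.null(annotations))
    annotations <- names(table)[vapply(table, is.numeric, logical(1))]
  if (length(annotations) == 0) stop("no numeric annotation columns")
  one <- function(ann) {
    if (paired) {
      x <- table[[ann]]; y <- table2[[ann]]
      ok <- !is.na(x) & !is.na(y)
      x <- x[ok]; y <- y[ok]
      if (sum(x != y) < 2)
        return(data.frame(annotation = ann, n = length(x), p_raw = 1))
      p <- suppressWarnings(
        stats::wilcox.test(x, y, paired = TRUE, alternative = direction,
                           exact = length(x) <= 50,
                           correct = TRUE)$p.value)
    } else {
      g <- as.logical(group)
      x <- table[[ann]][g]; y <- table[[ann]][!g]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 2 || length(y) < 2)
        return(data.frame(annotation = ann, n = length(x) + length(y), p_raw = NA_real_))
      if (length(unique(c(x, y))) == 1) {
        warning("all values tied for annotation ", ann)
        return(data.frame(annotation = ann, n = length(x) + length(y), p_raw = 1))
      }
      p <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = direction,
                           exact = length(x) + length(y) <= 50,
                           correct = TRUE)$p.value)
      x_n <- length(x) + length(y)
      return(data.frame(annotation = ann, n = x_n, p_raw = p))
    }
    data.frame(annotation = ann, n = length(x), p_raw = p)
  }
  out <- do.call(rbind, lapply(annotations, one))
  out$p_bh <- stats::p.adjust(out$p_raw, method = "BH")
  out
}

# ---- F_ST ------------------------------------------------------------------

#' Two-population F_ST from allele frequencies
#'
#' Hudson's two-population estimator in its uncorrected form,
#' `(p1 - p2)^2 / (p1 (1 - p2) + p2 (1 - p1))`: zero at identical
#' frequencies, one at fixation for alternative alleles. The Weir-Cockerham
#' two-population estimator (with sample sizes) is available via
#' `estimator = "wc"`.
#'
#' @param p1,p2 allele frequencies in the two populations.
#' @param n1,n2 sample sizes (haploid counts), required for `"wc"`.
#' @param estimator `"hudson"` (default) or `"wc"`.
#' @return F_ST estimate (may be negative for `"wc"`).
#' @export
fst_pair <- function(p1, p2, n1 = NULL, n2 = NULL,
                     estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  if (estimator == "hudson") {
    num <- (p1 - p2)^2
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    if (den == 0) return(0)
    return(num / den)
  }
  if (is.null(n1) || is.null(n2)) stop("Weir-Cockerham needs sample sizes")
  r <- 2
  nbar <- (n1 + n2) / 2
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2)
  if (a + b == 0) return(0)
  a / (a + b)
}

#' Moderator variables for a stability-guided selection
#'
#' Computes, per potential set, the six moderators used in the trend
#' analysis: (1) degree of stability — number of subpopulations in which
#' the stable variant has positive probability; (2) maximum pairwise
#' allele-frequency (ALT allele) difference between those subpopulations;
#' (3) maximum pairwise F_ST between them; (4)/(5) whether the top/stable
#' variant had positive probability in the Yoruban slice of the stability
#' run; (6) the top variant's posterior probability.
#'
#' @param stable_outcome a `finemap_selection` from [stable_select] (slice
#'   posteriors are read from its attributes).
#' @param top_outcome the matching `finemap_selection` from [top_select].
#' @param genotypes the [genotype_matrix] (with population labels) used for
#'   allele frequencies.
#' @param yri_label distal-slice label (default "YRI").
#' @param fst_estimator `"hudson"` or `"wc"`.
#' @return data.frame with one row per potential set and the six moderator
#'   columns.
#' @export
moderators <- function(stable_outcome, top_outcome, genotypes,
                       yri_label = "YRI",
                       fst_estimator = c("hudson", "wc")) {
  fst_estimator <- match.arg(fst_estimator)
  slice_sets <- attr(stable_outcome, "slice_sets")
  if (is.null(slice_sets)) stop("stable_outcome must retain slice posteriors")
  labels <- genotypes$population_labels
  rows <- lapply(seq_len(nrow(stable_outcome)), function(i) {
    cc <- stable_outcome$potential_set[i]
    sv_id <- stable_outcome$variant_id[i]
    sv_ix <- stable_outcome$variant_index[i]
    positive_in <- function(v_id, slice) {
      sets <- slice_sets[[slice]]
      if (length(sets) < cc) return(FALSE)
      j <- match(v_id, sets[[cc]]$variant_ids)
      !is.na(j) && sets[[cc]]$probs[j] > 0
    }
    pops_pos <- if (is.na(sv_id)) character(0)
                else names(slice_sets)[vapply(names(slice_sets),
                                              function(s) positive_in(sv_id, s),
                                              logical(1))]
    deg <- length(pops_pos)
    max_dp <- NA_real_; max_fst <- NA_real_
    if (deg >= 2 && !is.na(sv_ix)) {
      freqs <- vapply(pops_pos, function(pp)
        mean(genotypes$dosages[labels == pp, sv_ix]) / 2, numeric(1))
      sizes <- vapply(pops_pos, function(pp) 2 * sum(labels == pp), numeric(1))
      prs <- utils::combn(seq_along(pops_pos), 2)
      max_dp <- max(abs(freqs[prs[1, ]] - freqs[prs[2, ]]))
      max_fst <- max(apply(prs, 2, function(pr)
        fst_pair(freqs[pr[1]], freqs[pr[2]], sizes[pr[1]], sizes[pr[2]],
                 estimator = fst_estimator)))
    }
    top_row <- top_outcome[top_outcome$potential_set == cc, , drop = FALSE]
    top_id <- if (nrow(top_row)) top_row$variant_id[1] else NA_character_
    top_pp <- if (nrow(top_row)) top_row$pooled_prob[1] else NA_real_
    data.frame(potential_set = cc,
               degree_of_stability = deg,
               max_freq_diff = max_dp,
               max_fst = max_fst,
               top_in_yri = if (!is.na(top_id) && yri_label %in% names(slice_sets))
                 positive_in(top_id, yri_label) else NA,
               stable_in_yri = if (!is.na(sv_id) && yri_label %in% names(slice_sets))
                 positive_in(sv_id, yri_label) else NA,
               top_posterior = top_pp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- trend tests -----------------------------------------------------------

# Jonckheere-Terpstra statistic: sum over ordered group pairs (i < j) of
# Mann-Whitney counts #{(u,v): x_u in group i, x_v in group j, x_u < x_v},
# with ties counted 1/2.
jt_statistic <- function(x, g) {
  lev <- sort(unique(g))
  s <- 0
  for (i in seq_along(lev)[-length(lev)]) for (j in (which(lev > lev[i]))) {
    xi <- x[g == lev[i]]; xj <- x[g == lev[j]]
    cmp <- outer(xi, xj, "<")
    tie <- outer(xi, xj, "==")
    s <- s + sum(cmp) + 0.5 * sum(tie)
  }
  s
}

#' Jonckheere-Terpstra trend test by permutation
#'
#' Tests for a monotone trend of a numeric response across ordered groups.
#' The null distribution of the JT statistic is obtained by permuting group
#' labels (`nperm` draws, default 5000). One-sided p-values in both
#' directions are returned with the add-one permutation convention.
#'
#' @param x numeric response.
#' @param g ordered group labels (numeric or ordered factor).
#' @param nperm number of label permutations (default 5000).
#' @return list with `statistic`, `p_increasing`, `p_decreasing`.
#' @export
jonckheere_test <- function(x, g, nperm = 5000) {
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- as.numeric(g[ok])
  if (length(unique(g)) < 3) stop("Jonckheere-Terpstra needs >= 3 distinct group levels")
  obs <- jt_statistic(x, g)
  perm <- vapply(seq_len(nperm), function(i) jt_statistic(x, sample(g)), numeric(1))
  list(statistic = obs,
       p_increasing = (sum(perm >= obs) + 1) / (nperm + 1),
       p_decreasing = (sum(perm <= obs) + 1) / (nperm + 1))
}

#' Trend tests of annotation deltas against moderators
#'
#' For each (moderator, annotation) pair, tests whether the per-gene
#' stable-minus-top annotation difference trends with the moderator:
#' Jonckheere-Terpstra (permutation) for the ordinal degree of stability,
#' Pearson correlation tests for continuous moderators, and unpaired
#' Wilcoxon tests for binary moderators. One-sided p-values are reported in
#' both directions; BH adjustment is applied within each moderator across
#' all annotations (and rows supplied, e.g. potential sets).
#'
#' @param deltas data.frame of numeric per-gene annotation differences
#'   (stable minus top), one row per gene.
#' @param moderator_table data.frame aligned with `deltas` containing the
#'   moderator columns.
#' @param moderator_types named character vector mapping moderator column
#'   names to `"ordinal"`, `"continuous"`, or `"binary"`; defaults cover
#'   the six standard moderators.
#' @param nperm permutations for the JT test (default 5000).
#' @return long data.frame: moderator, annotation, test, n, p_greater,
#'   p_less, p_greater_bh, p_less_bh.
#' @export
trend_tests <- function(deltas, moderator_table,
                        moderator_types = c(degree_of_stability = "ordinal",
                                            max_freq_diff = "continuous",
                                            max_fst = "continuous",
                                            top_in_yri = "binary",
                                            stable_in_yri = "binary",
                                            top_posterior = "continuous"),
                        nperm = 5000) {
  anns <- names(deltas)[vapply(deltas, is.numeric, logical(1))]
  mods <- intersect(names(moderator_types), names(moderator_table))
  out <- list()
  for (mod in mods) {
    type <- moderator_types[[mod]]
    m <- moderator_table[[mod]]
    res <- lapply(anns, function(ann) {
      d <- deltas[[ann]]
      ok <- !is.na(d) & !is.na(m)
      di <- d[ok]; mi <- m[ok]
      na_row <- data.frame(moderator = mod, annotation = ann, test = type,
                           n = sum(ok), p_greater = NA_real_, p_less = NA_real_)
      if (sum(ok) < 3) return(na_row)
      if (type == "ordinal") {
        if (length(unique(mi)) < 3) return(na_row)
        jt <- jonckheere_test(di, mi, nperm = nperm)
        na_row$p_greater <- jt$p_increasing
        na_row$p_less <- jt$p_decreasing
      } else if (type == "continuous") {
        if (stats::sd(di) == 0 || stats::sd(mi) == 0) {
          warning("constant values: correlation undefined for ", ann, " vs ", mod)
          return(na_row)
        }
        na_row$p_greater <- stats::cor.test(mi, di, alternative = "greater")$p.value
        na_row$p_less <- stats::cor.test(mi, di, alternative = "less")$p.value
      } else { # binary
        g <- as.logical(mi)
        if (length(unique(g)) < 2 || length(unique(di)) == 1) return(na_row)
        na_row$p_greater <- suppressWarnings(
          stats::wilcox.test(di[g], di[!g], alternative = "greater")$p.value)
        na_row$p_less <- suppressWarnings(
          stats::wilcox.test(di[g], di[!g], alternative = "less")$p.value)
      }
      na_row
    })
    res <- do.call(rbind, res)
    res$p_greater_bh <- stats::p.adjust(res$p_greater, method = "BH")
    res$p_less_bh <- stats::p.adjust(res$p_less, method = "BH")
    out[[mod]] <- res
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
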