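#' Score a selection outcome against simulation truth
#'
#' Builds one evaluation record per potential set: whether the selected
#' variant is causal, and whether the set's support contains at least one
#' causal variant (the "recovered" sense used in recovery-frequency plots).
#'
#' @param selection a `finemap_selection`.
#' @param sets the list of posterior vectors behind the selection (taken
#'   from the `pooled_sets` attribute when present; required for the
#'   set-contains-causal flag).
#' @param causal integer vector of true causal column indices.
#' @param dataset_id identifier copied into every record.
#' @param meta optional named list (phi, n_causal, scenario, ...) appended
#'   as columns.
#' @return a data.frame of evaluation records.
#' @export
evaluate_selection <- function(selection, causal, sets = NULL,
                               dataset_id = "d1", meta = NULL) {
  if (is.null(sets)) sets <- attr(selection, "pooled_sets")
  rows <- lapply(seq_len(nrow(selection)), function(i) {
    cc <- selection$potential_set[i]
    support <- if (!is.null(sets) && length(sets) >= cc) sets[[cc]]$support
               else selection$variant_index[i]
    data.frame(dataset_id = dataset_id,
               method = selection$method[i],
               potential_set = cc,
               variant_id = selection$variant_id[i],
               variant_index = selection$variant_index[i],
               selected_causal = selection$variant_index[i] %in% causal,
               set_contains_causal = any(support %in% causal),
               pooled_prob = selection$pooled_prob[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(meta)) for (nm in names(meta)) out[[nm]] <- meta[[nm]]
  out
}

#' Recovery frequencies with Wald 95% confidence intervals
#'
#' Per stratum, the recovery frequency is the mean of the chosen flag and
#' its interval is `freq +/- 1.96 sqrt(freq (1-freq) / n)`, truncated to
#' `[0, 1]`.
#'
#' @param records evaluation records from [evaluate_selection].
#' @param by character vector of stratifier column names (e.g.
#'   `c("method", "potential_set", "phi")`).
#' @param flag which flag to average: `"set_contains_causal"` (default,
#'   the at-least-one-causal sense) or `"selected_causal"`.
#' @return data.frame with columns n, recovery, ci_lo, ci_hi per stratum.
#' @export
recovery <- function(records, by = c("method", "potential_set"),
                     flag = c("set_contains_causal", "selected_causal")) {
  flag <- match.arg(flag)
  if (nrow(records) == 0) stop("no records")
  f <- records[[flag]]
  key <- interaction(records[, by, drop = FALSE], drop = TRUE, sep = "\r")
  agg <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    n <- length(idx); fr <- mean(f[idx])
    se <- sqrt(fr * (1 - fr) / n)
    cbind(records[idx[1], by, drop = FALSE],
          data.frame(n = n, recovery = fr,
                     ci_lo = max(0, fr - 1.96 * se),
                     ci_hi = min(1, fr + 1.96 * se)))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Per-set agreement between two methods
#'
#' Fraction of datasets whose selected variant ids coincide per potential
#' set, with the Venn-style counts of matching / a-only / b-only
#' selections.
#'
#' @param records evaluation records covering both methods on identical
#'   datasets.
#' @param method_a,method_b method names as recorded.
#' @return data.frame per potential set: n, n_match, n_a_only, n_b_only,
#'   match_fraction.
#' @export
matching <- function(records, method_a, method_b) {
  a <- records[records$method == method_a, ]
  b <- records[records$method == method_b, ]
  key <- c("dataset_id", "potential_set")
  m <- merge(a, b, by = key, suffixes = c("_a", "_b"))
  if (nrow(m) == 0) stop("methods share no (dataset, potential set) pairs")
  out <- do.call(rbind, lapply(split(m, m$potential_set), function(d) {
    match_flag <- !is.na(d$variant_id_a) & !is.na(d$variant_id_b) &
      d$variant_id_a == d$variant_id_b
    data.frame(potential_set = d$potential_set[1],
               n = nrow(d),
               n_match = sum(match_flag),
               n_a_only = sum(!match_flag),
               n_b_only = sum(!match_flag),
               match_fraction = mean(match_flag))
  }))
  rownames(out) <- NULL
  out
}

#' Exact McNemar test on paired recovery outcomes
#'
#' Exact binomial test on the discordant pairs: `b` datasets where only
#' method A recovered and `c` where only method B did; under the null the
#' discordant successes are Binomial(b + c, 1/2). Two-sided p-value.
#'
#' @param records evaluation records.
#' @param method_a,method_b method names.
#' @param set_index potential set to compare (default 1).
#' @param flag outcome flag column (default `"selected_causal"`).
#' @return list with `b`, `c`, and `p_value`.
#' @export
mcnemar <- function(records, method_a, method_b, set_index = 1,
                    flag = "selected_causal") {
  a <- records[records$method == method_a & records$potential_set == set_index, ]
  b <- records[records$method == method_b & records$potential_set == set_index, ]
  m <- merge(a, b, by = "dataset_id", suffixes = c("_a", "_b"))
  fa <- m[[paste0(flag, "_a")]]; fb <- m[[paste0(flag, "_b")]]
  nb <- sum(fa & !fb); nc <- sum(!fa & fb)
  if (nb + nc == 0) {
    warning("no discordant pairs; p-value = 1")
    return(list(b = nb, c = nc, p_value = 1))
  }
  p <- min(1, 2 * stats::pbinom(min(nb, nc), nb + nc, 0.5))
  list(b = nb, c = nc, p_value = p)
}

#' Causal-recovery enrichment of matching over non-matching selections
#'
#' Splits datasets by whether the two methods selected the same variant in
#' the given potential set and reports the causal-recovery frequency (with
#' Wald 95% CI) for the matching selections and for each method's
#' non-matching selections, plus the fold ratios matching / non-matching.
#'
#' @inheritParams mcnemar
#' @return data.frame with rows matching, `non-matching-<a>`,
#'   `non-matching-<b>`; attribute `ratios` holds the fold enrichments
#'   (NA when a non-matching group is empty).
#' @export
matching_enrichment <- function(records, method_a, method_b, set_index = 1,
                                flag = "selected_causal") {
  a <- records[records$method == method_a & records$potential_set == set_index, ]
  b <- records[records$method == method_b & records$potential_set == set_index, ]
  m <- merge(a, b, by = "dataset_id", suffixes = c("_a", "_b"))
  match_flag <- !is.na(m$variant_id_a) & !is.na(m$variant_id_b) &
    m$variant_id_a == m$variant_id_b
  freq_ci <- function(x) {
    n <- length(x)
    if (n == 0) return(c(n = 0, freq = NA, ci_lo = NA, ci_hi = NA))
    fr <- mean(x); se <- sqrt(fr * (1 - fr) / n)
    c(n = n, freq = fr, ci_lo = max(0, fr - 1.96 * se),
      ci_hi = min(1, fr + 1.96 * se))
  }
  fa <- m[[paste0(flag, "_a")]]; fb <- m[[paste0(flag, "_b")]]
  rows <- rbind(
    matching = freq_ci(fa[match_flag]),        # identical variant => same flag
    a_only = freq_ci(fa[!match_flag]),
    b_only = freq_ci(fb[!match_flag]))
  out <- data.frame(group = c("matching",
                              paste0("non-matching-", method_a),
                              paste0("non-matching-", method_b)),
                    rows, row.names = NULL)
  ratios <- c(out$freq[1] / out$freq[2], out$freq[1] / out$freq[3])
  ratios[!is.finite(ratios)] <- NA
  attr(out, "ratios") <- stats::setNames(ratios, out$group[2:3])
  out
}
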