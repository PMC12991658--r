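#' Residualize a phenotype on top genotype principal components
#'
#' Standard population-structure correction: the dosage matrix is
#' mean-centered by column (unscaled by default), its top `n_pcs` principal
#' components are computed, and the phenotype is regressed on an intercept
#' plus those components by least squares. The residuals are returned.
#' With `n_pcs = 0` this reduces to mean-centering the phenotype, which
#' leaves all correlation-based statistics unchanged.
#'
#' @param genotypes a [genotype_matrix].
#' @param phenotype numeric vector of length N.
#' @param n_pcs number of principal components to remove (default 5).
#' @param scale. also scale dosage columns to unit variance before the PCA
#'   (default `FALSE`).
#' @return numeric residual vector with attributes `residualized = TRUE`
#'   and `n_pcs_removed`.
#' @export
residualize <- function(genotypes, phenotype, n_pcs = 5, scale. = FALSE) {
  x <- genotypes$dosages
  if (n_pcs >= min(dim(x))) stop("n_pcs must be smaller than min(N, P)")
  if (n_pcs == 0) {
    res <- phenotype - mean(phenotype)
  } else {
    keep <- apply(x, 2, stats::sd) > 0
    pc <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = scale.)
    k <- min(n_pcs, ncol(pc$x))
    pcs <- pc$x[, seq_len(k), drop = FALSE]
    ok <- apply(pcs, 2, stats::sd) > 1e-12
    if (!all(ok)) {
      warning("dropping ", sum(!ok), " collinear principal component(s)")
      pcs <- pcs[, ok, drop = FALSE]
    }
    fit <- stats::lm.fit(cbind(1, pcs), phenotype)
    res <- as.numeric(fit$residuals)
  }
  attr(res, "residualized") <- TRUE
  attr(res, "n_pcs_removed") <- as.integer(n_pcs)
  res
}

#' Suggest a number of genotype PCs by the elbow rule
#'
#' Utility (not a default behaviour): returns the index of the largest drop
#' between consecutive eigenvalues of the genotype covariance.
#'
#' @param genotypes a [genotype_matrix].
#' @param max_pcs largest number of components considered.
#' @return an integer number of components.
#' @export
elbow_n_pcs <- function(genotypes, max_pcs = 20) {
  x <- genotypes$dosages
  keep <- apply(x, 2, stats::sd) > 0
  ev <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE)$sdev^2
  ev <- ev[seq_len(min(max_pcs + 1, length(ev)))]
  which.max(-diff(ev))
}

# ---- backend contract ------------------------------------------------------

#' Fine-mapper backends for the stability wrapper
#'
#' A backend is a function `(genotypes, phenotype, params) -> list of
#' posterior vectors` carrying a `support_rule` attribute: a pure predicate
#' `(probs, n_variants_included) -> logical` declaring which entries count
#' as "positive" for the stability rule. The permutation backend counts
#' `prob > 0`; the single-effect (SuSiE-style) backend counts
#' `PIP >= 1/n_variants_included`, since such fine-mappers tend to assign
#' nonzero probability to every included variant.
#'
#' @param L for `backend_susie`, the number of single effects (credible
#'   sets) to return (default 3).
#' @return a classed backend function.
#' @name backends
NULL

#' @rdname backends
#' @export
backend_pics <- function() {
  f <- function(genotypes, phenotype, params) pics(genotypes, phenotype, params)$sets
  structure(f, support_rule = function(probs, n_included) probs > 0,
            backend_name = "pics", class = c("finemap_backend", "function"))
}

#' @rdname backends
#' @export
backend_susie <- function(L = 3) {
  f <- function(genotypes, phenotype, params) {
    seed <- if (inherits(params, "pics_params")) params$seed else NULL
    ser_finemap(genotypes, phenotype, L = L, seed = seed)
  }
  structure(f, support_rule = function(probs, n_included) probs >= 1 / n_included,
            backend_name = "susie", class = c("finemap_backend", "function"))
}

# Minimal iterative Bayesian single-effect fine-mapper, shipped to exercise
# the backend contract with PIP-style (non-sparse) probability vectors. It
# is NOT a port of the reference variational SuSiE algorithm and makes no
# claim of numerical parity with it.
ser_finemap <- function(genotypes, phenotype, L = 3, n_iter = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- genotypes$dosages
  n <- nrow(x); p <- ncol(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  d <- colSums(xc^2)
  poly <- d > 0
  y <- phenotype - mean(phenotype)
  sigma2 <- stats::var(y)
  v0 <- max(0.2 * sigma2, 1e-6)
  alpha <- matrix(1 / p, L, p)
  mu <- matrix(0, L, p)
  for (it in seq_len(n_iter)) {
    for (l in seq_len(L)) {
      fitted_others <- as.numeric(xc %*% colSums(alpha[-l, , drop = FALSE] *
                                                 mu[-l, , drop = FALSE]))
      r <- y - fitted_others
      bhat <- ifelse(poly, as.numeric(crossprod(xc, r)) / pmax(d, 1e-12), 0)
      s2 <- sigma2 / pmax(d, 1e-12)
      lbf <- ifelse(poly,
                    0.5 * log(s2 / (s2 + v0)) + 0.5 * bhat^2 / s2 * v0 / (s2 + v0),
                    -Inf)
      a <- exp(lbf - max(lbf))
      alpha[l, ] <- a / sum(a)
      mu[l, ] <- ifelse(poly, v0 / (v0 + s2) * bhat, 0)
    }
  }
  lapply(seq_len(L), function(l) {
    probs <- alpha[l, ]
    posterior_vector(support = seq_len(p), probs = probs / sum(probs),
                     variant_ids = genotypes$variant_ids,
                     lead_index = which.max(probs))
  })
}

#' Filter a PIP vector by the prior-inclusion threshold
#'
#' Retains indices whose posterior inclusion probability is at least
#' `1/n_variants_included` (boundary inclusive) — the "good variant" rule
#' for PIP-style fine-mappers whose probability vectors are dense.
#'
#' @param pip_vector numeric PIPs.
#' @param n_variants_included number of variants included in the
#'   fine-mapping run.
#' @return integer indices of retained variants (possibly empty).
#' @export
susie_support_filter <- function(pip_vector, n_variants_included) {
  if (n_variants_included < 1) stop("n_variants_included must be >= 1")
  which(pip_vector >= 1 / n_variants_included)
}

# ---- selection strategies --------------------------------------------------

selection_outcome <- function(rows, method, params = NULL) {
  df <- do.call(rbind, rows)
  df$method <- method
  attr(df, "params") <- params
  class(df) <- c("finemap_selection", "data.frame")
  df
}

#' @export
print.finemap_selection <- function(x, ...) {
  cat(sprintf("finemap_selection (%s): %d potential set(s)\n",
              x$method[1], nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

set_argmax_row <- function(pv, set_idx, positions) {
  i <- best_index(pv$probs, positions[pv$support], pv$variant_ids)
  data.frame(potential_set = set_idx,
             variant_id = pv$variant_ids[i],
             variant_index = pv$support[i],
             pooled_prob = pv$probs[i],
             support_count = NA_integer_,
             in_yri_support = NA,
             stringsAsFactors = FALSE)
}

#' Plain selection: per-set argmax of the pooled posterior
#'
#' The "plain" strategy neither residualizes the phenotype nor uses
#' stability: for each potential set it reports the variant with the
#' maximum pooled posterior probability (ties broken by smallest position,
#' then id).
#'
#' @param fit a [pics] object (or list of posterior vectors).
#' @param positions variant positions for tie-breaking; taken from the fit
#'   when available.
#' @return a `finemap_selection` data.frame.
#' @export
plain_select <- function(fit, positions = NULL) {
  sets <- if (inherits(fit, "pics")) fit$sets else fit
  if (is.null(positions))
    positions <- if (inherits(fit, "pics")) fit$positions
                 else seq_len(max(unlist(lapply(sets, `[[`, "support"))))
  rows <- lapply(seq_along(sets), function(cc)
    set_argmax_row(sets[[cc]], cc, positions))
  selection_outcome(rows, "plain")
}

#' Top-variant selection: fine-map the PC-residualized phenotype
#'
#' Runs the backend on the phenotype residualized on the top `n_pcs`
#' genotype principal components and reports the per-set argmax — the
#' standard residualization approach to population-structure correction.
#'
#' @param genotypes a [genotype_matrix].
#' @param phenotype numeric phenotype vector.
#' @param backend a backend from [backend_pics()] or [backend_susie()].
#' @param params a [pics_params] object.
#' @param n_pcs number of PCs removed before fine-mapping (default 5).
#' @return a `finemap_selection` data.frame.
#' @export
top_select <- function(genotypes, phenotype, backend = backend_pics(),
                       params = pics_params(), n_pcs = 5) {
  yr <- residualize(genotypes, phenotype, n_pcs = n_pcs)
  sets <- backend(genotypes, yr, params)
  rows <- lapply(seq_along(sets), function(cc)
    set_argmax_row(sets[[cc]], cc, genotypes$positions))
  out <- selection_outcome(rows, "top", params = list(n_pcs = n_pcs))
  attr(out, "n_pcs_removed") <- as.integer(n_pcs)
  out
}

#' Stability-guided selection across subpopulation slices
#'
#' Runs the backend on the pooled (unresidualized) data and once per
#' subpopulation slice, then applies the two-stage stability rule per
#' potential set: among variants with positive probability (per the
#' backend's support rule) in the pooled vector, keep those whose count of
#' positive appearances across all available vectors (pooled + slices) is
#' maximal, and report the one with the largest pooled probability.
#'
#' @param genotypes a [genotype_matrix] with population labels (or pass
#'   `labels`).
#' @param phenotype numeric phenotype vector.
#' @param labels optional length-N population labels overriding those in
#'   `genotypes`.
#' @param backend a backend function.
#' @param params a [pics_params]; slice runs derive their seeds from
#'   `params$seed` so the whole procedure is reproducible.
#' @param min_slice slices with fewer samples are skipped with a warning
#'   (default 3).
#' @param yri_label label identifying the distal (Yoruban) slice for the
#'   `in_yri_support` flag.
#' @return a `finemap_selection` data.frame with `support_count` and
#'   `in_yri_support` filled; the pooled and slice posterior vectors are
#'   attached as attributes `pooled_sets` and `slice_sets`.
#' @export
stable_select <- function(genotypes, phenotype, labels = NULL,
                          backend = backend_pics(), params = pics_params(),
                          min_slice = 3, yri_label = "YRI") {
  if (is.null(labels)) labels <- genotypes$population_labels
  if (is.null(labels)) stop("population labels are required for stability selection")
  pops <- unique(labels)
  sizes <- table(labels)[pops]
  small <- pops[sizes < min_slice]
  if (length(small) > 0) {
    warning("skipping slice(s) with < ", min_slice, " samples: ",
            paste(small, collapse = ", "))
    pops <- setdiff(pops, small)
  }
  if (length(pops) < 1) stop("need at least one usable slice")

  run_params <- function(offset) {
    if (is.null(params$seed)) return(params)
    p2 <- params; p2$seed <- (params$seed + offset) %% .Machine$integer.max; p2
  }
  pooled_sets <- backend(genotypes, phenotype, run_params(0L))
  slice_sets <- lapply(seq_along(pops), function(k) {
    idx <- which(labels == pops[k])
    backend(subset_samples(genotypes, idx), phenotype[idx], run_params(k))
  })
  names(slice_sets) <- pops

  out <- stable_rule(pooled_sets, slice_sets,
                     support_rule = attr(backend, "support_rule"),
                     positions = genotypes$positions,
                     yri_label = yri_label)
  out
}

#' Apply the two-stage stability rule to given posterior vectors
#'
#' Exposed separately so the rule can be applied to externally computed
#' probability vectors. `pooled_sets` is a list of posterior vectors (one
#' per potential set); `slice_sets` is a named list of such lists, one per
#' slice. A slice that returned fewer than `c` sets contributes no vector
#' for set `c` (counts run over available vectors only).
#'
#' @param pooled_sets list of posterior vectors from the pooled run.
#' @param slice_sets named list (one per slice) of lists of posterior
#'   vectors.
#' @param support_rule predicate `(probs, n_included) -> logical`; default
#'   is strict positivity.
#' @param positions variant positions for tie-breaking.
#' @param yri_label name of the distal slice for the `in_yri_support` flag.
#' @return a `finemap_selection` data.frame (method "stable").
#' @export
stable_rule <- function(pooled_sets, slice_sets,
                        support_rule = function(probs, n_included) probs > 0,
                        positions = NULL, yri_label = "YRI") {
  rows <- lapply(seq_along(pooled_sets), function(cc) {
    pv <- pooled_sets[[cc]]
    n_inc <- length(pv$support)
    pos_pool <- support_rule(pv$probs, n_inc)
    vecs <- list()
    for (s in names(slice_sets)) {
      if (length(slice_sets[[s]]) >= cc) vecs[[s]] <- slice_sets[[s]][[cc]]
    }
    # count positive appearances across pooled + available slice vectors
    count_for <- function(v_index, v_id) {
      cnt <- 1L   # positive in the pooled vector by construction of S_c
      for (s in names(vecs)) {
        sv <- vecs[[s]]
        j <- match(v_id, sv$variant_ids)
        if (!is.na(j) && support_rule(sv$probs, length(sv$support))[j])
          cnt <- cnt + 1L
      }
      cnt
    }
    cand <- which(pos_pool)
    if (length(cand) == 0L) {
      return(data.frame(potential_set = cc, variant_id = NA_character_,
                        variant_index = NA_integer_, pooled_prob = NA_real_,
                        support_count = NA_integer_, in_yri_support = NA,
                        stringsAsFactors = FALSE))
    }
    counts <- vapply(cand, function(i)
      count_for(pv$support[i], pv$variant_ids[i]), integer(1))
    s_c <- cand[counts == max(counts)]
    pos_vec <- if (is.null(positions)) pv$support else positions[pv$support]
    i <- s_c[best_index(pv$probs[s_c], pos_vec[s_c], pv$variant_ids[s_c])]
    in_yri <- NA
    if (yri_label %in% names(vecs)) {
      sv <- vecs[[yri_label]]
      j <- match(pv$variant_ids[i], sv$variant_ids)
      in_yri <- !is.na(j) && support_rule(sv$probs, length(sv$support))[j]
    }
    data.frame(potential_set = cc,
               variant_id = pv$variant_ids[i],
               variant_index = pv$support[i],
               pooled_prob = pv$probs[i],
               support_count = max(counts),
               in_yri_support = in_yri,
               stringsAsFactors = FALSE)
  })
  out <- selection_outcome(rows, "stable")
  attr(out, "pooled_sets") <- pooled_sets
  attr(out, "slice_sets") <- slice_sets
  out
}

#' Combined selection: stability guidance on the residualized phenotype
#'
#' Identical to [stable_select] with the phenotype first residualized on
#' the top `n_pcs` genotype principal components.
#'
#' @inheritParams stable_select
#' @param n_pcs number of PCs removed (default 5).
#' @return a `finemap_selection` data.frame (method "combined").
#' @export
combined_select <- function(genotypes, phenotype, labels = NULL,
                            backend = backend_pics(), params = pics_params(),
                            n_pcs = 5, min_slice = 3, yri_label = "YRI") {
  yr <- residualize(genotypes, phenotype, n_pcs = n_pcs)
  out <- stable_select(genotypes, yr, labels = labels, backend = backend,
                       params = params, min_slice = min_slice,
                       yri_label = yri_label)
  out$method <- "combined"
  attr(out, "n_pcs_removed") <- as.integer(n_pcs)
  out
}
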