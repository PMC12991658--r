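test_that("residualization removes exactly the PC-spanned signal", {
  set.seed(1)
  g <- synth_genotypes(n_variants = 30, seed = 1)
  x <- g$dosages
  pc <- prcomp(x, center = TRUE)

  # phenotype equal to PC1 -> residual is the zero vector
  y_pc1 <- pc$x[, 1]
  r1 <- residualize(g, y_pc1, n_pcs = 5)
  expect_lt(max(abs(r1)), 1e-10)

  # mean-zero phenotype orthogonal to the top PCs passes through unchanged
  y_orth <- residuals(lm(rnorm(nrow(x)) ~ pc$x[, 1:5]))
  r2 <- residualize(g, y_orth, n_pcs = 5)
  expect_equal(as.numeric(r2), as.numeric(y_orth), tolerance = 1e-10)

  # residuals are orthogonal to every retained PC, and the flag is set
  y <- rnorm(nrow(x))
  r3 <- residualize(g, y, n_pcs = 5)
  for (k in 1:5) expect_lt(abs(sum(r3 * pc$x[, k])), 1e-8)
  expect_true(attr(r3, "residualized"))
  expect_equal(attr(r3, "n_pcs_removed"), 5L)

  # idempotence
  r4 <- residualize(g, as.numeric(r3), n_pcs = 5)
  expect_lt(max(abs(r4 - r3)), 1e-10)

  expect_error(residualize(gm(matrix(c(0, 1, 2), 3, 4)), rnorm(3), n_pcs = 5),
               "n_pcs")
})

test_that("plain selection is the per-set pooled argmax", {
  pooled <- as_pv_list(list(c(0.45, 0.43, 0.02, 0.10, 0.00)))
  sel <- plain_select(pooled, positions = 1:5)
  expect_equal(sel$variant_id, "A1")
  expect_equal(sel$pooled_prob, 0.45)

  single <- as_pv_list(list(c(1)))
  expect_equal(plain_select(single, positions = 1)$variant_id, "A1")

  set.seed(2)
  for (i in 1:20) {
    v <- runif(8); v <- v / sum(v)
    sel <- plain_select(as_pv_list(list(v)), positions = 1:8)
    expect_equal(sel$variant_index, which.max(v))
  }
})

test_that("the worked stability example selects A2 with pooled probability 0.43", {
  pooled <- as_pv_list(list(c(0.45, 0.43, 0.02, 0.10, 0.00)))
  slices <- list(E1 = as_pv_list(list(c(0.00, 0.40, 0.10, 0.25, 0.25))),
                 E2 = as_pv_list(list(c(0.20, 0.60, 0.00, 0.10, 0.10))))
  sel <- stable_rule(pooled, slices)
  expect_equal(sel$variant_id, "A2")
  expect_equal(sel$pooled_prob, 0.43)
  expect_equal(sel$support_count, 3L)   # pooled + both slices

  # S_1 = {A2, A4}: both appear in all three vectors
  oracle <- brute_stable(c(0.45, 0.43, 0.02, 0.10, 0.00),
                         list(c(0.00, 0.40, 0.10, 0.25, 0.25),
                              c(0.20, 0.60, 0.00, 0.10, 0.10)))
  expect_equal(oracle$S, c(2L, 4L))
  expect_equal(oracle$variant, 2L)
})

test_that("the stability rule matches a brute-force two-stage filter on random vectors", {
  set.seed(3)
  for (i in 1:100) {
    sparsify <- function() {
      v <- runif(6) * rbinom(6, 1, 0.6)
      if (sum(v) == 0) v[sample(6, 1)] <- 1
      v / sum(v)
    }
    pooled_v <- sparsify()
    s1 <- sparsify(); s2 <- sparsify()
    sel <- stable_rule(as_pv_list(list(pooled_v)),
                       list(E1 = as_pv_list(list(s1)),
                            E2 = as_pv_list(list(s2))))
    oracle <- brute_stable(pooled_v, list(s1, s2))
    expect_equal(sel$variant_index, oracle$variant)
    expect_equal(sel$pooled_prob, oracle$prob)
    expect_equal(sel$support_count, oracle$count)
  }
})

test_that("stable selection reduces to plain when every slice equals the pooled data", {
  pooled <- as_pv_list(list(c(0.5, 0.3, 0.2), c(0.9, 0.1, 0)))
  sel_stable <- stable_rule(pooled, list(E1 = pooled))
  sel_plain <- plain_select(pooled, positions = 1:3)
  expect_equal(sel_stable$variant_id, sel_plain$variant_id)
  expect_equal(sel_stable$pooled_prob, sel_plain$pooled_prob)
})

test_that("stable variant lies in the pooled support with maximal support count", {
  set.seed(4)
  for (s in 1:5) {
    g <- synth_genotypes(n_per_pop = rep(30, 5), n_variants = 20,
                         seed = 40 + s)
    sim <- simulate_phenotype(g, simulation_spec(phi = 0.3, seed = 50 + s))
    sel <- stable_select(g, sim$values, params = pics_params(R = 60, seed = s))
    pooled <- attr(sel, "pooled_sets")
    slices <- attr(sel, "slice_sets")
    for (i in seq_len(nrow(sel))) {
      cc <- sel$potential_set[i]
      pv <- pooled[[cc]]
      expect_true(sel$variant_index[i] %in% pv$support)
      # recompute support counts for every pooled-supported variant
      counts <- sapply(seq_along(pv$support), function(j) {
        cnt <- as.integer(pv$probs[j] > 0)
        for (sl in slices) {
          if (length(sl) >= cc) {
            k <- match(pv$variant_ids[j], sl[[cc]]$variant_ids)
            if (!is.na(k) && sl[[cc]]$probs[k] > 0) cnt <- cnt + 1L
          }
        }
        cnt
      })
      expect_equal(sel$support_count[i], max(counts[pv$probs > 0]))
      expect_true(sel$support_count[i] >= 1 &&
                  sel$support_count[i] <= length(slices) + 1)
    }
  }
})

test_that("top selection with zero PCs reproduces plain selection", {
  g <- synth_genotypes(n_variants = 15, seed = 5)
  sim <- simulate_phenotype(g, simulation_spec(phi = 0.3, seed = 5))
  params <- pics_params(R = 60, seed = 99)
  sel_plain <- plain_select(pics(g, sim$values, params))
  sel_top0 <- top_select(g, sim$values, params = params, n_pcs = 0)
  expect_equal(sel_top0$variant_id, sel_plain$variant_id)
  expect_equal(sel_top0$pooled_prob, sel_plain$pooled_prob)

  # determinism given seed
  sel_a <- top_select(g, sim$values, params = params, n_pcs = 5)
  sel_b <- top_select(g, sim$values, params = params, n_pcs = 5)
  expect_identical(sel_a$variant_id, sel_b$variant_id)
  expect_identical(sel_a$pooled_prob, sel_b$pooled_prob)
})

test_that("top and plain variants usually coincide when structure is uninformative", {
  agree <- 0
  for (s in 1:20) {
    g <- synth_genotypes(n_per_pop = rep(30, 5), n_variants = 15,
                         fst_like_drift = 0, seed = 400 + s)
    sim <- simulate_phenotype(g, simulation_spec(n_causal = 1, phi = 0.4,
                                                 seed = 500 + s))
    params <- pics_params(R = 60, C = 1, seed = s)
    vp <- plain_select(pics(g, sim$values, params))$variant_id[1]
    vt <- top_select(g, sim$values, params = params, n_pcs = 5)$variant_id[1]
    if (identical(vp, vt)) agree <- agree + 1
  }
  expect_gte(agree, 18)
})

test_that("combined selection is stable selection on the residualized phenotype", {
  g <- synth_genotypes(n_per_pop = rep(25, 5), n_variants = 15, seed = 6)
  sim <- simulate_phenotype(g, simulation_spec(phi = 0.3, seed = 6))
  params <- pics_params(R = 60, seed = 7)

  # n_pcs = 0 on a centered phenotype gives exactly stable_select
  y_centered <- sim$values - mean(sim$values)
  sc0 <- combined_select(g, sim$values, params = params, n_pcs = 0)
  ss <- stable_select(g, y_centered, params = params)
  expect_equal(sc0$variant_id, ss$variant_id)
  expect_equal(sc0$pooled_prob, ss$pooled_prob)
  expect_equal(sc0$method[1], "combined")
  expect_equal(attr(sc0, "n_pcs_removed"), 0L)

  sc5 <- combined_select(g, sim$values, params = params, n_pcs = 5)
  expect_equal(attr(sc5, "n_pcs_removed"), 5L)
  expect_equal(unique(sc5$method), "combined")
})

test_that("combined with a single uninformative slice equals top selection", {
  g <- synth_genotypes(n_per_pop = rep(25, 5), n_variants = 15, seed = 8)
  g$population_labels <- rep("ALL", nrow(g$dosages))   # K = 1, same as pooled
  sim <- simulate_phenotype(g, simulation_spec(phi = 0.3, seed = 8,
                                               scenario = "homogeneous"))
  params <- pics_params(R = 60, seed = 11)
  sel_comb <- combined_select(g, sim$values, params = params, n_pcs = 5)
  sel_top <- top_select(g, sim$values, params = params, n_pcs = 5)
  expect_equal(sel_comb$variant_id, sel_top$variant_id)
})

test_that("PIP support filter retains variants at or above 1/n_included", {
  expect_equal(susie_support_filter(rep(0.2, 5), 5), 1:5)   # boundary inclusive
  expect_equal(susie_support_filter(c(0.5, 0.3, 0.1, 0.05, 0.05), 5), 1:2)
  expect_length(susie_support_filter(c(0.1, 0.15), 2), 0)
  expect_error(susie_support_filter(c(0.5), 0), "n_variants_included")
})

test_that("the SuSiE-style backend honours the contract and the PIP support rule", {
  set.seed(9)
  g <- synth_genotypes(n_per_pop = rep(30, 5), n_variants = 20, ld_rho = 0,
                       fst_like_drift = 0, seed = 9)
  sim <- simulate_phenotype(g, simulation_spec(n_causal = 1, phi = 0.5,
                                               seed = 9))
  be <- backend_susie(L = 2)
  sets <- be(g, sim$values, pics_params(seed = 9))
  expect_length(sets, 2)
  for (pv in sets) {
    expect_true(all(pv$probs >= 0))
    expect_equal(sum(pv$probs), 1, tolerance = 1e-9)
  }
  # the strong causal variant dominates the first single effect
  expect_equal(which.max(sets[[1]]$probs), sim$causal)

  rule <- attr(be, "support_rule")
  kept <- which(rule(sets[[1]]$probs, length(sets[[1]]$support)))
  expect_equal(kept, susie_support_filter(sets[[1]]$probs,
                                          length(sets[[1]]$support)))

  # the stability wrapper runs end-to-end with the PIP rule
  sel <- stable_select(g, sim$values, backend = be,
                       params = pics_params(seed = 9))
  expect_equal(nrow(sel), 2L)
  expect_false(anyNA(sel$variant_id))

  # an empty filtered support yields no stable variant for that set
  degen <- as_pv_list(list(c(0.6, 0.4)))
  sel2 <- stable_rule(degen, list(E1 = degen),
                      support_rule = function(p, n) p >= 0.99)
  expect_true(is.na(sel2$variant_id[1]))
})

test_that("small slices are skipped with a warning", {
  g <- synth_genotypes(n_per_pop = rep(20, 5), n_variants = 10, seed = 10)
  labels <- g$population_labels
  labels[1:2] <- "TINY"
  labels[labels == "TSI"] <- "CEU"
  sim <- simulate_phenotype(g, simulation_spec(phi = 0.3, seed = 10,
                                               scenario = "homogeneous"))
  expect_warning(
    sel <- stable_select(g, sim$values, labels = labels,
                         params = pics_params(R = 40, seed = 3)),
    "TINY")
  expect_false("TINY" %in% names(attr(sel, "slice_sets")))
})
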