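test_that("marginal association is squared correlation with sane edge cases", {
  set.seed(1)
  g <- synth_genotypes(n_variants = 15, seed = 1)
  x <- g$dosages

  # variant identical to the phenotype up to an affine map -> r^2 = 1
  y <- 3 * x[, 4] - 2
  a <- marginal_assoc(g, y)
  expect_equal(unname(a[4]), 1.0, tolerance = 1e-12)

  # phenotype independent of a variant: statistic near 0 for most seeds
  stats_null <- replicate(100, {
    yy <- rnorm(nrow(x))
    unname(marginal_assoc(g, yy)[1])
  })
  expect_gte(mean(stats_null < 0.02), 0.90)

  # ranking by r^2 equals ranking by the simple-regression F statistic
  y2 <- rnorm(nrow(x)) + 0.4 * x[, 2]
  a2 <- marginal_assoc(g, y2)
  fstat <- apply(x, 2, function(col) {
    if (sd(col) == 0) return(0)
    summary(lm(y2 ~ col))$fstatistic[1]
  })
  expect_equal(order(a2, decreasing = TRUE), order(fstat, decreasing = TRUE))

  # degenerate inputs
  expect_error(marginal_assoc(g, rep(1, nrow(x))), "constant phenotype")
  g_mono <- gm(matrix(1, 5, 2))
  expect_error(marginal_assoc(g_mono, rnorm(5)), "polymorphic")
})

test_that("lead SNP is the argmax with position-then-id tie breaking", {
  expect_equal(lead_snp(c(0.1, 0.9, 0.3)), 2L)
  expect_equal(lead_snp(c(0.5, 0.5), positions = c(200, 100)), 2L)
  expect_equal(lead_snp(c(0.5, 0.5), positions = c(100, 100),
                        variant_ids = c("b", "a")), 2L)
  expect_warning(i <- lead_snp(c(0, 0, 0), positions = c(3, 1, 2)), "zero")
  expect_equal(i, 2L)
  set.seed(42)
  for (rep in 1:10) {
    v <- runif(50)
    expect_equal(lead_snp(v), which.max(v))
  }
})

test_that("neighbourhood matches a brute-force pairwise correlation filter", {
  g <- gm(cbind(c(0, 0, 1, 1, 2, 2), c(0, 0, 1, 1, 2, 2), c(2, 1, 0, 2, 1, 0)))
  nb <- neighborhood(g, lead = 1, r_threshold = 0.5)
  expect_true(2 %in% nb)   # duplicated column of the lead is included
  expect_true(1 %in% nb)   # the lead is always its own neighbour

  set.seed(7)
  g2 <- synth_genotypes(n_variants = 30, ld_block_size = 10, ld_rho = 0.9,
                        seed = 7)
  lead <- 15
  nb2 <- neighborhood(g2, lead, 0.5)
  brute <- which(sapply(seq_len(30), function(k) {
    r <- suppressWarnings(cor(g2$dosages[, k], g2$dosages[, lead]))
    !is.na(r) && r^2 > 0.25
  }))
  expect_equal(nb2, sort(unique(c(lead, brute))))

  # isolated lead
  g3 <- gm(cbind(c(0, 1, 0, 1, 0, 1), c(1, 1, 0, 0, 1, 0), c(0, 0, 1, 1, 1, 0)))
  expect_equal(neighborhood(g3, 1, 0.99), 1L)
})

test_that("constrained permutations shuffle rows only within focal-dosage strata", {
  x <- matrix(c(0, 0, 1, 1,
                5, 6, 7, 8), ncol = 2)   # second column tags the rows
  g <- gm(cbind(x[, 1], x[, 1]))
  set.seed(1)
  for (i in 1:50) {
    perm <- constrained_permutation(g, focal = 1)
    expect_setequal(perm[1:2], 1:2)      # rows 1-2 stay among themselves
    expect_setequal(perm[3:4], 3:4)
    expect_identical(g$dosages[perm, 1], g$dosages[, 1])  # focal column fixed
  }

  # constant focal column: permutation ranges over all N! orders
  gc <- gm(cbind(rep(1, 4), c(0, 1, 2, 0)))
  set.seed(2)
  seen <- unique(replicate(500, paste(constrained_permutation(gc, 1),
                                      collapse = ",")))
  expect_equal(length(seen), factorial(4))
})

test_that("the constrained group with strata (3,2,1) has exactly 12 uniform elements", {
  focal <- c(0, 0, 0, 1, 1, 2)
  g <- gm(cbind(focal, rnorm_dosages <- sample(0:2, 6, TRUE)))
  all_perms <- enumerate_strata_perms(focal)
  expect_equal(length(all_perms), factorial(3) * factorial(2) * factorial(1))

  set.seed(3)
  draws <- replicate(10000, paste(constrained_permutation(g, 1), collapse = ","))
  tab <- table(factor(draws, levels = sapply(all_perms, paste, collapse = ",")))
  expect_equal(length(tab), 12L)
  expect_true(all(tab > 0))
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("constrained permutations exactly preserve focal column, rows, and LD", {
  set.seed(4)
  g <- synth_genotypes(n_per_pop = c(8, 8, 8, 8, 8), n_variants = 12, seed = 4)
  x <- g$dosages
  base_cor <- cor(x)
  for (i in 1:200) {
    focal <- sample(12, 1)
    perm <- constrained_permutation(g, focal)
    xp <- x[perm, ]
    expect_identical(xp[, focal], x[, focal])
    expect_identical(xp[order(perm), ], x)      # row multiset preserved
    expect_equal(cor(xp), base_cor, tolerance = 1e-12)
  }
})

test_that("Monte-Carlo posterior agrees with exhaustive enumeration on a tiny locus", {
  # 6 samples, 4 variants; focal strata small enough to enumerate
  x <- cbind(c(0, 0, 1, 1, 2, 2),
             c(0, 1, 1, 1, 2, 2),
             c(0, 0, 1, 2, 2, 2),
             c(2, 2, 1, 1, 0, 0))
  g <- gm(x)
  y <- c(0.1, 0.3, 1.1, 0.9, 2.2, 1.8)
  assoc <- marginal_assoc(g, y)
  lead <- lead_snp(assoc, g$positions, g$variant_ids)
  nbhd <- neighborhood(g, lead, 0.5)
  expect_gt(length(nbhd), 1)

  oracle <- exhaustive_pics_posterior(g, y, lead, nbhd)
  set.seed(5)
  R <- 5000
  pv <- pics_posterior(g, y, lead, pics_params(R = R), nbhd = nbhd)
  win_mc <- attr(pv, "win_fractions")
  se <- sqrt(pmax(oracle$win * (1 - oracle$win), 0.25 / R) / R)
  expect_true(all(abs(win_mc - oracle$win) <= 3 * se + 1e-12))
  expect_equal(pv$probs, oracle$posterior, tolerance = 0.05)
})

test_that("posterior vectors are normalized probability distributions", {
  set.seed(6)
  for (s in 1:5) {
    g <- synth_genotypes(n_variants = 25, seed = s)
    y <- simulate_phenotype(g, simulation_spec(phi = 0.2, seed = s))$values
    fit <- pics(g, y, pics_params(R = 80, seed = s))
    for (pv in fit$sets) {
      expect_true(all(pv$probs >= 0))
      expect_equal(sum(pv$probs), 1, tolerance = 1e-9)
      expect_true(pv$lead_index %in% pv$support)
    }
    # supports pairwise disjoint
    sup <- lapply(fit$sets, `[[`, "support")
    expect_equal(length(unlist(sup)), length(unique(unlist(sup))))
  }
})

test_that("the potential-set loop removes neighbourhoods and stops when exhausted", {
  # 3 variants in mutual high LD -> a single potential set even with C = 3
  base <- c(0, 0, 0, 1, 1, 1, 2, 2, 2)
  x <- cbind(base, base, c(0, 0, 1, 1, 1, 1, 2, 2, 2))
  g <- gm(x)
  y <- base + rnorm(9, sd = 0.1)
  set.seed(8)
  fit <- pics(g, y, pics_params(R = 50, C = 3, seed = 8))
  expect_equal(length(fit$sets), 1L)
  expect_setequal(fit$sets[[1]]$support, 1:3)

  # a single strong causal variant with no LD lands on top of set 1
  hits <- 0
  for (s in 1:20) {
    g2 <- synth_genotypes(n_per_pop = rep(40, 5), n_variants = 12,
                          ld_rho = 0, fst_like_drift = 0, seed = 200 + s)
    sim <- simulate_phenotype(g2, simulation_spec(n_causal = 1, phi = 0.45,
                                                  seed = 300 + s))
    fit2 <- pics(g2, sim$values, pics_params(R = 100, C = 1, seed = s))
    pv <- fit2$sets[[1]]
    in_support <- sim$causal %in% pv$support
    top <- pv$support[which.max(pv$probs)]
    if (in_support && top == sim$causal) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("pics is reproducible given a seed and invariant to prior rescaling", {
  g <- synth_genotypes(n_variants = 20, seed = 9)
  y <- simulate_phenotype(g, simulation_spec(phi = 0.3, seed = 9))$values
  f1 <- pics(g, y, pics_params(R = 60, seed = 123))
  f2 <- pics(g, y, pics_params(R = 60, seed = 123))
  expect_identical(as.data.frame(f1), as.data.frame(f2))

  p0 <- rep(1, 20)
  f3 <- pics(g, y, pics_params(R = 60, seed = 123, prior = p0))
  f4 <- pics(g, y, pics_params(R = 60, seed = 123, prior = 7.3 * p0))
  expect_equal(as.data.frame(f3)$prob, as.data.frame(f4)$prob, tolerance = 1e-12)
  expect_equal(order(coef(f3)), order(coef(f4)))

  # singleton neighbourhood forces a point-mass posterior
  pv <- pics_posterior(gm(cbind(c(0, 1, 2, 0, 1), c(1, 0, 1, 0, 1))),
                       c(0, 1, 2, 0, 1), lead = 1,
                       pics_params(R = 10), nbhd = 1L)
  expect_equal(pv$probs, 1.0)
})
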