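#' Draw sparse causal effects for a locus
#'
#' Causal indices are sampled uniformly without replacement; effects on the
#' causal set are independent Normal(0, `effect_sd`^2) and zero elsewhere.
#'
#' @param P number of variants at the locus.
#' @param n_causal number of causal variants.
#' @param effect_sd standard deviation of causal effect sizes (default 0.6).
#' @param maf optional vector of P allele frequencies; with `min_maf > 0`,
#'   causal indices are drawn among variants with `min(maf, 1-maf) >=
#'   min_maf` to avoid degenerate monomorphic picks.
#' @param min_maf minor-allele-frequency floor for eligible causal variants
#'   (default 0.01; set 0 to disable).
#' @return list with `causal` (sorted indices) and `effects` (length P).
#' @export
draw_effects <- function(P, n_causal, effect_sd = 0.6,
                         maf = NULL, min_maf = 0.01) {
  if (n_causal > P) stop("n_causal must be <= P")
  eligible <- seq_len(P)
  if (!is.null(maf) && min_maf > 0) {
    ok <- pmin(maf, 1 - maf) >= min_maf
    if (sum(ok) >= n_causal) eligible <- which(ok)
  }
  causal <- sort(sample(eligible, n_causal))
  b <- numeric(P)
  b[causal] <- stats::rnorm(n_causal, 0, effect_sd)
  list(causal = causal, effects = b)
}

#' Exogenous variance achieving a target proportion of variance explained
#'
#' Solves `phi = var(Xb) / (var(Xb) + sigma2)` for `sigma2`, i.e.
#' `sigma2 = var(Xb) (1 - phi) / phi`, where `var` is the empirical
#' variance (denominator N-1) of the genetic values across samples. The
#' implied signal-to-noise ratio is `var(Xb)/sigma2 = phi/(1-phi)`.
#'
#' @param genotypes a [genotype_matrix].
#' @param effects length-P effect vector b.
#' @param phi target proportion of variance explained, in (0,1).
#' @return the scalar `sigma2`.
#' @export
sigma2_for_phi <- function(genotypes, effects, phi) {
  if (phi <= 0 || phi >= 1) stop("phi must be in (0,1)")
  g <- as.numeric(genotypes$dosages %*% effects)
  vg <- stats::var(g)
  if (vg == 0) stop("var(Xb) is zero (degenerate signal: monomorphic causal variants)")
  vg * (1 - phi) / phi
}

#' Signal-to-noise ratio implied by a proportion of variance explained
#' @param phi proportion of variance explained in (0,1).
#' @return `phi / (1 - phi)`.
#' @export
snr_from_phi <- function(phi) phi / (1 - phi)

#' Exponentiated population-size proportions
#'
#' `alpha_POP(t) = N_POP^t / sum_POP' N_POP'^t`, computed in log space so
#' large exponents (t = 128, 256) do not overflow. `t = 0` gives the
#' uniform vector; as `t` grows the mass concentrates on the largest
#' subpopulation.
#'
#' @param t nonnegative exponent.
#' @param pop_sizes named vector of subpopulation sizes; default is the
#'   (TSI, GBR, FIN, CEU, YRI) = (91, 86, 92, 89, 87) cohort composition.
#' @return vector of proportions summing to 1, named by population.
#' @export
alpha_weights <- function(t, pop_sizes = c(TSI = 91, GBR = 86, FIN = 92,
                                           CEU = 89, YRI = 87)) {
  if (t < 0) stop("t must be >= 0")
  lw <- t * log(pop_sizes)
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Scenario definitions for environmental heterogeneity
#'
#' The homogeneous scenario draws i.i.d. noise Normal(0, sigma2). Variance
#' heterogeneity (`"t=8"`, `"t=16"`, `"t=128"`, `"t=256"`) replaces the
#' common variance with population-specific variances
#' `sigma2(t) = 5 sigma2 alpha(t)`; `t = 0` reproduces the homogeneous
#' setup exactly. Mean heterogeneity keeps the common variance but shifts
#' the noise mean by population: `"smooth_mean"` uses
#' `mu = (2 sigma, 0, sigma, sigma, 2 sigma)` and `"spiked_mean"` uses
#' `mu = (0, 2 sigma, 0, 0, 0)`, in population order (TSI, GBR, FIN, CEU,
#' YRI), with `sigma = sqrt(sigma2)`.
#'
#' @name scenarios
NULL

scenario_levels <- c("homogeneous", "t=0", "t=8", "t=16", "t=128", "t=256",
                     "smooth_mean", "spiked_mean")
pop_order <- c("TSI", "GBR", "FIN", "CEU", "YRI")

#' Specify a phenotype simulation
#'
#' @param n_causal number of causal variants.
#' @param phi proportion of variance explained, in (0,1).
#' @param effect_sd causal effect SD (default 0.6).
#' @param scenario one of `"homogeneous"`, `"t=0"`, `"t=8"`, `"t=16"`,
#'   `"t=128"`, `"t=256"`, `"smooth_mean"`, `"spiked_mean"`.
#' @param window_bp cis window half-width (default 1 Mb); used by callers
#'   that restrict a locus before simulating.
#' @param min_maf MAF floor for causal-variant eligibility (default 0.01).
#' @param seed integer seed.
#' @return a list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_causal = 1, phi = 0.1, effect_sd = 0.6,
                            scenario = "homogeneous", window_bp = 1e6,
                            min_maf = 0.01, seed = NULL) {
  scenario <- match.arg(scenario, scenario_levels)
  if (phi <= 0 || phi >= 1) stop("phi must be in (0,1)")
  if (n_causal < 1) stop("n_causal must be >= 1")
  structure(list(n_causal = as.integer(n_causal), phi = phi,
                 effect_sd = effect_sd, scenario = scenario,
                 window_bp = window_bp, min_maf = min_maf,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a cis-eQTL phenotype over a genotype matrix
#'
#' Draws causal effects, calibrates the exogenous variance to the requested
#' proportion of variance explained, and generates
#' `y = Xb + noise` where the noise law depends on the scenario (see
#' [scenarios]). Noise is independent across individuals in every scenario.
#'
#' @param genotypes a [genotype_matrix]; heterogeneity scenarios require
#'   population labels covering (TSI, GBR, FIN, CEU, YRI).
#' @param spec a [simulation_spec].
#' @return a list of class `simulated_phenotype`: `values`, `causal`
#'   (indices), `effects`, `sigma2`, `noise_mean` and `noise_var`
#'   (per-sample), `scenario`, `phi`.
#' @export
simulate_phenotype <- function(genotypes, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  x <- genotypes$dosages
  n <- nrow(x); p <- ncol(x)
  maf <- colMeans(x) / 2
  eff <- draw_effects(p, spec$n_causal, spec$effect_sd,
                      maf = maf, min_maf = spec$min_maf)
  g <- as.numeric(x %*% eff$effects)
  if (stats::var(g) == 0) stop("degenerate signal: var(Xb) = 0")
  sigma2 <- stats::var(g) * (1 - spec$phi) / spec$phi
  sigma <- sqrt(sigma2)

  scen <- spec$scenario
  if (scen %in% c("homogeneous")) {
    mu_i <- rep(0, n); var_i <- rep(sigma2, n)
  } else {
    labels <- genotypes$population_labels
    if (is.null(labels) || !all(labels %in% pop_order))
      stop("heterogeneity scenarios need population labels in ",
           paste(pop_order, collapse = "/"))
    k_i <- match(labels, pop_order)
    if (grepl("^t=", scen)) {
      t <- as.numeric(sub("^t=", "", scen))
      sizes <- stats::setNames(as.numeric(table(factor(labels, pop_order))), pop_order)
      a <- alpha_weights(t, sizes)
      var_pop <- 5 * sigma2 * a
      mu_i <- rep(0, n); var_i <- var_pop[k_i]
    } else if (scen == "smooth_mean") {
      mu_pop <- c(2 * sigma, 0, sigma, sigma, 2 * sigma)
      mu_i <- mu_pop[k_i]; var_i <- rep(sigma2, n)
    } else { # spiked_mean
      mu_pop <- c(0, 2 * sigma, 0, 0, 0)
      mu_i <- mu_pop[k_i]; var_i <- rep(sigma2, n)
    }
  }
  y <- g + stats::rnorm(n, mean = mu_i, sd = sqrt(var_i))
  structure(list(values = y, causal = eff$causal, effects = eff$effects,
                 sigma2 = sigma2, noise_mean = mu_i, noise_var = var_i,
                 scenario = scen, phi = spec$phi,
                 snr = spec$phi / (1 - spec$phi)),
            class = "simulated_phenotype")
}

#' @export
print.simulated_phenotype <- function(x, ...) {
  cat(sprintf("simulated_phenotype: %d samples, %d causal variant(s), phi=%.3g (SNR=%.3g), scenario=%s\n",
              length(x$values), length(x$causal), x$phi, x$snr, x$scenario))
  invisible(x)
}

# small deterministic 32-bit mixing hash for per-cell seeds (< 2^31)
cell_seed <- function(master_seed, ...) {
  parts <- paste(c(master_seed, ...), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Enumerate a factorial simulation grid
#'
#' Deterministically enumerates every (locus, n_causal, phi, replicate,
#' scenario) cell, assigning each a reproducible seed derived from the
#' master seed. With the defaults (3 causal counts x 4 phi values x 2
#' replicates, one scenario), 100 loci give 2400 cells; 10 loci across the
#' 6 heterogeneity scenarios give 1440 cells.
#'
#' @param loci character vector of locus (gene) identifiers.
#' @param n_causal_set causal-count levels (default `c(1, 2, 3)`).
#' @param phi_set phi levels (default `c(0.05, 0.1, 0.2, 0.4)`).
#' @param replicates replicates per cell (default 2).
#' @param scenarios scenario levels (default `"homogeneous"`).
#' @param seed master seed.
#' @param path optional path: the manifest is written as a TSV.
#' @return a data.frame manifest with one row per dataset and a `seed`
#'   column.
#' @export
simulation_grid <- function(loci, n_causal_set = c(1, 2, 3),
                            phi_set = c(0.05, 0.1, 0.2, 0.4),
                            replicates = 2, scenarios = "homogeneous",
                            seed = 1, path = NULL) {
  if (length(loci) == 0) stop("loci must be non-empty")
  grid <- expand.grid(locus = loci, n_causal = n_causal_set, phi = phi_set,
                      replicate = seq_len(replicates), scenario = scenarios,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$locus, grid$scenario, grid$n_causal,
                     grid$phi, grid$replicate), ]
  rownames(grid) <- NULL
  grid$dataset_id <- sprintf("%s_%s_C%d_phi%g_rep%d", grid$locus,
                             gsub("[^A-Za-z0-9]", "", grid$scenario),
                             grid$n_causal, grid$phi, grid$replicate)
  grid$seed <- mapply(function(l, s, c, p, r)
    cell_seed(seed, l, s, c, p, r),
    grid$locus, grid$scenario, grid$n_causal, grid$phi, grid$replicate)
  if (!is.null(path))
    utils::write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  grid
}
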