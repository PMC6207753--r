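#' Configuration for the synthetic metapopulation generator
#'
#' Defines the study design the generator emulates: an island model of
#' `n_pops` lake populations sampled as `clones_per_pop` diploid clones,
#' genotyped at `n_loci` unlinked biallelic SNPs with
#' genotyping-by-sequencing depth and missingness structure. Defaults mirror
#' the nine-lake, 30-clone, FST = 0.18 design the package's analyses are
#' calibrated against.
#'
#' Locus classes are drawn multinomially from the class fractions: a
#' `diversifying` locus gets a positive locus effect `+alpha_effect` on the
#' logit of its per-population differentiation, a `balancing` locus
#' `-alpha_effect`, and an `env_correlated` locus has its population allele
#' frequency mean shifted on the logit scale by `env_beta` times the
#' standardized environmental value of the population.
#'
#' @param n_pops number of populations.
#' @param clones_per_pop diploid clones sampled per population.
#' @param n_loci number of unlinked biallelic loci.
#' @param baseline_fst neutral differentiation; logit(baseline_fst) is the
#'   shared population effect of the differentiation model.
#' @param frac_diversifying,frac_balancing,frac_env fractions of loci in
#'   each selected class (the remainder is neutral); must sum to at most 1.
#' @param alpha_effect magnitude of the locus effect (logit scale) for
#'   diversifying/balancing loci.
#' @param env_beta logit-scale frequency shift per standard deviation of the
#'   environmental gradient at `env_correlated` loci.
#' @param env_values optional numeric vector of per-population environmental
#'   values (standardized internally); default is an evenly spaced gradient.
#' @param depth_mean,depth_dispersion negative-binomial read-depth mean and
#'   dispersion (`size`) per genotype.
#' @param missing_rate extra fraction of genotypes set missing at random, on
#'   top of any depth-based masking applied later.
#' @param trait_effects optional tibble/data.frame with columns `locus`
#'   (column index) and `effect` (trait units per dosage copy) for the
#'   phenotype generator.
#' @param noise_sd residual standard deviation of the simulated trait.
#' @param seed integer seed; the same config always reproduces the same
#'   output exactly.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 9, clones_per_pop = 30, n_loci = 2000,
                       baseline_fst = 0.18,
                       frac_diversifying = 0, frac_balancing = 0,
                       frac_env = 0, alpha_effect = 2, env_beta = 0.8,
                       env_values = NULL,
                       depth_mean = 20, depth_dispersion = 5,
                       missing_rate = 0.05,
                       trait_effects = NULL, noise_sd = 1, seed = 1) {
  fr <- c(frac_diversifying, frac_balancing, frac_env)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    abort("locus-class fractions must lie in [0,1] and sum to at most 1")
  }
  if (baseline_fst <= 0 || baseline_fst >= 1) {
    abort("baseline_fst must lie strictly in (0, 1)")
  }
  stopifnot(n_pops >= 2, clones_per_pop >= 1, n_loci >= 1,
            depth_mean > 0, depth_dispersion > 0,
            missing_rate >= 0, missing_rate < 1, noise_sd >= 0)
  if (is.null(env_values)) env_values <- seq_len(n_pops)
  if (length(env_values) != n_pops) abort("env_values must have one value per population")
  structure(
    list(
      n_pops = n_pops, clones_per_pop = clones_per_pop, n_loci = n_loci,
      baseline_fst = baseline_fst,
      frac_diversifying = frac_diversifying,
      frac_balancing = frac_balancing, frac_env = frac_env,
      alpha_effect = alpha_effect, env_beta = env_beta,
      env_values = env_values,
      depth_mean = depth_mean, depth_dispersion = depth_dispersion,
      missing_rate = missing_rate,
      trait_effects = trait_effects, noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate per-population allele frequencies under the F-model
#'
#' Draws ancestral frequencies uniform on \[0.05, 0.95\] and
#' per-population frequencies from the Balding-Nichols beta model:
#' `p_ij ~ Beta(pi_i (1-c_ij)/c_ij, (1-pi_i)(1-c_ij)/c_ij)` where the
#' per-locus, per-population differentiation is
#' `c_ij = plogis(alpha_i + beta_j)`, `beta_j = qlogis(baseline_fst)` and
#' `alpha_i` is 0 (neutral), `+alpha_effect` (diversifying) or
#' `-alpha_effect` (balancing). Environmentally correlated loci keep the
#' neutral differentiation but have the beta mean shifted on the logit
#' scale by `env_beta` times the standardized environment.
#'
#' @param config a [sim_config()].
#' @return A list with `freq` (loci x populations frequency matrix),
#'   `truth` (tibble of per-locus class, true alpha, true env effect and
#'   ancestral frequency), and `env` (standardized environmental values).
#' @export
simulate_allele_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    L <- config$n_loci; J <- config$n_pops
    classes <- sample(
      c("diversifying", "balancing", "env_correlated", "neutral"), L,
      replace = TRUE,
      prob = c(config$frac_diversifying, config$frac_balancing,
               config$frac_env,
               1 - config$frac_diversifying - config$frac_balancing -
                 config$frac_env)
    )
    alpha <- ifelse(classes == "diversifying", config$alpha_effect,
                    ifelse(classes == "balancing", -config$alpha_effect, 0))
    env_b <- ifelse(classes == "env_correlated", config$env_beta, 0)
    env <- as.numeric(scale(config$env_values))
    beta_pop <- .logit(config$baseline_fst)
    pi0 <- runif(L, 0.05, 0.95)
    c_mat <- .inv_logit(outer(alpha, rep(beta_pop, J), `+`))
    if (any(c_mat <= 0 | c_mat >= 1)) {
      abort("degenerate per-locus differentiation (c = 0 or 1); reduce alpha_effect or adjust baseline_fst")
    }
    # beta mean: ancestral frequency, logit-shifted for env-correlated loci
    m <- .inv_logit(outer(.logit(pi0), rep(0, J), `+`) +
                      outer(env_b, env, `*`))
    shape1 <- m * (1 - c_mat) / c_mat
    shape2 <- (1 - m) * (1 - c_mat) / c_mat
    freq <- matrix(rbeta(L * J, shape1, shape2), L, J)
    dimnames(freq) <- list(
      sprintf("snp%04d", seq_len(L)),
      sprintf("pop%d", seq_len(J))
    )
    truth <- tibble(
      snp_id = rownames(freq), class = classes,
      alpha = alpha, env_effect = env_b, pi = pi0
    )
    list(freq = freq, truth = truth, env = env)
  })
}

#' Simulate diploid genotypes with GBS depth and missingness
#'
#' Dosages are binomial(2, p) draws within each population (HWE), read
#' depths are negative-binomial, and an extra `missing_rate` fraction of
#' genotypes is set missing at random. Positions are laid out on synthetic
#' scaffolds, 25 kb apart, 40 SNPs per scaffold.
#'
#' @param freq loci x populations allele-frequency matrix from
#'   [simulate_allele_frequencies()].
#' @param config the [sim_config()] used to generate `freq`.
#' @return A [geno_matrix()].
#' @export
simulate_genotypes <- function(freq, config) {
  stopifnot(inherits(config, "sim_config"), all(freq >= 0 & freq <= 1))
  withr::with_seed(config$seed + 1L, {
    L <- nrow(freq); J <- ncol(freq); n <- config$clones_per_pop
    dosage <- matrix(NA_integer_, J * n, L)
    for (j in seq_len(J)) {
      rows <- (j - 1L) * n + seq_len(n)
      dosage[rows, ] <- matrix(
        rbinom(n * L, 2L, rep(freq[, j], each = n)), n, L)
    }
    depth <- matrix(
      rnbinom(length(dosage), size = config$depth_dispersion,
              mu = config$depth_mean),
      nrow(dosage), ncol(dosage)
    )
    if (config$missing_rate > 0) {
      dosage[runif(length(dosage)) < config$missing_rate] <- NA_integer_
    }
    clones <- tibble(
      clone = sprintf("cl_%s_%02d", rep(colnames(freq), each = n),
                      rep(seq_len(n), J)),
      population = rep(colnames(freq), each = n)
    )
    per_scaf <- 40L
    snps <- tibble(
      snp_id = rownames(freq),
      scaffold = sprintf("scaffold%03d", (seq_len(L) - 1L) %/% per_scaf + 1L),
      pos = as.integer(((seq_len(L) - 1L) %% per_scaf) * 25000L + 1000L),
      ref = "A", alt = "T"
    )
    geno_matrix(dosage, depth, clones, snps)
  })
}

#' Simulate a clone-level quantitative trait
#'
#' `trait = sum(effect * dosage) + Normal(0, noise_sd^2)`; missing dosages
#' at effect loci contribute the clone's population-mean dosage so every
#' clone gets a phenotype.
#'
#' @param geno a [geno_matrix()].
#' @param config a [sim_config()]; `trait_effects` (columns `locus`,
#'   `effect`) and `noise_sd` are used.
#' @return A tibble with `clone`, `population`, `trait`.
#' @export
simulate_phenotypes <- function(geno, config) {
  stopifnot(inherits(config, "sim_config"))
  eff <- config$trait_effects
  withr::with_seed(config$seed + 2L, {
    g <- rep(0, nrow(geno$dosage))
    if (!is.null(eff) && nrow(eff) > 0) {
      stopifnot(all(eff$locus >= 1), all(eff$locus <= ncol(geno$dosage)))
      for (r in seq_len(nrow(eff))) {
        d <- geno$dosage[, eff$locus[r]]
        if (anyNA(d)) {
          pm <- tapply(d, geno$clones$population, mean, na.rm = TRUE)
          d[is.na(d)] <- pm[geno$clones$population[is.na(d)]]
        }
        g <- g + eff$effect[r] * d
      }
    }
    tibble(
      clone = geno$clones$clone,
      population = geno$clones$population,
      trait = g + rnorm(length(g), 0, config$noise_sd)
    )
  })
}

#' Simulate a monthly wet/dry presence-absence series
#'
#' Each year-month cell is wet with that calendar month's probability,
#' independently across years — the data layout Colwell's predictability
#' indices are computed from.
#'
#' @param years number of years.
#' @param monthly_wet_prob length-12 vector of wet probabilities, January
#'   to December.
#' @param seed integer seed.
#' @return A tibble with `year`, `month`, `state` (1 = wet, 0 = dry).
#' @export
simulate_wetdry_series <- function(years, monthly_wet_prob, seed = 1) {
  stopifnot(years >= 1, length(monthly_wet_prob) == 12,
            all(monthly_wet_prob >= 0 & monthly_wet_prob <= 1))
  withr::with_seed(as.integer(seed), {
    tibble(
      year = rep(seq_len(years), each = 12),
      month = rep(1:12, years),
      state = as.integer(runif(12 * years) <
                           rep(monthly_wet_prob, years))
    )
  })
}

#' Simulate a complete study: frequencies, genotypes, phenotype
#'
#' @param config a [sim_config()].
#' @return A list with `geno` ([geno_matrix()]), `truth`, `freq`, `env` and
#'   (when `trait_effects` is set) `phenotype`.
#' @export
simulate_study <- function(config) {
  fr <- simulate_allele_frequencies(config)
  geno <- simulate_genotypes(fr$freq, config)
  out <- list(geno = geno, truth = fr$truth, freq = fr$freq, env = fr$env)
  if (!is.null(config$trait_effects)) {
    out$phenotype <- simulate_phenotypes(geno, config)
  }
  out
}
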