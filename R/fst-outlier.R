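#' MCMC settings for the F-model scan
#'
#' Chain shape follows the convention of Bayesian F-model scans: short
#' pilot runs tune the random-walk proposal scales to a 25-45% acceptance
#' window, then a burn-in, then thinned sampling. Defaults are the
#' full-scale settings (20 pilots x 1,000 iterations, 10,000 burn-in,
#' 2,000 samples at thinning 10); calibration and power studies in the
#' tests and the worked examples use reduced chains, which the functions
#' accept through this config.
#'
#' @param n_pilot number of pilot runs for proposal tuning.
#' @param pilot_iter iterations per pilot run.
#' @param burn_in burn-in iterations after tuning.
#' @param n_samples posterior samples to retain.
#' @param thin thinning interval between retained samples.
#' @param prior_odds prior odds for neutrality; the prior inclusion
#'   probability of a locus effect is `1 / (prior_odds + 1)`.
#' @param seed integer seed; fixed seed gives identical posterior
#'   summaries.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_pilot = 20, pilot_iter = 1000, burn_in = 10000,
                        n_samples = 2000, thin = 10, prior_odds = 10,
                        seed = 1) {
  stopifnot(n_pilot >= 0, pilot_iter >= 1, burn_in >= 0, n_samples >= 1,
            thin >= 1, prior_odds > 0)
  structure(
    list(n_pilot = n_pilot, pilot_iter = pilot_iter, burn_in = burn_in,
         n_samples = n_samples, thin = thin, prior_odds = prior_odds,
         seed = as.integer(seed)),
    class = "mcmc_config"
  )
}

# beta-binomial marginal log-likelihood matrix of minor-allele counts `a`
# out of `n` (both L x J), under the F-model: the latent population
# frequency p_ij ~ Beta(theta_ij pi_i, theta_ij (1 - pi_i)) with
# theta_ij = 1/c_ij - 1 and logit(c_ij) = alpha_i + beta_j, integrated out
# analytically. Binomial coefficients are omitted (constant in the
# parameters).
fmodel_loglik <- function(a, n, alpha, logit_pi, beta) {
  c_ij <- .inv_logit(outer(alpha, beta, `+`))
  theta <- 1 / c_ij - 1
  pi_i <- .inv_logit(logit_pi)
  s1 <- theta * pi_i
  s2 <- theta * (1 - pi_i)
  lgamma(a + s1) + lgamma(n - a + s2) - lgamma(n + s1 + s2) -
    lgamma(s1) - lgamma(s2) + lgamma(s1 + s2)
}

#' Fit the Bayesian F-model FST-outlier scan
#'
#' Reversible-jump MCMC over the locus-by-population differentiation model
#' `logit(FST_ij) = alpha_i + beta_j`: `beta_j` captures the shared drift
#' of population j, and a locus-specific `alpha_i` is toggled in and out of
#' the model with prior odds for neutrality `prior_odds`. Positive included
#' `alpha` marks above-background differentiation (diversifying selection),
#' negative marks below-background (balancing/purifying). Minor-allele
#' counts enter through the beta-binomial marginal likelihood of the
#' Balding-Nichols frequency model. Priors: `alpha ~ N(0,1)`,
#' `beta_j ~ N(-1,1)`, ancestral frequency uniform (sampled on the logit
#' scale with the appropriate Jacobian). The reversible-jump birth proposal
#' is the alpha prior, so the proposal density cancels the prior in the
#' acceptance ratio.
#'
#' @param geno a filtered, biallelic [geno_matrix()].
#' @param mcmc an [mcmc_config()].
#' @return Object of class `fmodel_fit` with per-locus posterior summaries
#'   (`tidy()` it), population effects, and chain diagnostics (`glance()`).
#' @export
fit_f_model <- function(geno, mcmc = mcmc_config()) {
  stopifnot(inherits(mcmc, "mcmc_config"))
  ac <- allele_counts(geno)
  a <- ac$count; n <- ac$n
  mono <- rowSums(a) == 0 | rowSums(a) == rowSums(n)
  if (any(mono)) {
    abort(sprintf("%d monomorphic loci; filter them out before the scan",
                  sum(mono)))
  }
  L <- nrow(a); J <- ncol(a)
  p_incl <- 1 / (mcmc$prior_odds + 1)
  log_odds_incl <- log(p_incl) - log1p(-p_incl)

  withr::with_seed(mcmc$seed, {
    # initial values: moment estimates
    p_hat <- a / pmax(n, 1L)
    logit_pi <- .logit(pmin(pmax(rowMeans(p_hat), 0.01), 0.99))
    alpha <- rep(0, L)
    delta <- rep(FALSE, L)
    beta <- rep(-1, J)
    sd_pi <- rep(0.5, L); sd_alpha <- rep(0.5, L); sd_beta <- rep(0.2, J)

    ll <- fmodel_loglik(a, n, alpha, logit_pi, beta)

    run_sweep <- function(record_acc = FALSE) {
      acc <- c(pi = 0, alpha = 0, beta = 0, jump = 0)
      # 1. ancestral frequencies (logit scale, uniform prior on pi)
      prop <- logit_pi + rnorm(L) * sd_pi
      ll_new <- fmodel_loglik(a, n, alpha, prop, beta)
      jac <- (prop - 2 * log1p(exp(prop))) -
        (logit_pi - 2 * log1p(exp(logit_pi)))
      ratio <- rowSums(ll_new - ll) + jac
      take <- log(runif(L)) < ratio
      logit_pi[take] <<- prop[take]
      ll[take, ] <<- ll_new[take, , drop = FALSE]
      acc["pi"] <- mean(take)
      # 2. locus effects for included loci only
      if (any(delta)) {
        idx <- which(delta)
        prop_a <- alpha[idx] + rnorm(length(idx)) * sd_alpha[idx]
        ll_new <- fmodel_loglik(a[idx, , drop = FALSE],
                                n[idx, , drop = FALSE],
                                prop_a, logit_pi[idx], beta)
        ratio <- rowSums(ll_new - ll[idx, , drop = FALSE]) +
          dnorm(prop_a, 0, 1, log = TRUE) -
          dnorm(alpha[idx], 0, 1, log = TRUE)
        ok <- log(runif(length(idx))) < ratio
        alpha[idx[ok]] <<- prop_a[ok]
        ll[idx[ok], ] <<- ll_new[ok, , drop = FALSE]
        acc["alpha"] <- mean(ok)
      }
      # 3. reversible jump: toggle every locus
      prop_a <- ifelse(delta, 0, rnorm(L))
      ll_new <- fmodel_loglik(a, n, prop_a, logit_pi, beta)
      ratio <- rowSums(ll_new - ll) +
        ifelse(delta, -log_odds_incl, log_odds_incl)
      take <- log(runif(L)) < ratio
      alpha[take] <<- prop_a[take]
      delta[take] <<- !delta[take]
      ll[take, ] <<- ll_new[take, , drop = FALSE]
      acc["jump"] <- mean(take)
      # 4. population effects
      nacc <- 0
      for (j in seq_len(J)) {
        bj <- beta; bj[j] <- beta[j] + rnorm(1) * sd_beta[j]
        c_j <- .inv_logit(alpha + bj[j])
        theta <- 1 / c_j - 1
        pi_i <- .inv_logit(logit_pi)
        s1 <- theta * pi_i; s2 <- theta * (1 - pi_i)
        ll_col <- lgamma(a[, j] + s1) + lgamma(n[, j] - a[, j] + s2) -
          lgamma(n[, j] + s1 + s2) - lgamma(s1) - lgamma(s2) +
          lgamma(s1 + s2)
        ratio <- sum(ll_col - ll[, j]) +
          dnorm(bj[j], -1, 1, log = TRUE) - dnorm(beta[j], -1, 1, log = TRUE)
        if (log(runif(1)) < ratio) {
          beta[j] <<- bj[j]
          ll[, j] <<- ll_col
          nacc <- nacc + 1
        }
      }
      acc["beta"] <- nacc / J
      acc
    }

    # pilot runs: tune proposal scales toward a 25-45% acceptance window
    for (p in seq_len(mcmc$n_pilot)) {
      acc_sum <- c(pi = 0, alpha = 0, beta = 0, jump = 0)
      for (it in seq_len(mcmc$pilot_iter)) {
        acc_sum <- acc_sum + run_sweep()
      }
      rate <- acc_sum / mcmc$pilot_iter
      adj <- function(sds, r) {
        if (r > 0.45) sds * 1.3 else if (r < 0.25) sds / 1.3 else sds
      }
      sd_pi <- adj(sd_pi, rate["pi"])
      if (rate["alpha"] > 0) sd_alpha <- adj(sd_alpha, rate["alpha"])
      sd_beta <- adj(sd_beta, rate["beta"])
    }

    for (it in seq_len(mcmc$burn_in)) run_sweep()

    incl_sum <- numeric(L)
    alpha_sum <- numeric(L)
    alpha_incl_sum <- numeric(L)
    fst_sum <- numeric(L)
    beta_sum <- numeric(J)
    acc_sum <- c(pi = 0, alpha = 0, beta = 0, jump = 0)
    for (s in seq_len(mcmc$n_samples)) {
      for (t in seq_len(mcmc$thin)) acc_sum <- acc_sum + run_sweep()
      incl_sum <- incl_sum + delta
      alpha_sum <- alpha_sum + alpha
      alpha_incl_sum <- alpha_incl_sum + alpha * delta
      fst_sum <- fst_sum + rowMeans(.inv_logit(outer(alpha, beta, `+`)))
      beta_sum <- beta_sum + beta
    }
    acc_rate <- acc_sum / (mcmc$n_samples * mcmc$thin)
    if (any(acc_rate[c("pi", "beta")] < 0.1 | acc_rate[c("pi", "beta")] > 0.6)) {
      warn(sprintf(
        "proposal acceptance outside [0.1, 0.6] after tuning (pi %.2f, beta %.2f)",
        acc_rate["pi"], acc_rate["beta"]))
    }

    incl <- incl_sum / mcmc$n_samples
    loci <- tibble(
      snp_id = rownames(a),
      inclusion_prob = incl,
      alpha_mean = ifelse(incl_sum > 0, alpha_incl_sum / pmax(incl_sum, 1),
                          NA_real_),
      fst = fst_sum / mcmc$n_samples
    )
    structure(
      list(
        loci = loci,
        beta = tibble(population = colnames(a), beta_mean = beta_sum / mcmc$n_samples),
        acceptance = acc_rate,
        config = mcmc
      ),
      class = "fmodel_fit"
    )
  })
}

#' @export
print.fmodel_fit <- function(x, ...) {
  cat(sprintf(
    "<fmodel_fit> %d loci, %d populations; %d loci with inclusion prob > 0.5\n",
    nrow(x$loci), nrow(x$beta), sum(x$loci$inclusion_prob > 0.5)))
  invisible(x)
}

#' @export
tidy.fmodel_fit <- function(x, ...) {
  mutate(x$loci, q = q_values(x$loci$inclusion_prob))
}

#' @export
glance.fmodel_fit <- function(x, ...) {
  tibble(
    n_loci = nrow(x$loci), n_populations = nrow(x$beta),
    acc_pi = unname(x$acceptance["pi"]),
    acc_alpha = unname(x$acceptance["alpha"]),
    acc_beta = unname(x$acceptance["beta"]),
    acc_jump = unname(x$acceptance["jump"]),
    n_samples = x$config$n_samples
  )
}

#' Bayesian q-values from posterior inclusion probabilities
#'
#' Sort loci by decreasing posterior inclusion probability; the q-value of
#' a locus is the mean posterior probability of neutrality (1 - inclusion)
#' over all loci at least as extreme. The selected set at FDR `f` is
#' `q < f`. q is non-decreasing down the sorted list.
#'
#' @param x an `fmodel_fit` or a numeric vector of inclusion probabilities.
#' @return Numeric vector of q-values in the input locus order.
#' @export
q_values <- function(x) {
  po <- if (inherits(x, "fmodel_fit")) x$loci$inclusion_prob else x
  ord <- order(po, decreasing = TRUE)
  q_sorted <- cummean(1 - po[ord])
  q <- numeric(length(po))
  q[ord] <- q_sorted
  # ties in PO must share the (worst) q of the tied block
  for (v in unique(po[duplicated(po)])) {
    idx <- po == v
    q[idx] <- max(q[idx])
  }
  q
}

#' Classify loci as diversifying, balancing/purifying or neutral
#'
#' Loci with `q < fdr` are selected and classified by the sign of the
#' posterior mean locus effect: positive alpha means above-background
#' differentiation (diversifying selection), negative means
#' below-background (balancing/purifying). For the low-differentiation
#' class, two balancing-consistency flags are evaluated: minor allele
#' frequency above the mean MAF of non-outlier SNPs, and positive Tajima's
#' D — balancing selection maintains intermediate frequencies, purifying
#' selection does not.
#'
#' @param fit an `fmodel_fit` (or its `tidy()` tibble with `snp_id`,
#'   `alpha_mean`, `inclusion_prob`, `fst`).
#' @param maf tibble with `snp_id`, `maf` (e.g. from [snp_meta()]).
#' @param tajima tibble with `snp_id`, `d` (e.g. `tajimas_d()$snps`).
#' @param fdr q-value threshold for calling selection.
#' @return A tibble: per locus `q`, `class`, `maf`, `tajima_d`,
#'   `maf_above_background`, `tajima_positive` (flags are `NA` outside the
#'   balancing/purifying class or where the inputs are missing).
#' @export
classify_selection <- function(fit, maf = NULL, tajima = NULL, fdr = 0.05) {
  calls <- if (inherits(fit, "fmodel_fit")) tidy(fit) else as_tibble(fit)
  if (!"q" %in% names(calls)) calls$q <- q_values(calls$inclusion_prob)
  calls$class <- case_when(
    calls$q < fdr & !is.na(calls$alpha_mean) & calls$alpha_mean > 0 ~ "diversifying",
    calls$q < fdr & !is.na(calls$alpha_mean) & calls$alpha_mean < 0 ~ "balancing/purifying",
    .default = "neutral"
  )
  calls$maf <- if (!is.null(maf)) maf$maf[match(calls$snp_id, maf$snp_id)] else NA_real_
  calls$tajima_d <- if (!is.null(tajima)) tajima$d[match(calls$snp_id, tajima$snp_id)] else NA_real_
  background_maf <- mean(calls$maf[calls$class == "neutral"], na.rm = TRUE)
  low <- calls$class == "balancing/purifying"
  calls$maf_above_background <- ifelse(low, calls$maf > background_maf, NA)
  calls$tajima_positive <- ifelse(low, calls$tajima_d > 0, NA)
  attr(calls, "background_maf") <- background_maf
  calls
}

#' Balancing-consistency summary of classified loci
#'
#' Among the loci called balancing/purifying, the fractions carrying each
#' balancing signature: above-background minor allele frequency, and
#' positive Tajima's D.
#'
#' @param calls tibble from [classify_selection()].
#' @return One-row tibble: counts and percentages per signature.
#' @export
balancing_consistency <- function(calls) {
  low <- filter(calls, .data$class == "balancing/purifying")
  n_maf <- sum(low$maf_above_background, na.rm = TRUE)
  n_taj <- sum(low$tajima_positive, na.rm = TRUE)
  tibble(
    n_low_fst = nrow(low),
    n_maf_above = n_maf,
    pct_maf_above = if (nrow(low)) 100 * n_maf / nrow(low) else NA_real_,
    n_tajima_positive = n_taj,
    pct_tajima_positive = if (nrow(low)) 100 * n_taj / nrow(low) else NA_real_
  )
}

#' @export
autoplot.fmodel_fit <- function(object, fdr = 0.05, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = log10(pmax(.data$q, 1e-4)), y = .data$fst)) +
    geom_point(aes(colour = .data$q < fdr), alpha = 0.6) +
    geom_vline(xintercept = log10(fdr), linetype = 2) +
    labs(x = "log10(q value)", y = "FST",
         colour = sprintf("q < %.2f", fdr)) +
    theme_minimal()
}
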