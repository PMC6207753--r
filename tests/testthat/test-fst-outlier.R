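# reduced chain used throughout: desk-scale runs of the sampler
short_chain <- function(seed = 7) {
  mcmc_config(n_pilot = 5, pilot_iter = 200, burn_in = 1500,
              n_samples = 600, thin = 2, seed = seed)
}

sim_filtered <- function(...) {
  st <- simulate_study(sim_config(...))
  keep <- predscan:::pooled_maf(st$geno) > 0
  list(geno = st$geno[, keep], truth = st$truth[keep, ])
}

test_that("q-values follow the Bayesian FDR definition", {
  expect_equal(q_values(c(0.99, 0.95, 0.50)),
               c(0.01, 0.03, (0.01 + 0.05 + 0.5) / 3))
  expect_equal(q_values(c(1, 1, 1)), c(0, 0, 0))
  withr::with_seed(3, {
    for (i in 1:20) {
      po <- runif(50)
      q <- q_values(po)
      expect_true(all(diff(q[order(po, decreasing = TRUE)]) >= -1e-12))
      expect_true(all(q >= 0 & q <= 1))
    }
  })
})

test_that("selection classes follow the alpha sign and q threshold", {
  calls <- tibble::tibble(
    snp_id = c("a", "b", "c", "d"),
    inclusion_prob = c(0.99, 0.99, 0.40, 0.98),
    alpha_mean = c(-1.2, 1.5, 2.0, -0.8),
    fst = c(0.05, 0.6, 0.5, 0.08),
    q = c(0.01, 0.01, 0.20, 0.02)
  )
  maf <- tibble::tibble(snp_id = c("a", "b", "c", "d"),
                        maf = c(0.30, 0.10, 0.20, 0.05))
  taj <- tibble::tibble(snp_id = c("a", "b", "c", "d"),
                        d = c(0.8, -0.5, 0.1, 1.0))
  out <- classify_selection(calls, maf, taj)
  expect_equal(out$class,
               c("balancing/purifying", "diversifying", "neutral",
                 "balancing/purifying"))
  # flags evaluated only for the low-FST class; background MAF is the
  # neutral mean (0.20 here)
  expect_true(out$maf_above_background[1])
  expect_true(out$tajima_positive[1])
  expect_false(out$maf_above_background[4])
  expect_true(is.na(out$maf_above_background[2]))
  summ <- balancing_consistency(out)
  expect_equal(summ$n_low_fst, 2L)
  expect_equal(summ$pct_maf_above, 50)
  expect_equal(summ$pct_tajima_positive, 100)
})

test_that("the sampler is deterministic for a fixed seed", {
  s <- sim_filtered(n_loci = 60, clones_per_pop = 8, n_pops = 4, seed = 2)
  mc <- mcmc_config(n_pilot = 2, pilot_iter = 50, burn_in = 100,
                    n_samples = 50, thin = 1, seed = 5)
  f1 <- suppressWarnings(fit_f_model(s$geno, mc))  # tiny tuning run
  f2 <- suppressWarnings(fit_f_model(s$geno, mc))
  expect_identical(f1$loci, f2$loci)
  expect_identical(f1$beta, f2$beta)
})

test_that("monomorphic loci are rejected up front", {
  g <- toy_geno(list(p1 = matrix(0L, 6, 3), p2 = matrix(0L, 6, 3)))
  expect_error(fit_f_model(g, short_chain()), "monomorphic")
})

test_that("two identical populations keep inclusion near the prior", {
  withr::with_seed(19, {
    d <- vapply(runif(120, 0.2, 0.8), function(q) rbinom(20, 2, q),
                integer(20))
  })
  g <- toy_geno(list(p1 = d[1:10, ], p2 = d[11:20, ]))
  g <- g[, predscan:::pooled_maf(g) > 0]
  fit <- fit_f_model(g, short_chain(3))
  # prior inclusion is 1/11; exchangeable pops should stay close to it
  expect_lt(mean(fit$loci$inclusion_prob), 2 / 11)
  expect_equal(sum(tidy(fit)$q < 0.05), 0)
})

test_that("all-neutral scans stay within the FDR budget", {
  s <- sim_filtered(n_loci = 400, seed = 51, missing_rate = 0.03)
  fit <- fit_f_model(s$geno, short_chain(51))
  n_out <- sum(tidy(fit)$q < 0.05)
  expect_lte(n_out, ceiling(0.05 * nrow(s$truth)))
})

test_that("injected diversifying loci are recovered with positive alpha", {
  s <- sim_filtered(n_pops = 16, n_loci = 400, frac_diversifying = 0.05,
                    alpha_effect = 2, seed = 52, missing_rate = 0.03)
  fit <- fit_f_model(s$geno, short_chain(52))
  d <- tidy(fit)
  div <- s$truth$class == "diversifying"
  hits <- d$q < 0.05 & !is.na(d$alpha_mean) & d$alpha_mean > 0
  expect_gte(sum(hits & div) / sum(div), 0.8)
  # recovered effects carry the right sign
  expect_true(all(d$alpha_mean[hits & div] > 0))
})

test_that("balancing loci are recovered with negative alpha", {
  s <- sim_filtered(n_pops = 16, n_loci = 400, frac_balancing = 0.10,
                    alpha_effect = 2, baseline_fst = 0.25, seed = 53,
                    missing_rate = 0.03)
  fit <- fit_f_model(s$geno, short_chain(53))
  d <- tidy(fit)
  bal <- s$truth$class == "balancing"
  hits <- d$q < 0.05 & !is.na(d$alpha_mean) & d$alpha_mean < 0
  # balancing signals are intrinsically weaker; require sign correctness
  # and a majority recovery
  expect_gte(sum(hits & bal) / sum(bal), 0.5)
  called <- d$q < 0.05 & bal & !is.na(d$alpha_mean)
  expect_true(mean(d$alpha_mean[called] < 0) > 0.9)
})

test_that("raising prior odds for neutrality never raises inclusion", {
  s <- sim_filtered(n_loci = 100, clones_per_pop = 10, n_pops = 5,
                    frac_diversifying = 0.05, alpha_effect = 2, seed = 54)
  po_at <- function(odds) {
    mc <- mcmc_config(n_pilot = 2, pilot_iter = 100, burn_in = 400,
                      n_samples = 400, thin = 1, prior_odds = odds, seed = 9)
    mean(fit_f_model(s$geno, mc)$loci$inclusion_prob)
  }
  p1 <- po_at(1); p10 <- po_at(10); p100 <- po_at(100)
  expect_gt(p1, p10 - 0.02)
  expect_gt(p10, p100 - 0.02)
})
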