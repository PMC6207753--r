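test_that("config validation rejects impossible designs", {
  expect_error(sim_config(baseline_fst = 0), "baseline_fst")
  expect_error(sim_config(frac_diversifying = 0.7, frac_balancing = 0.5),
               "fractions")
  expect_error(sim_config(env_values = 1:3), "one value per population")
})

test_that("the generator is deterministic given a config", {
  cfg <- sim_config(n_loci = 80, frac_env = 0.1, seed = 99)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$geno$dosage, b$geno$dosage)
  expect_identical(a$geno$depth, b$geno$depth)
  expect_identical(a$freq, b$freq)
  expect_identical(a$truth, b$truth)
})

test_that("no-differentiation limit collapses population frequencies to pi", {
  cfg <- sim_config(n_loci = 300, baseline_fst = 1e-4, clones_per_pop = 40,
                    missing_rate = 0, seed = 4)
  fr <- simulate_allele_frequencies(cfg)
  expect_lt(max(abs(fr$freq - fr$truth$pi)), 0.05)
  geno <- simulate_genotypes(fr$freq, cfg)
  theta <- wc_fst(geno, pairwise = FALSE)$overall
  expect_lt(abs(theta), 0.01)
})

test_that("multilocus theta recovers the configured baseline FST", {
  # frequency-level calibration at the anchors 0.05, 0.18 and 0.3
  for (f in c(0.05, 0.18, 0.30)) {
    cfg <- sim_config(n_loci = 2000, baseline_fst = f, missing_rate = 0,
                      seed = 200 + round(100 * f))
    st <- simulate_study(cfg)
    theta <- wc_fst(st$geno, pairwise = FALSE)$overall
    # Monte-Carlo SE of the multilocus ratio estimate, via a leave-one-out
    # style locus-level spread: ~ f * sqrt(2/(J-1)) / sqrt(L)
    se <- f * sqrt(2 / (cfg$n_pops - 1)) / sqrt(cfg$n_loci)
    expect_lt(abs(theta - f), 3 * max(se, 0.004))
  }
})

test_that("locus classes separate in realized differentiation", {
  cfg <- sim_config(n_loci = 1500, frac_diversifying = 1 / 3,
                    frac_balancing = 1 / 3, alpha_effect = 1.5,
                    missing_rate = 0, seed = 6)
  st <- simulate_study(cfg)
  per_locus <- wc_fst(st$geno, pairwise = FALSE)$per_locus
  mean_by <- tapply(per_locus, st$truth$class, mean, na.rm = TRUE)
  expect_gt(mean_by["diversifying"], mean_by["neutral"])
  expect_gt(mean_by["neutral"], mean_by["balancing"])
})

test_that("genotype depth and missingness follow the configured model", {
  cfg <- sim_config(n_loci = 500, depth_mean = 20, depth_dispersion = 50,
                    missing_rate = 0, seed = 8)
  st <- simulate_study(cfg)
  frac_low <- mean(st$geno$depth < 6)
  expect_equal(frac_low, pnbinom(5, size = 50, mu = 20), tolerance = 0.005)

  # fixed frequency of 0 gives all-zero dosage and He = 0
  freq0 <- matrix(0, 5, 3, dimnames = list(paste0("s", 1:5), paste0("pop", 1:3)))
  cfg2 <- sim_config(n_pops = 3, clones_per_pop = 10, n_loci = 5,
                     missing_rate = 0, seed = 1)
  g0 <- simulate_genotypes(freq0, cfg2)
  expect_true(all(g0$dosage == 0))
  expect_equal(diversity_per_population(g0)$he, rep(0, 3))
})

test_that("simulated genotypes are in HWE within populations", {
  cfg <- sim_config(n_loci = 2000, missing_rate = 0, seed = 10)
  st <- simulate_study(cfg)
  hw <- hwe_exact(st$geno[, 1:2000])
  rate <- mean(hw$p < 0.05, na.rm = TRUE)
  # exact-test rejection rate at nominal 5%; discreteness keeps it below
  expect_lt(rate, 0.07)
  expect_gt(rate, 0.005)
})

test_that("phenotypes respond to effect loci as configured", {
  # null: no effects, no Bonferroni hits in most replicates
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(n_loci = 150, clones_per_pop = 10, missing_rate = 0,
                      noise_sd = 1, seed = 400 + s)
    st <- simulate_study(cfg)
    ph <- simulate_phenotypes(st$geno, cfg)
    gw <- eigenstrat_scan(st$geno, ph, k_pcs = 5)
    sum(tidy(gw)$p_bonferroni < 0.05, na.rm = TRUE)
  }, 0)
  expect_gte(mean(hits == 0), 0.8)

  # noiseless single-locus trait is perfectly collinear with its dosage
  cfg <- sim_config(n_loci = 50, clones_per_pop = 10, missing_rate = 0,
                    noise_sd = 0,
                    trait_effects = data.frame(locus = 7, effect = 1),
                    seed = 12)
  st <- simulate_study(cfg)
  ph <- simulate_phenotypes(st$geno, cfg)
  expect_equal(cor(ph$trait, st$geno$dosage[, 7])^2, 1, tolerance = 1e-12)
})

test_that("a strong effect locus tops the association ranking", {
  top <- vapply(1:8, function(s) {
    cfg <- sim_config(n_loci = 200, missing_rate = 0, noise_sd = 1,
                      trait_effects = data.frame(locus = 50, effect = 0.8),
                      seed = 500 + s)
    st <- simulate_study(cfg)
    ph <- simulate_phenotypes(st$geno, cfg)
    gw <- tidy(eigenstrat_scan(st$geno, ph, k_pcs = 5))
    which.min(gw$p) == 50
  }, TRUE)
  expect_gte(mean(top), 0.9)
})

test_that("simulated studies round-trip through VCF", {
  cfg <- sim_config(n_loci = 60, clones_per_pop = 5, n_pops = 3, seed = 14)
  st <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  back <- read_geno_vcf(file.path(dir, "genotypes.vcf"),
                        file.path(dir, "populations.tsv"))
  expect_equal(unname(back$dosage), unname(st$geno$dosage))
  expect_equal(unname(back$depth), unname(st$geno$depth))
  expect_equal(back$clones$population, st$geno$clones$population)
})
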