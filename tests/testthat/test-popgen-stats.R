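test_that("diversity matches hand arithmetic on a worked example", {
  # genotype counts AA=2, Aa=2, aa=0: p = 0.75, Ho = 0.5,
  # unbiased He = (8/7) * 0.375
  g <- toy_geno(list(p1 = matrix(c(0L, 0L, 1L, 1L), 4, 1)))
  div <- diversity_per_population(g)
  expect_equal(div$ho, 0.5)
  expect_equal(div$he, (8 / 7) * 0.375, tolerance = 1e-12)
  expect_equal(div$fis, 1 - 0.5 / ((8 / 7) * 0.375), tolerance = 1e-12)
})

test_that("monomorphic and all-heterozygote loci hit the documented edges", {
  mono <- toy_geno(list(p1 = matrix(0L, 5, 1)))
  div <- diversity_per_population(mono)
  expect_equal(div$ho, 0)
  expect_equal(div$he, 0)
  expect_true(is.nan(div$fis) || is.na(div$fis))

  het <- toy_geno(list(p1 = matrix(1L, 6, 1)))
  div2 <- diversity_per_population(het)
  expect_equal(div2$ho, 1)
  expect_lt(div2$fis, 0)
})

test_that("theta is 1 for fixed alternate alleles and ~0 under identity", {
  fixed <- toy_geno(list(p1 = matrix(0L, 8, 5), p2 = matrix(2L, 8, 5)))
  expect_equal(wc_fst(fixed, pairwise = FALSE)$overall, 1)

  withr::with_seed(77, {
    p <- runif(400, 0.2, 0.8)
    d1 <- vapply(p, function(q) rbinom(60, 2, q), integer(60))
    d2 <- vapply(p, function(q) rbinom(60, 2, q), integer(60))
  })
  null <- toy_geno(list(p1 = d1, p2 = d2))
  expect_lt(abs(wc_fst(null, pairwise = FALSE)$overall), 0.01)
})

test_that("theta equals the independent variance-component oracle", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      d1 <- matrix(sample(0:2, 10 * 12, TRUE), 10, 12)
      d2 <- matrix(sample(0:2, 8 * 12, TRUE), 8, 12)
      d3 <- matrix(sample(0:2, 6 * 12, TRUE), 6, 12)
      d1[sample(length(d1), 6)] <- NA
      g <- toy_geno(list(a = d1, b = d2, c = d3))
      expect_equal(wc_fst(g, pairwise = FALSE)$overall,
                   oracle_wc_theta(list(d1, d2, d3)), tolerance = 1e-10)
    }
  })
})

test_that("pairwise theta matrix is symmetric with an empty diagonal", {
  cfg <- sim_config(n_pops = 4, clones_per_pop = 15, n_loci = 150, seed = 3)
  st <- simulate_study(cfg)
  f <- wc_fst(st$geno)
  expect_true(isSymmetric(f$pairwise))
  expect_true(all(is.na(diag(f$pairwise))))
  td <- tidy(f)
  expect_equal(nrow(td), choose(4, 2))
})

test_that("the packaged tables reproduce the published He~log(area) correlation", {
  res <- he_area_correlation(diversity_table(), lake_table())
  expect_equal(round(res$r2, 2), 0.40)
  expect_equal(round(res$t, 2), 2.15)
  expect_equal(res$df, 7)
  expect_equal(round(res$p_one_sided, 3), 0.034)
})

test_that("correlation edges: perfect linearity and constant He", {
  lakes <- lake_table()
  div <- tibble::tibble(population = lakes$population,
                        he = 0.1 + 0.02 * log10(lakes$area_m2))
  expect_equal(he_area_correlation(div, lakes)$r2, 1, tolerance = 1e-12)
  div$he <- 0.17
  expect_true(is.na(he_area_correlation(div, lakes)$r))
  expect_error(he_area_correlation(div[1:2, ], lakes[1:2, ]), "three")
})

test_that("PCA separates simulated clusters and conserves variance", {
  cfg <- sim_config(n_pops = 2, clones_per_pop = 25, n_loci = 400,
                    baseline_fst = 0.3, missing_rate = 0.05, seed = 5)
  st <- simulate_study(cfg)
  pc <- pca_genotypes(st$geno)
  expect_equal(sum(pc$var_pct), 100, tolerance = 1e-6)
  skip_if_not_installed("cluster")
  sil <- cluster::silhouette(as.integer(factor(pc$scores$population)),
                             dist(pc$scores$PC1))
  expect_gt(mean(sil[, 3]), 0.8)
})

test_that("duplicated clones land on identical PCA coordinates", {
  cfg <- sim_config(n_pops = 2, clones_per_pop = 6, n_loci = 80,
                    missing_rate = 0, seed = 6)
  st <- simulate_study(cfg)
  g2 <- st$geno[c(1, 1, 2:12), ]
  g2$clones$clone <- sprintf("c%02d", 1:13)
  pc <- pca_genotypes(g2)
  expect_equal(unlist(pc$scores[1, -(1:2)]), unlist(pc$scores[2, -(1:2)]),
               tolerance = 1e-8)
})

test_that("Mantel test: self-comparison, label invariance, null validity", {
  f <- pairwise_fst_table(as_matrix = TRUE)
  self <- mantel_ibd(f, f, n_perm = 199, seed = 1)
  expect_equal(self$r, 1)
  expect_equal(self$p, 1 / 200)

  # joint relabeling leaves r unchanged
  withr::with_seed(8, {
    m2 <- f + matrix(runif(81), 9, 9)
    m2 <- (m2 + t(m2)) / 2; diag(m2) <- 0
  })
  r1 <- mantel_ibd(f, m2, n_perm = 99, seed = 2)$r
  s <- sample(9)
  r2 <- mantel_ibd(f[s, s], m2[s, s], n_perm = 99, seed = 2)$r
  expect_equal(r1, r2)

  # permutation p-values are uniform under independence
  withr::with_seed(9, {
    ps <- vapply(1:200, function(i) {
      a <- matrix(runif(49), 7, 7); a <- (a + t(a)) / 2; diag(a) <- 0
      b <- matrix(runif(49), 7, 7); b <- (b + t(b)) / 2; diag(b) <- 0
      mantel_ibd(a, b, n_perm = 99, seed = i)$p
    }, 0)
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.1)
})

test_that("Mantel r agrees with vegan on a fixture", {
  skip_if_not_installed("vegan")
  f <- pairwise_fst_table(as_matrix = TRUE)
  withr::with_seed(10, {
    g <- matrix(runif(81), 9, 9); g <- (g + t(g)) / 2; diag(g) <- 0
    dimnames(g) <- dimnames(f)
  })
  ours <- mantel_ibd(f, g, n_perm = 99, seed = 1)$r
  theirs <- vegan::mantel(as.dist(f), as.dist(g), permutations = 99)$statistic
  expect_equal(ours, unname(theirs), tolerance = 1e-12)
})
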