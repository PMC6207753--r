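#' Per-population diversity: Ho, He, FIS
#'
#' Per locus and population, observed heterozygosity is the heterozygote
#' fraction among called clones and expected heterozygosity is Nei's
#' unbiased gene diversity `(2n/(2n-1)) * (1 - sum p_k^2)` with `n` called
#' diploids. `FIS = 1 - Ho/He` at loci where `He > 0`; monomorphic loci are
#' excluded from the FIS average but contribute zeros to Ho and He.
#' Each quantity is then averaged over loci with data.
#'
#' @param geno a filtered [geno_matrix()].
#' @return A tibble with `population`, `ho`, `he`, `fis`.
#' @export
diversity_per_population <- function(geno) {
  pops <- populations(geno)
  rows <- map(pops, function(p) {
    d <- geno$dosage[geno$clones$population == p, , drop = FALSE]
    n <- colSums(!is.na(d))
    if (all(n == 0)) abort(sprintf("population %s has no called genotypes", p))
    has <- n > 0
    d <- d[, has, drop = FALSE]; n <- n[has]
    ho <- colSums(d == 1L, na.rm = TRUE) / n
    pfreq <- colSums(d, na.rm = TRUE) / (2 * n)
    he_raw <- 1 - pfreq^2 - (1 - pfreq)^2
    he <- ifelse(n > 0, (2 * n / pmax(2 * n - 1, 1)) * he_raw, NA_real_)
    fis <- ifelse(he > 0, 1 - ho / he, NA_real_)
    tibble(population = p, ho = mean(ho), he = mean(he),
           fis = mean(fis, na.rm = TRUE))
  })
  bind_rows(rows)
}

# Weir-Cockerham (1984) per-locus variance components for one biallelic
# locus over r populations. Inputs per population: sample size n_i
# (diploids), allele frequency p_i, observed heterozygote fraction h_i.
# Returns c(a, b, c): among-population, among-individual-within-population,
# within-individual components.
wc_components <- function(n_i, p_i, h_i) {
  keep <- n_i > 0
  n_i <- n_i[keep]; p_i <- p_i[keep]; h_i <- h_i[keep]
  r <- length(n_i)
  if (r < 2) return(c(NA_real_, NA_real_, NA_real_))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a, b, cc)
}

#' Weir-Cockerham FST
#'
#' Per-locus theta from the Weir-Cockerham variance components; the
#' multilocus estimate is the ratio of summed components (ratio of
#' averages, not the average of per-locus ratios). Loci informative in
#' fewer than two populations are skipped.
#'
#' @param geno a [geno_matrix()].
#' @param pairwise also compute the pairwise population matrix?
#' @return An object of class `fst_result`: list with `overall` (multilocus
#'   theta over all populations), `per_locus` (named vector), and when
#'   `pairwise = TRUE` a symmetric `pairwise` matrix of multilocus theta per
#'   population pair.
#' @export
wc_fst <- function(geno, pairwise = TRUE) {
  pops <- populations(geno)
  if (length(pops) < 2) abort("need at least two populations")
  stats_per_pop <- map(pops, function(p) {
    d <- geno$dosage[geno$clones$population == p, , drop = FALSE]
    n <- colSums(!is.na(d))
    list(n = n,
         p = ifelse(n > 0, colSums(d, na.rm = TRUE) / (2 * n), NA_real_),
         h = ifelse(n > 0, colSums(d == 1L, na.rm = TRUE) / n, NA_real_))
  })
  names(stats_per_pop) <- pops

  theta_multi <- function(pop_set) {
    L <- ncol(geno$dosage)
    abc <- vapply(seq_len(L), function(l) {
      n_i <- vapply(stats_per_pop[pop_set], function(s) s$n[l], 0)
      p_i <- vapply(stats_per_pop[pop_set], function(s) s$p[l], 0)
      h_i <- vapply(stats_per_pop[pop_set], function(s) s$h[l], 0)
      wc_components(n_i, p_i, h_i)
    }, numeric(3))
    ok <- !is.na(abc[1, ])
    list(
      overall = sum(abc[1, ok]) / sum(colSums(abc[, ok, drop = FALSE])),
      per_locus = abc[1, ] / colSums(abc)
    )
  }

  all_pop <- theta_multi(pops)
  out <- list(overall = all_pop$overall,
              per_locus = setNames(all_pop$per_locus, geno$snps$snp_id),
              pops = pops)
  if (pairwise && length(pops) > 2) {
    pw <- matrix(NA_real_, length(pops), length(pops),
                 dimnames = list(pops, pops))
    for (i in seq_along(pops)[-1]) for (j in seq_len(i - 1)) {
      th <- theta_multi(pops[c(i, j)])$overall
      pw[i, j] <- pw[j, i] <- th
    }
    out$pairwise <- pw
  } else if (pairwise) {
    out$pairwise <- matrix(all_pop$overall, 2, 2,
                           dimnames = list(pops, pops)) *
      (1 - diag(2)) + diag(2) * NA
  }
  structure(out, class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("<fst_result> multilocus Weir-Cockerham theta = %.4f over %d loci, %d populations\n",
              x$overall, length(x$per_locus), length(x$pops)))
  invisible(x)
}

#' @export
tidy.fst_result <- function(x, ...) {
  if (is.null(x$pairwise)) {
    return(tibble(snp_id = names(x$per_locus), fst = unname(x$per_locus)))
  }
  pw <- x$pairwise
  idx <- which(lower.tri(pw), arr.ind = TRUE)
  tibble(pop1 = rownames(pw)[idx[, 1]], pop2 = colnames(pw)[idx[, 2]],
         fst = pw[idx])
}

#' Heterozygosity versus log lake area
#'
#' Pearson correlation of per-population expected heterozygosity against
#' log10 lake area — larger lakes proxy larger effective population sizes,
#' so the expected direction is positive and the primary p-value is
#' one-sided. The t statistic is `t = r * sqrt(df) / sqrt(1 - r^2)` with
#' `df = n - 2`.
#'
#' @param diversity tibble with `population` and `he` (e.g. from
#'   [diversity_per_population()]).
#' @param lakes tibble with `population` and `area_m2` (e.g. [lake_table()]).
#' @return One-row tibble: `r`, `r2`, `t`, `df`, `p_one_sided`,
#'   `p_two_sided`. Degenerate inputs (constant He) give `NA` statistics.
#' @export
he_area_correlation <- function(diversity, lakes) {
  d <- inner_join(diversity, lakes, by = "population")
  if (nrow(d) < 3) abort("need at least three populations")
  if (sd(d$he) == 0 || sd(d$area_m2) == 0) {
    return(tibble(r = NA_real_, r2 = NA_real_, t = NA_real_,
                  df = nrow(d) - 2L, p_one_sided = NA_real_,
                  p_two_sided = NA_real_))
  }
  r <- cor(d$he, log10(d$area_m2))
  df <- nrow(d) - 2L
  t <- r * sqrt(df) / sqrt(1 - r^2)
  tibble(
    r = r, r2 = r^2, t = t, df = df,
    p_one_sided = pt(t, df, lower.tail = FALSE),
    p_two_sided = 2 * pt(abs(t), df, lower.tail = FALSE)
  )
}

#' PCA of the genotype matrix
#'
#' Missing dosages are mean-imputed per SNP, columns centred, and the
#' clone-by-clone configuration obtained by eigendecomposition. Per-axis
#' percentages of variance sum to 100 over all axes. All-missing SNP
#' columns are dropped with a warning.
#'
#' @param geno a [geno_matrix()].
#' @param n_axes number of axes to return coordinates for.
#' @return Object of class `geno_pca`: list with `scores` (tibble of clone,
#'   population, PC columns) and `var_pct` (percent variance per axis).
#' @export
pca_genotypes <- function(geno, n_axes = 10) {
  x <- geno$dosage
  allmiss <- colSums(!is.na(x)) == 0
  if (any(allmiss)) {
    warn(sprintf("dropping %d all-missing SNP columns", sum(allmiss)))
    x <- x[, !allmiss, drop = FALSE]
  }
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
  x <- sweep(x, 2, colMeans(x))
  pc <- prcomp(x, center = FALSE)
  var_pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_axes, ncol(pc$x))
  scores <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores <- bind_cols(geno$clones[, c("clone", "population")], scores)
  structure(list(scores = scores, var_pct = var_pct), class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("<geno_pca> %d clones; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), x$var_pct[1], x$var_pct[2]))
  invisible(x)
}

#' Mantel test for isolation by distance
#'
#' Mantel correlation between two symmetric distance-like matrices (e.g.
#' pairwise FST and geographic distance), with a one-sided permutation
#' p-value `(count of permuted r >= observed, + 1) / (n_perm + 1)`.
#'
#' @param m1,m2 symmetric matrices with matching population labels in
#'   `dimnames` (or identical ordering).
#' @param n_perm number of label permutations (>= 99).
#' @param seed integer seed for the permutations.
#' @return One-row tibble: `r`, `p`, `n_perm`.
#' @export
mantel_ibd <- function(m1, m2, n_perm = 999, seed = 1) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (!identical(dim(m1), dim(m2))) abort("matrix size mismatch")
  if (n_perm < 99) abort("use at least 99 permutations")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    if (!setequal(rownames(m1), rownames(m2))) abort("matrix label mismatch")
    m2 <- m2[rownames(m1), rownames(m1)]
  }
  low <- lower.tri(m1)
  obs <- cor(m1[low], m2[low])
  n <- nrow(m1)
  withr::with_seed(as.integer(seed), {
    perm_r <- vapply(seq_len(n_perm), function(i) {
      s <- sample.int(n)
      cor(m1[low], m2[s, s][low])
    }, 0)
  })
  tibble(r = obs, p = (sum(perm_r >= obs) + 1) / (n_perm + 1),
         n_perm = as.integer(n_perm))
}

#' @export
autoplot.geno_pca <- function(object, axes = c(1, 2), ...) {
  nm <- paste0("PC", axes)
  ggplot(object$scores,
         aes(x = .data[[nm[1]]], y = .data[[nm[2]]],
             colour = .data$population)) +
    geom_point(alpha = 0.8) +
    labs(
      x = sprintf("%s (%.1f%%)", nm[1], object$var_pct[axes[1]]),
      y = sprintf("%s (%.1f%%)", nm[2], object$var_pct[axes[2]])
    ) +
    theme_minimal()
}
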