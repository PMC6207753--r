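#' EIGENSTRAT-style stratification-corrected association scan
#'
#' Clone-level genotype-phenotype association with principal-component
#' correction for population stratification: the top `k_pcs` axes of the
#' mean-imputed, centred genotype matrix are computed, both the phenotype
#' and every SNP dosage are residualized on them, and each SNP is tested
#' with the statistic `(n - k - 1) * r^2` (r = residual correlation)
#' referred to a 1-df chi-square. With `k_pcs = 0` this reduces to an
#' Armitage-trend-style test. Bonferroni correction is over the tested
#' SNPs; the genomic-inflation factor lambda (median chi-square over its
#' null median) is reported but not applied.
#'
#' @param geno a filtered [geno_matrix()].
#' @param phenotype tibble with `clone` and `trait`, or a numeric vector in
#'   clone order. Must cover at least 90% of clones; clones without a
#'   phenotype are dropped.
#' @param k_pcs number of principal components to residualize on.
#' @return Object of class `gwas_fit`: `tidy()` gives per-SNP `statistic`,
#'   `p`, `p_bonferroni`, `r2`; `glance()` gives `lambda`, sizes. SNPs
#'   constant after residualization are skipped (`NA` statistics).
#' @export
eigenstrat_scan <- function(geno, phenotype, k_pcs = 10) {
  if (is.data.frame(phenotype)) {
    y <- phenotype$trait[match(geno$clones$clone, phenotype$clone)]
  } else {
    stopifnot(length(phenotype) == nrow(geno$dosage))
    y <- as.numeric(phenotype)
  }
  if (mean(!is.na(y)) < 0.9) abort("phenotype defined for < 90% of clones")
  keep <- !is.na(y)
  y <- y[keep]
  x <- geno$dosage[keep, , drop = FALSE]
  n <- nrow(x)
  if (k_pcs >= n - 2) abort("k_pcs must be < n_clones - 2")
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
  x <- sweep(x, 2, colMeans(x))
  if (sd(y) == 0) abort("phenotype is constant")

  if (k_pcs > 0) {
    pcs <- prcomp(x, center = FALSE)$x[, seq_len(k_pcs), drop = FALSE]
    qr_p <- qr(cbind(1, pcs))
    y_res <- qr.resid(qr_p, y)
    x_res <- qr.resid(qr_p, x)
  } else {
    y_res <- y - mean(y)
    x_res <- x
  }
  if (sd(y_res) == 0) abort("phenotype fully explained by the principal components")
  sx <- sqrt(colSums(x_res^2))
  ok <- sx > 1e-12
  r <- rep(NA_real_, ncol(x))
  r[ok] <- as.numeric(crossprod(x_res[, ok, drop = FALSE], y_res)) /
    (sx[ok] * sqrt(sum(y_res^2)))
  stat <- (n - k_pcs - 1) * r^2
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  m <- sum(ok)
  res <- tibble(
    snp_id = geno$snps$snp_id,
    statistic = stat, p = p,
    p_bonferroni = pmin(1, p * m),
    r2 = r^2
  )
  lambda <- median(stat, na.rm = TRUE) / qchisq(0.5, 1)
  structure(
    list(result = res, lambda = lambda, n = n, k_pcs = k_pcs,
         n_tested = m),
    class = "gwas_fit"
  )
}

#' @export
print.gwas_fit <- function(x, ...) {
  cat(sprintf(
    "<gwas_fit> %d SNPs tested, n = %d, k = %d PCs, lambda = %.2f; %d Bonferroni-significant\n",
    x$n_tested, x$n, x$k_pcs, x$lambda,
    sum(x$result$p_bonferroni < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' @export
tidy.gwas_fit <- function(x, ...) x$result

#' @export
glance.gwas_fit <- function(x, ...) {
  tibble(n_clones = x$n, n_tested = x$n_tested, k_pcs = x$k_pcs,
         lambda = x$lambda,
         n_significant = sum(x$result$p_bonferroni < 0.05, na.rm = TRUE))
}

#' @export
autoplot.gwas_fit <- function(object, ...) {
  d <- mutate(tidy(object), idx = dplyr::row_number())
  ggplot(d, aes(x = .data$idx, y = -log10(.data$p))) +
    geom_point(alpha = 0.6) +
    geom_hline(yintercept = -log10(0.05 / object$n_tested), linetype = 2) +
    labs(x = "SNP index", y = "-log10 p") +
    theme_minimal()
}
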