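# harmonic-number constants of Tajima's D for n sequences
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# D for one window given per-site minor allele counts `ac` out of `n`
# sequences (n constant within the window)
tajima_d_window <- function(ac, n) {
  seg <- ac > 0 & ac < n
  s <- sum(seg)
  if (s < 2 || n < 4) return(NA_real_)
  ac <- ac[seg]
  # mean pairwise differences summed over segregating sites
  pi <- sum(2 * ac * (n - ac) / (n * (n - 1)))
  k <- tajima_constants(n)
  theta_w <- s / k$a1
  (pi - theta_w) / sqrt(k$e1 * s + k$e2 * s * (s - 1))
}

#' Tajima's D per window, assigned to member SNPs
#'
#' Standard Tajima's D from the mean pairwise diversity and Watterson's
#' theta over the called sequences (2 x clones). Because D is undefined for
#' a single SNP, it is computed per window — by default the whole scaffold
#' — and every SNP inherits its window's value. Windows with fewer than two
#' segregating sites, or fewer than four sequences, yield `NA`. Sample
#' sizes vary across sites with missingness; the window uses the median
#' called-allele count.
#'
#' @param geno a [geno_matrix()] whose SNP metadata carries `scaffold` and
#'   `pos`.
#' @param window `"scaffold"` or a window width in bp.
#' @return A list with `windows` (tibble: window id, n sites, segregating
#'   sites, D) and `snps` (tibble: snp_id, window, d).
#' @export
tajimas_d <- function(geno, window = "scaffold") {
  stopifnot(all(c("scaffold", "pos") %in% names(geno$snps)))
  win <- if (identical(window, "scaffold")) {
    geno$snps$scaffold
  } else {
    sprintf("%s:%d", geno$snps$scaffold,
            (geno$snps$pos - 1L) %/% as.integer(window))
  }
  idx <- split(seq_len(ncol(geno$dosage)), win)
  windows <- imap_tibble(idx, function(cols, wname) {
    d <- geno$dosage[, cols, drop = FALSE]
    n_seq <- as.integer(round(median(2 * colSums(!is.na(d)))))
    ac <- colSums(d, na.rm = TRUE)
    seg <- ac > 0 & ac < 2 * colSums(!is.na(d))
    tibble(window = wname, n_sites = length(cols),
           n_segregating = as.integer(sum(seg)), n_sequences = n_seq,
           d = tajima_d_window(ac, n_seq))
  })
  snps <- tibble(snp_id = geno$snps$snp_id, window = win) |>
    left_join(windows[, c("window", "d")], by = "window")
  list(windows = windows, snps = snps)
}

imap_tibble <- function(x, f) bind_rows(map2(x, names(x), f))

# exact HWE probabilities of every possible heterozygote count given
# n diploids carrying n_a copies of the minor allele (Levene's conditional
# distribution), computed on the log scale
hwe_het_logprobs <- function(n, n_a) {
  n_b <- 2L * n - n_a
  ks <- seq(n_a %% 2L, min(n_a, n_b), by = 2L)
  lp <- vapply(ks, function(k) {
    naa <- (n_a - k) / 2; nbb <- (n_b - k) / 2
    lfactorial(n) - lfactorial(naa) - lfactorial(k) - lfactorial(nbb) +
      k * log(2) + lfactorial(n_a) + lfactorial(n_b) - lfactorial(2L * n)
  }, 0)
  setNames(lp - log_sum_exp(lp), ks)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# exact HWE p-value: total probability of heterozygote counts no more
# likely than the observed one
hwe_exact_p <- function(n_het, n, n_a) {
  if (n_a == 0L || n_a == 2L * n) return(1)
  lp <- hwe_het_logprobs(n, n_a)
  p_obs <- lp[as.character(n_het)]
  if (is.na(p_obs)) abort("heterozygote count incompatible with allele count")
  min(1, sum(exp(lp[lp <= p_obs + 1e-12])))
}

#' Exact Hardy-Weinberg tests per SNP and population
#'
#' Exact conditional test on the heterozygote count given the allele
#' counts, per SNP within each population, with Bonferroni correction over
#' all SNP-by-population tests. Monomorphic SNPs give p = 1.
#'
#' @param geno a [geno_matrix()].
#' @param alpha significance level applied after Bonferroni correction.
#' @return A tibble: `snp_id`, `population`, `n`, `p`, `p_bonferroni`,
#'   `reject` (p_bonferroni < alpha).
#' @export
hwe_exact <- function(geno, alpha = 0.05) {
  pops <- populations(geno)
  res <- map(pops, function(p) {
    d <- geno$dosage[geno$clones$population == p, , drop = FALSE]
    n <- colSums(!is.na(d))
    n_het <- colSums(d == 1L, na.rm = TRUE)
    n_a <- colSums(d, na.rm = TRUE)
    pv <- vapply(seq_along(n), function(l) {
      if (n[l] == 0) return(NA_real_)
      hwe_exact_p(n_het[l], n[l], n_a[l])
    }, 0)
    tibble(snp_id = geno$snps$snp_id, population = p, n = n, p = pv)
  })
  out <- bind_rows(res)
  m <- sum(!is.na(out$p))
  out$p_bonferroni <- pmin(1, out$p * m)
  out$reject <- !is.na(out$p_bonferroni) & out$p_bonferroni < alpha
  out
}

#' Linkage-disequilibrium decay with physical distance
#'
#' Composite genotypic r-squared (squared Pearson correlation of dosages
#' over pairwise-complete clones) between all SNP pairs on the same
#' scaffold within `max_dist_bp`, plus a binned mean-decay curve.
#'
#' @param geno a [geno_matrix()] with `scaffold` and `pos` metadata.
#' @param max_dist_bp maximum pair distance in bp.
#' @param bin_width_bp width of distance bins for the decay curve.
#' @return A list with `pairs` (tibble: snp_a, snp_b, distance_bp, r2) and
#'   `bins` (tibble: bin midpoint, mean r2, n pairs). Both empty when no
#'   intra-scaffold pair qualifies.
#' @export
ld_decay <- function(geno, max_dist_bp = 100000, bin_width_bp = 5000) {
  stopifnot(all(c("scaffold", "pos") %in% names(geno$snps)))
  pairs <- list()
  for (sc in unique(geno$snps$scaffold)) {
    cols <- which(geno$snps$scaffold == sc)
    if (length(cols) < 2) next
    pos <- geno$snps$pos[cols]
    cmb <- which(upper.tri(diag(length(cols))), arr.ind = TRUE)
    dist <- abs(pos[cmb[, 1]] - pos[cmb[, 2]])
    keep <- dist <= max_dist_bp
    if (!any(keep)) next
    cmb <- cmb[keep, , drop = FALSE]; dist <- dist[keep]
    r2 <- vapply(seq_len(nrow(cmb)), function(k) {
      suppressWarnings(
        cor(geno$dosage[, cols[cmb[k, 1]]], geno$dosage[, cols[cmb[k, 2]]],
            use = "pairwise.complete.obs")^2
      )
    }, 0)
    pairs[[sc]] <- tibble(
      snp_a = geno$snps$snp_id[cols[cmb[, 1]]],
      snp_b = geno$snps$snp_id[cols[cmb[, 2]]],
      distance_bp = as.integer(dist), r2 = r2
    )
  }
  pairs <- bind_rows(pairs)
  if (nrow(pairs) == 0) {
    return(list(pairs = tibble(snp_a = character(), snp_b = character(),
                               distance_bp = integer(), r2 = double()),
                bins = tibble(distance_bp = double(), mean_r2 = double(),
                              n_pairs = integer())))
  }
  bins <- pairs |>
    mutate(bin = (.data$distance_bp - 1) %/% bin_width_bp) |>
    group_by(.data$bin) |>
    summarise(distance_bp = (first(.data$bin) + 0.5) * bin_width_bp,
              mean_r2 = mean(.data$r2, na.rm = TRUE),
              n_pairs = n(), .groups = "drop") |>
    select(!"bin")
  list(pairs = pairs, bins = bins)
}
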