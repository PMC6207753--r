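#' Genotype matrix container
#'
#' Bundles a clones-by-SNPs dosage matrix (minor-allele counts 0/1/2, `NA`
#' for missing), the matching per-genotype read-depth matrix, the
#' clone-to-population map, and per-SNP metadata. All downstream analyses
#' (QC, diversity, FST, selection scans) consume this object.
#'
#' @param dosage integer matrix, clones in rows, SNPs in columns; entries
#'   0/1/2 or `NA`.
#' @param depth non-negative integer matrix of per-genotype read depths,
#'   same dimensions as `dosage`. May be `NULL` when depth is unknown.
#' @param clones tibble with columns `clone` and `population`, one row per
#'   dosage row.
#' @param snps tibble of per-SNP metadata with at least `snp_id`; typically
#'   also `scaffold`, `pos` (1-based), `ref`, `alt`. One row per dosage
#'   column.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, depth = NULL, clones, snps) {
  dosage <- as.matrix(dosage)
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    stopifnot(identical(dim(depth), dim(dosage)))
  }
  clones <- as_tibble(clones)
  snps <- as_tibble(snps)
  stopifnot(
    nrow(clones) == nrow(dosage),
    nrow(snps) == ncol(dosage),
    all(c("clone", "population") %in% names(clones)),
    "snp_id" %in% names(snps)
  )
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% 0:2)) {
    abort("dosages must be 0, 1, 2 or NA")
  }
  rownames(dosage) <- clones$clone
  colnames(dosage) <- snps$snp_id
  if (!is.null(depth)) dimnames(depth) <- dimnames(dosage)
  structure(
    list(dosage = dosage, depth = depth, clones = clones, snps = snps),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d clones x %d SNPs, %d populations, %.1f%% missing\n",
    nrow(x$dosage), ncol(x$dosage),
    length(unique(x$clones$population)),
    100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by clones and/or SNPs
#'
#' @param x a [geno_matrix()].
#' @param i clone index (logical, integer or clone names).
#' @param j SNP index (logical, integer or SNP ids).
#' @param ... unused.
#' @return A `geno_matrix` restricted to the selected clones and SNPs.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(i)) i <- match(i, x$clones$clone)
  if (is.character(j)) j <- match(j, x$snps$snp_id)
  geno_matrix(
    x$dosage[i, j, drop = FALSE],
    if (!is.null(x$depth)) x$depth[i, j, drop = FALSE],
    x$clones[i, , drop = FALSE],
    x$snps[j, , drop = FALSE]
  )
}

#' @export
as_tibble.geno_matrix <- function(x, ...) {
  long <- as_tibble(x$dosage, rownames = "clone") |>
    tidyr::pivot_longer(-"clone", names_to = "snp_id", values_to = "dosage")
  if (!is.null(x$depth)) {
    dl <- as_tibble(x$depth, rownames = "clone") |>
      tidyr::pivot_longer(-"clone", names_to = "snp_id", values_to = "depth")
    long <- left_join(long, dl, by = c("clone", "snp_id"))
  }
  left_join(long, x$clones, by = "clone")
}

#' Population labels of a genotype matrix
#' @param geno a [geno_matrix()].
#' @return Character vector of unique population labels, in order of first
#'   appearance.
#' @export
populations <- function(geno) unique(geno$clones$population)

# per-population minor-allele count and called-allele count matrices,
# loci in rows, populations in columns
allele_counts <- function(geno) {
  pops <- populations(geno)
  a <- n <- matrix(0L, ncol(geno$dosage), length(pops),
                   dimnames = list(geno$snps$snp_id, pops))
  for (k in seq_along(pops)) {
    d <- geno$dosage[geno$clones$population == pops[k], , drop = FALSE]
    a[, k] <- colSums(d, na.rm = TRUE)
    n[, k] <- 2L * colSums(!is.na(d))
  }
  list(count = a, n = n, pops = pops)
}

# per-SNP pooled minor allele frequency over called genotypes
pooled_maf <- function(geno) {
  p <- colSums(geno$dosage, na.rm = TRUE) / (2 * colSums(!is.na(geno$dosage)))
  pmin(p, 1 - p)
}

#' Per-SNP summary metadata recomputed from genotypes
#'
#' Refreshes `mean_depth` (over called genotypes) and `maf` (pooled minor
#' allele frequency) in the SNP metadata table.
#'
#' @param geno a [geno_matrix()].
#' @return A tibble: the SNP metadata with `mean_depth` and `maf` columns.
#' @export
snp_meta <- function(geno) {
  meta <- geno$snps
  called <- !is.na(geno$dosage)
  meta$mean_depth <- if (is.null(geno$depth)) NA_real_ else {
    colSums(geno$depth * called) / pmax(colSums(called), 1L)
  }
  meta$maf <- pooled_maf(geno)
  meta
}
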