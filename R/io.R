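#' Write a genotype matrix as VCF
#'
#' Plain-text VCF 4.2 with per-genotype `GT` and `DP` fields; unphased
#' genotypes, missing as `./.`.
#'
#' @param geno a [geno_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  snps <- geno$snps
  gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  n_clone <- nrow(geno$dosage)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=predscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$clones$clone), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(geno$dosage)), function(l) {
    d <- geno$dosage[, l]
    gt <- ifelse(is.na(d), "./.", gt_codes[as.character(d)])
    dp <- if (is.null(geno$depth)) rep(".", n_clone) else geno$depth[, l]
    paste(c(snps$scaffold[l], snps$pos[l], snps$snp_id[l],
            snps$ref[l] %||% "A", snps$alt[l] %||% "T", ".", "PASS", ".",
            "GT:DP", paste(gt, dp, sep = ":")), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF plus population map into a genotype matrix
#'
#' Parses `GT` (dosage of the ALT allele) and `DP` per genotype with vcfR
#' and joins the clone-to-population TSV (columns `clone`, `population`).
#'
#' @param vcf_path path to a VCF (optionally gzipped).
#' @param pop_path path to the population-map TSV.
#' @return A [geno_matrix()].
#' @export
read_geno_vcf <- function(vcf_path, pop_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dosage <- matrix(NA_integer_, ncol(gt), nrow(gt))
  gt_clean <- gsub("\\|", "/", gt)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  code[gt_clean == "0/0"] <- 0L
  code[gt_clean %in% c("0/1", "1/0")] <- 1L
  code[gt_clean == "1/1"] <- 2L
  dosage <- t(code)
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  depth <- if (all(is.na(dp))) NULL else {
    d <- t(dp); d[is.na(d)] <- 0L; d
  }
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- sprintf("%s_%s", fix$CHROM, fix$POS)[
    is.na(ids) | ids == "."]
  snps <- tibble(
    snp_id = ids, scaffold = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    n_alleles = 1L + ifelse(is.na(fix$ALT) | fix$ALT == ".", 0L,
                            stringr::str_count(fix$ALT, ",") + 1L)
  )
  pops <- readr::read_tsv(pop_path, col_types = readr::cols(.default = "c"))
  clones <- tibble(clone = colnames(gt)) |>
    left_join(pops, by = "clone")
  if (anyNA(clones$population)) abort("clones in VCF missing from population map")
  geno_matrix(dosage, depth, clones, snps)
}

#' Packaged lake and population tables
#'
#' The per-lake environmental and phenotypic table (area, salinity,
#' hydroperiod, environmental predictability, propensity for sex, hatching
#' fraction), the published per-population diversity summaries (Ho, He,
#' FIS), and the published pairwise FST values for the nine study lakes,
#' shipped as plain TSV fixtures.
#'
#' @return A tibble (`pairwise_fst_table()` additionally returns a matrix
#'   via `as_matrix = TRUE`).
#' @export
lake_table <- function() {
  readr::read_tsv(
    system.file("extdata", "lake_variables.tsv", package = "predscan"),
    col_types = "ccdddddd")
}

#' @rdname lake_table
#' @export
diversity_table <- function() {
  readr::read_tsv(
    system.file("extdata", "population_diversity.tsv", package = "predscan"),
    col_types = "cddd")
}

#' @param as_matrix return a symmetric matrix instead of the long tibble?
#' @rdname lake_table
#' @export
pairwise_fst_table <- function(as_matrix = FALSE) {
  d <- readr::read_tsv(
    system.file("extdata", "pairwise_fst.tsv", package = "predscan"),
    col_types = "ccd")
  if (!as_matrix) return(d)
  pops <- unique(c(d$pop1, d$pop2))
  m <- matrix(NA_real_, length(pops), length(pops),
              dimnames = list(pops, pops))
  for (i in seq_len(nrow(d))) {
    m[d$pop1[i], d$pop2[i]] <- m[d$pop2[i], d$pop1[i]] <- d$fst[i]
  }
  m
}

#' Reference-genome summary constants
#'
#' Assembly-level constants used for genome-scale arithmetic: the k-mer
#' based genome-size estimate (115.77 Mb) and the round count of genotyped
#' SNPs (4,500 of the 4,543 retained) used when quoting the mean inter-SNP
#' spacing.
#'
#' @return A one-row tibble: `genome_size_mb`, `n_snps_filtered`,
#'   `n_snps_round`.
#' @export
genome_stats <- function() {
  tibble(genome_size_mb = 115.77, n_snps_filtered = 4543L,
         n_snps_round = 4500L)
}

#' Mean inter-SNP spacing in kb
#'
#' `genome_size_mb * 1000 / n_snps`: the average distance between assayed
#' SNPs, the quantity to compare against the scale of LD decay.
#'
#' @param genome_size_mb genome size in Mb.
#' @param n_snps number of SNPs spread over it.
#' @return Spacing in kb.
#' @export
mean_snp_spacing_kb <- function(genome_size_mb = genome_stats()$genome_size_mb,
                                n_snps = genome_stats()$n_snps_round) {
  genome_size_mb * 1000 / n_snps
}

#' Write a simulated study to disk
#'
#' Writes the VCF, the clone-to-population map, and — when present — the
#' trait table and the per-locus truth table, as plain text.
#'
#' @param study list from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(study$geno, file.path(dir, "genotypes.vcf"))
  readr::write_tsv(study$geno$clones, file.path(dir, "populations.tsv"))
  readr::write_tsv(study$truth, file.path(dir, "truth.tsv"))
  if (!is.null(study$phenotype)) {
    readr::write_tsv(study$phenotype, file.path(dir, "traits.tsv"))
  }
  invisible(dir)
}
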