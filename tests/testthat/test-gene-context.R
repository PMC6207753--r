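toy_genes <- function() {
  tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    scaffold = c("sc1", "sc1", "sc2"),
    start = c(10000L, 40000L, 5000L),
    end = c(12000L, 45000L, 8000L),
    strand = c("+", "-", "+")
  )
}

toy_snps <- function() {
  tibble::tibble(
    snp_id = c("inside", "upstream2k", "far", "other_scaf", "lonely"),
    scaffold = c("sc1", "sc1", "sc1", "sc2", "sc3"),
    pos = c(11000L, 8000L, 20000L, 6000L, 1000L)
  )
}

test_that("flanking windows assign SNPs as designed", {
  res <- snps_to_genes(toy_snps(), toy_genes())
  a <- res$assignments
  # inside a gene body: assigned at every flank including 0
  expect_setequal(a$flank_bp[a$snp_id == "inside" & a$gene_id == "g1"],
                  c(0, 2500, 5000))
  # exactly 2 kb upstream: assigned at 2.5 kb and 5 kb, not at 0
  expect_setequal(a$flank_bp[a$snp_id == "upstream2k"], c(2500, 5000))
  # 8 kb from anything: unassigned, with nearest distance reported
  expect_true("far" %in% res$unassigned$snp_id)
  far <- dplyr::filter(res$unassigned, snp_id == "far")
  expect_equal(far$nearest_gene, "g1")
  expect_equal(far$distance_bp, 8000L)
  # scaffold without genes: NA distance
  lon <- dplyr::filter(res$unassigned, snp_id == "lonely")
  expect_true(is.na(lon$distance_bp))
})

test_that("interval assignment matches a brute-force scan", {
  withr::with_seed(55, {
    genes <- tibble::tibble(
      gene_id = sprintf("g%03d", 1:40),
      scaffold = sample(c("A", "B", "C"), 40, TRUE),
      start = as.integer(sample(1:200000, 40)),
      strand = "+"
    )
    genes$end <- genes$start + as.integer(sample(200:5000, 40))
    snps <- tibble::tibble(
      snp_id = sprintf("s%03d", 1:60),
      scaffold = sample(c("A", "B", "C"), 60, TRUE),
      pos = as.integer(sample(1:210000, 60))
    )
  })
  for (fl in c(0, 2500)) {
    got <- snps_to_genes(snps, genes, flank_bp = fl)$assignments
    want <- list()
    for (i in seq_len(nrow(snps))) for (j in seq_len(nrow(genes))) {
      if (snps$scaffold[i] == genes$scaffold[j] &&
          snps$pos[i] >= genes$start[j] - fl &&
          snps$pos[i] <= genes$end[j] + fl) {
        want[[length(want) + 1]] <- c(snps$snp_id[i], genes$gene_id[j])
      }
    }
    want <- do.call(rbind, want)
    expect_equal(nrow(got), NROW(want))
    if (NROW(want)) {
      expect_setequal(paste(got$snp_id, got$gene_id),
                      paste(want[, 1], want[, 2]))
    }
  }
})

test_that("gene models read from GFF3 with GO annotations", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "sc1\ttest\tgene\t10000\t12000\t.\t+\t.\tID=g1",
    "sc1\ttest\tmRNA\t10000\t12000\t.\t+\t.\tID=m1;Parent=g1",
    "sc1\ttest\tgene\t40000\t45000\t.\t-\t.\tID=g2"
  ), gff)
  go <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene_id = c("g1", "g1", "g2"),
                                  go_id = c("GO:1", "GO:2", "GO:1")), go)
  genes <- read_gene_models(gff, go)
  expect_equal(genes$gene_id, c("g1", "g2"))
  expect_equal(genes$start, c(10000L, 40000L))
  expect_equal(genes$go[[1]], c("GO:1", "GO:2"))
})

test_that("Fisher enrichment equals the hypergeometric oracle", {
  # in-set with term 5, in-set without 5, out-set with 10, out-set without 80
  go_map <- tibble::tibble(
    gene_id = c(sprintf("c%02d", 1:5), sprintf("u%02d", 1:10)),
    go_id = "GO:X"
  )
  cand <- c(sprintf("c%02d", 1:10))
  univ <- c(cand, sprintf("u%02d", 1:90))
  res <- go_enrichment(cand, univ, go_map)
  expect_equal(res$in_set_with, 5L)
  expect_equal(res$out_set_without, 80L)
  expect_equal(res$p, oracle_fisher_p(5, 5, 10, 80), tolerance = 1e-10)
})

test_that("enrichment degenerate cases behave as documented", {
  go_map <- tibble::tibble(gene_id = c("a", "b"), go_id = c("GO:1", "GO:1"))
  univ <- c("a", "b", "c", "d")
  # candidate set = universe: no contrast
  res <- go_enrichment(univ, univ, go_map)
  expect_equal(res$odds_ratio, 1)
  expect_false(res$significant)
  expect_error(go_enrichment(character(), univ, go_map), "empty")
  expect_error(go_enrichment(c("zzz"), univ, go_map), "subset")
})

test_that("Fisher p is symmetric under set/complement swap with reciprocal OR", {
  go_map <- tibble::tibble(gene_id = sprintf("g%02d", c(1:6, 20:28)),
                           go_id = "GO:Y")
  univ <- sprintf("g%02d", 1:40)
  cand <- sprintf("g%02d", 1:12)
  comp <- setdiff(univ, cand)
  a <- go_enrichment(cand, univ, go_map)
  b <- go_enrichment(comp, univ, go_map)
  expect_equal(a$p, b$p, tolerance = 1e-10)
  expect_equal(a$odds_ratio * b$odds_ratio, 1, tolerance = 1e-6)
})

test_that("BH adjustment matches the direct definition", {
  withr::with_seed(66, {
    genes <- sprintf("g%03d", 1:200)
    go_map <- tibble::tibble(
      gene_id = sample(genes, 400, TRUE),
      go_id = sample(sprintf("GO:%02d", 1:15), 400, TRUE)
    ) |> dplyr::distinct()
    cand <- sample(genes, 40)
  })
  res <- go_enrichment(cand, genes, go_map)
  expect_equal(res$q, p.adjust(res$p, "BH"))
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-12))
})
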