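mock_stats <- function(completeness = NA, contamination = NA,
                       rrnas = c(1, 1, 1), n_trna = 20) {
  tibble::tibble(
    genome_id = "g", contig_count = 10L, total_length = 2e6,
    n_trna = n_trna, rrna_5s = rrnas[1], rrna_16s = rrnas[2],
    rrna_23s = rrnas[3], completeness = completeness,
    contamination = contamination, taxonomy = NA_character_
  )
}

test_that("MIMAG quality tiers follow the standard thresholds", {
  expect_equal(assign_quality(mock_stats(95, 2))$quality, "high")
  expect_equal(assign_quality(mock_stats(60, 4, rrnas = c(1, 0, 1)))$quality,
               "medium")
  expect_equal(assign_quality(mock_stats(40, 2))$quality, "low")
  # boundaries: >90 / <5 / >=18 tRNA for high; >=50 / <10 for medium
  expect_equal(assign_quality(mock_stats(90, 2))$quality, "medium")
  expect_equal(assign_quality(mock_stats(95, 5))$quality, "medium")
  expect_equal(assign_quality(mock_stats(95, 2, n_trna = 17))$quality,
               "medium")
  expect_equal(assign_quality(mock_stats(50, 9.9))$quality, "medium")
  expect_equal(assign_quality(mock_stats(49.9, 2))$quality, "low")
  expect_equal(assign_quality(mock_stats())$quality, "low")
})

test_that("quality rank is monotone in completeness and contamination", {
  for (comp in c(40, 60, 95)) {
    for (cont in c(2, 8, 20)) {
      q1 <- assign_quality(mock_stats(comp, cont))$quality
      q2 <- assign_quality(mock_stats(comp + 5, cont))$quality
      q3 <- assign_quality(mock_stats(comp, cont - 1))$quality
      lvl <- c(low = 1, medium = 2, high = 3)
      expect_gte(lvl[q2], lvl[q1])
      expect_gte(lvl[q3], lvl[q1])
    }
  }
})

test_that("genome stats count RNAs and pass user fields through verbatim", {
  mock <- generate_mock_genomes(seed = 4)
  rna <- generate_mock_rna_table(unique(mock$contigs$genome_id), seed = 4)
  quality <- tibble::tibble(
    genome_id = c("genome_01", "genome_02"),
    completeness = c(95, 60), contamination = c(2, 4)
  )
  taxonomy <- tibble::tibble(
    genome_id = "genome_01", taxonomy = "d__Bacteria;p__Mockota"
  )
  stats <- summarize_genome_stats(mock$contigs, rna, quality, taxonomy)
  expect_equal(stats$n_trna, c(20, 20))
  expect_equal(stats$contig_count, c(1, 1))
  expect_equal(stats$total_length, c(3000, 3000))
  expect_equal(stats$taxonomy,
               c("d__Bacteria;p__Mockota", NA_character_))
  expect_equal(stats$quality, c("high", "medium"))

  # without user quality, only low is derivable
  bare <- summarize_genome_stats(mock$contigs, rna)
  expect_true(all(is.na(bare$completeness)))
  expect_true(all(bare$quality == "low"))

  expect_warning(
    summarize_genome_stats(
      mock$contigs, rna,
      tibble::tibble(genome_id = "nope", completeness = 1,
                     contamination = 1)
    ),
    "Unknown genome"
  )
})

test_that("distillate counts genes per identifier per genome", {
  raw <- tibble::tibble(
    gene_id = paste0("g", 1:5), genome_id = c("A", "A", "A", "B", "B"),
    contig_id = "c", start = 1:5, end = 2:6, strand = "+",
    rank = "C", status = "annotated",
    kegg_id = c("K00001", "K00001", "K00001", "K00002", NA),
    kofam_id = c(NA, "K00001", NA, NA, NA), # same KO from two databases
    dbcan_id = c(NA, NA, NA, NA, "GH13")
  )
  form <- read_distillate_form(
    system.file("extdata", "synthetic_distillate_form.tsv",
                package = "magdistill")
  )
  dist <- build_distillate(raw, form)
  tab <- tibble::as_tibble(dist)
  expect_equal(tab$A[tab$identifier == "K00001"][1], 3)
  expect_equal(tab$B[tab$identifier == "K00002"][1], 1)
  # promiscuous CAZyme counted in each substrate row
  gh13 <- tab[tab$identifier == "GH13", ]
  expect_equal(nrow(gh13), 2)
  expect_equal(gh13$B, c(1, 1))
  # absent identifiers keep an all-zero row
  expect_equal(tab$A[tab$identifier == "K00399"], 0)
  # counted once per (gene, identifier) even when two databases agree
  expect_equal(sum(tab$A[tab$identifier == "K00001"]), 3)
})

test_that("distillate counts are invariant to gene input order", {
  mock <- generate_mock_genomes(seed = 8)
  ann <- annotate_genes(mock$genes, mock$hits, mock$reverse_hits)
  form <- read_distillate_form(
    system.file("extdata", "synthetic_distillate_form.tsv",
                package = "magdistill")
  )
  d1 <- build_distillate(ann$raw, form)
  shuffled <- ann$raw[rev(seq_len(nrow(ann$raw))), ]
  d2 <- build_distillate(shuffled, form,
                         genome_ids = unique(ann$raw$genome_id))
  expect_equal(tibble::as_tibble(d1), tibble::as_tibble(d2))
})

test_that("single-substrate column sums equal gene-identifier assignments", {
  mock <- generate_mock_genomes(seed = 9)
  ann <- annotate_genes(mock$genes, mock$hits, mock$reverse_hits)
  form <- read_distillate_form(
    system.file("extdata", "synthetic_distillate_form.tsv",
                package = "magdistill")
  )
  single <- form[!duplicated(form$identifier) &
                   !form$identifier %in%
                     form$identifier[duplicated(form$identifier)], ]
  dist <- tibble::as_tibble(build_distillate(ann$raw, single))
  ids <- gene_identifiers(ann$raw)
  ids <- ids[ids$identifier %in% single$identifier, ]
  for (g in unique(ann$raw$genome_id)) {
    expect_equal(sum(dist[[g]]), sum(ids$genome_id == g))
  }
})

test_that("form rows with empty identifiers are rejected", {
  raw <- generate_mock_genomes(seed = 1)
  bad_form <- tibble::tibble(
    identifier = c("K00001", ""), description = "x",
    category = "energy", subcategory = "y"
  )
  expect_error(
    build_distillate(
      annotate_genes(raw$genes, raw$hits, raw$reverse_hits)$raw, bad_form
    ),
    class = "magdistill_form_error"
  )
})
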