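test_that("contig filter keeps contigs at or above the 2500 bp cutoff", {
  contigs <- tibble::tibble(
    id = paste0("c", 1:4), description = "",
    sequence = vapply(c(1000, 2499, 2500, 5000), strrep, character(1),
                      x = "A"),
    genome_id = "g"
  )
  kept <- filter_contigs(contigs)
  expect_equal(kept$id, c("c3", "c4"))
  expect_equal(nrow(filter_contigs(contigs,
                                   annotation_config(min_contig_length = 1))),
               4)
  expect_equal(nrow(filter_contigs(contigs[0, ])), 0)
})

test_that("best-hit selection applies the strict bit-score floor", {
  best <- select_best_hit(make_hits(scores = c(59.9, 80, 75)))
  expect_equal(best$bit_score, 80)
  expect_equal(nrow(select_best_hit(make_hits(scores = c(10, 59)))), 0)
  expect_equal(nrow(select_best_hit(make_hits(scores = numeric()))), 0)
  # boundary: exactly 60 is not > 60
  expect_equal(nrow(select_best_hit(make_hits(scores = 60))), 0)
  expect_error(
    select_best_hit(dplyr::bind_rows(
      make_hits(db = "kegg"), make_hits(db = "uniref")
    )),
    class = "magdistill_contract_error"
  )
})

test_that("best-hit selection is permutation invariant under the tie-break", {
  hits <- make_hits(
    scores = c(80, 80, 80, 70),
    evalues = c(1e-20, 1e-30, 1e-30, 1e-50),
    targets = c("tZ", "tB", "tA", "tQ")
  )
  expected <- select_best_hit(hits)$target_id
  expect_equal(expected, "tA") # lowest e-value, then smallest target id
  set.seed(42)
  for (i in 1:20) {
    shuffled <- hits[sample(nrow(hits)), ]
    expect_equal(select_best_hit(shuffled)$target_id, expected)
  }
})

test_that("reciprocal best hits require the original gene on top above 350", {
  fwd <- make_hits(query = "g1", scores = 400, targets = "K1")
  rev_ok <- tibble::tibble(query_id = "K1", target_id = c("g1", "g2"),
                           database = "kegg", bit_score = c(400, 300),
                           e_value = 1e-40)
  expect_true(confirm_rbh(fwd, rev_ok))
  rev_wrong_gene <- dplyr::mutate(rev_ok, target_id = c("g2", "g1"))
  expect_false(confirm_rbh(fwd, rev_wrong_gene))
  rev_low <- dplyr::mutate(rev_ok, bit_score = c(300, 100))
  expect_false(confirm_rbh(fwd, rev_low))
  # boundary: exactly 350 fails the strict inequality
  rev_350 <- dplyr::mutate(rev_ok, bit_score = c(350, 100))
  expect_false(confirm_rbh(fwd, rev_350))
})

test_that("profile-HMM filter applies strict coverage and e-value bounds", {
  hit <- function(cov, ev) {
    dplyr::mutate(make_hits(db = "pfam", scores = 80, evalues = ev),
                  model_coverage = cov)
  }
  expect_true(filter_profile_hit(hit(0.40, 1e-20)))
  expect_false(filter_profile_hit(hit(0.30, 1e-20)))
  expect_false(filter_profile_hit(hit(0.40, 1e-10)))
  # exact boundary values fail on both axes
  expect_false(filter_profile_hit(hit(0.35, 1e-20)))
  expect_false(filter_profile_hit(hit(0.40, 1e-15)))
  expect_error(
    filter_profile_hit(make_hits(db = "pfam")),
    class = "magdistill_contract_error"
  )
})

test_that("per-model KOfam thresholds override the generic profile rule", {
  thresholds <- tibble::tibble(
    model_id = c("K1", "K2"), score_threshold = c(100, NA),
    score_type = "full"
  )
  hit <- function(target, score) {
    dplyr::mutate(
      make_hits(db = "kofam", scores = score, targets = target,
                evalues = 1e-5),
      model_coverage = 0.9
    )
  }
  expect_true(filter_profile_hit(hit("K1", 100), thresholds))
  expect_false(filter_profile_hit(hit("K1", 99.9), thresholds))
  # no-threshold model falls back to coverage/e-value (fails on e-value)
  expect_false(filter_profile_hit(hit("K2", 500), thresholds))
})

test_that("rank truth table matches the A-E rule order exhaustively", {
  grid <- expand.grid(
    kegg_rbh = c(TRUE, FALSE), uniref_rbh = c(TRUE, FALSE),
    kegg_hit = c(TRUE, FALSE), uniref_hit = c(TRUE, FALSE),
    d_hit = c(TRUE, FALSE)
  )
  # an RBH implies the corresponding plain hit; drop unrealizable rows
  grid <- grid[!(grid$kegg_rbh & !grid$kegg_hit) &
                 !(grid$uniref_rbh & !grid$uniref_hit), ]
  got <- rank_from_evidence(grid$kegg_rbh, grid$uniref_rbh, grid$kegg_hit,
                            grid$uniref_hit, grid$d_hit)
  expected <- apply(grid, 1, function(r) {
    if (r[["kegg_rbh"]]) "A"
    else if (r[["uniref_rbh"]]) "B"
    else if (r[["kegg_hit"]] || r[["uniref_hit"]]) "C"
    else if (r[["d_hit"]]) "D"
    else "E"
  })
  expect_equal(got, unname(expected))
  # VOGDB-only evidence never leaves rank E
  vog_only <- assign_rank(best_hit_row("g1", "vogdb"), "g1")
  expect_equal(vog_only$rank, "E")
  merops_only <- assign_rank(best_hit_row("g1", "merops"), "g1")
  expect_equal(merops_only$rank, "D")
})

test_that("removing a database never raises a gene's rank", {
  rank_level <- c(A = 1, B = 2, C = 3, D = 4, E = 5)
  bh <- dplyr::bind_rows(
    best_hit_row("g1", "kegg", rbh = TRUE),
    best_hit_row("g1", "uniref", rbh = TRUE),
    best_hit_row("g1", "pfam"),
    best_hit_row("g2", "uniref"),
    best_hit_row("g2", "dbcan"),
    best_hit_row("g3", "merops"),
    best_hit_row("g4", "vogdb")
  )
  genes <- paste0("g", 1:4)
  full_dbs <- c("kegg", "kofam", "uniref", "merops", "pfam", "dbcan",
                "vogdb")
  base <- assign_rank(bh, genes,
                      annotation_config(databases_in_use = full_dbs))
  for (drop in full_dbs) {
    reduced <- assign_rank(
      bh, genes,
      annotation_config(databases_in_use = setdiff(full_dbs, drop))
    )
    expect_true(
      all(rank_level[reduced$rank] >= rank_level[base$rank]),
      info = paste("dropping", drop)
    )
  }
})

test_that("status classification follows the hypothetical keyword rule", {
  genes <- c("g1", "g2", "g3", "g4")
  bh <- dplyr::bind_rows(
    best_hit_row("g1", "pfam", desc = "ABC transporter"),
    best_hit_row("g2", "kegg", desc = "hypothetical protein"),
    best_hit_row("g3", "vogdb", desc = "capsid protein"),
    best_hit_row("g4", "uniref", desc = "Uncharacterized protein YjjA"),
    best_hit_row("g4", "pfam", desc = "Domain of Unknown Function DUF123")
  )
  st <- classify_status(bh, genes)
  expect_equal(st$status, c("annotated", "hypothetical", "unannotated",
                            "hypothetical"))
})

test_that("status unannotated implies rank E on merged annotations", {
  mock <- generate_mock_genomes(seed = 21)
  ann <- annotate_genes(mock$genes, mock$hits, mock$reverse_hits)
  un <- ann$raw[ann$raw$status == "unannotated", ]
  expect_true(all(un$rank == "E"))
})

test_that("merged raw table is deterministic and complete", {
  mock <- generate_mock_genomes(seed = 2)
  ann <- annotate_genes(mock$genes, mock$hits, mock$reverse_hits)
  raw <- ann$raw
  expect_equal(nrow(raw), nrow(mock$genes))
  expect_false(is.unsorted(raw$genome_id))
  # rank-A gene planted in each genome by the default plan
  expect_equal(sum(raw$rank == "A"), 2)
  # no-hit genes are present with empty fields and rank E
  none <- raw[raw$gene_id == "genome_01_gene_5", ]
  expect_equal(none$rank, "E")
  expect_true(is.na(none$kegg_id))
  dup_genes <- dplyr::bind_rows(mock$genes, mock$genes[1, ])
  expect_error(merge_raw_table(dup_genes, ann$best_hits),
               class = "magdistill_contract_error")
})

test_that("tidy and glance summarize annotations consistently", {
  mock <- generate_mock_genomes(seed = 2)
  ann <- annotate_genes(mock$genes, mock$hits, mock$reverse_hits)
  expect_identical(tidy(ann), ann$raw)
  g <- glance(ann)
  expect_equal(g$n_genes, 10)
  expect_equal(g$n_annotated + g$n_hypothetical + g$n_unannotated, 10)
  p <- ggplot2::autoplot(ann)
  expect_s3_class(p, "ggplot")
})
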