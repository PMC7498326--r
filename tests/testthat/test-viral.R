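test_that("evidence classification maps codes and warns on unknowns", {
  affi <- tibble::tibble(
    contig_id = "c", gene_id = paste0("g", 1:3), ordinal = 0:2,
    start = c(1, 1001, 2001), end = c(900, 1900, 2900), strand = "+",
    evidence_code = c("0", "1", "zz")
  )
  expect_warning(ev <- classify_viral_evidence(affi), "Unmapped")
  expect_equal(ev$evidence, c("hallmark", "viral_like", "none"))
  empty <- classify_viral_evidence(affi[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("auxiliary scores reproduce the five published rules", {
  expect_equal(engine_aux_score(c("hallmark", "none", "hallmark"))[2], 1L)
  expect_equal(engine_aux_score(c("hallmark", "none", "viral_like"))[2], 2L)
  expect_equal(engine_aux_score(c("viral_like", "none", "viral_like"))[2],
               3L)
  expect_equal(
    engine_aux_score(c("hallmark", "none", "none", "none"))[2], 4L
  )
  expect_equal(engine_aux_score(rep("none", 4))[2], 5L)
  # terminal genes score 5 even with flanking evidence
  expect_equal(engine_aux_score(c("none", "hallmark", "hallmark"))[1], 5L)
  # metabolic stretch of three raises mid-contig scores to 4, never lowers 5
  scores <- engine_aux_score(
    c("hallmark", "none", "none", "none", "hallmark"),
    metabolic = c(FALSE, TRUE, TRUE, TRUE, FALSE)
  )
  expect_equal(scores[3], 4L)
  expect_equal(scores[1], 5L)
})

test_that("auxiliary scores match a straight-line oracle exhaustively", {
  evidence_states <- c("hallmark", "viral_like", "none")
  for (n in 2:5) {
    ev_grid <- do.call(
      expand.grid,
      c(rep(list(evidence_states), n), stringsAsFactors = FALSE)
    )
    for (r in seq_len(nrow(ev_grid))) {
      evidence <- as.character(ev_grid[r, ])
      # metabolic status only matters where evidence is none; probe the
      # all-metabolic and no-metabolic extremes plus one mixed pattern
      for (metabolic in list(
        rep(FALSE, n), rep(TRUE, n),
        rep(c(TRUE, FALSE), length.out = n)
      )) {
        expect_identical(
          engine_aux_score(evidence, metabolic),
          oracle_aux_score(evidence, metabolic),
          info = paste(paste(evidence, collapse = ","), "|",
                       paste(metabolic, collapse = ","))
        )
      }
    }
  }
})

test_that("upgrading flank evidence never worsens the target's score", {
  ladder <- c("none", "viral_like", "hallmark")
  withr::with_seed(31, {
    for (rep_i in 1:50) {
      n <- sample(3:6, 1)
      evidence <- sample(ladder, n, replace = TRUE)
      target <- sample(2:(n - 1), 1)
      pos <- sample(setdiff(seq_len(n), target), 1)
      cur <- which(ladder == evidence[pos])
      if (cur == 3) next
      upgraded <- evidence
      upgraded[pos] <- ladder[cur + 1]
      expect_lte(
        engine_aux_score(upgraded)[target],
        engine_aux_score(evidence)[target]
      )
    }
  })
})

viral_fixture <- function(layout, seed = 1) {
  v <- generate_mock_viral_contig(layout, seed = seed)
  cfg <- amg_call_config_from_lists()
  res <- annotate_viral_contigs(v$affi, v$raw_table, v$form, v$contig_lengths,
                        config = cfg)
  list(v = v, res = res, cfg = cfg)
}

test_that("flags capture metabolism, AMG lists, contig ends and stretches", {
  fx <- viral_fixture("H M X M H")
  ctx <- fx$res$contexts
  target <- ctx[ctx$gene_id == fx$v$target_gene_id, ]
  flags <- target$flags[[1]]
  # K00001 is in the form (M), known and verified lists (K, E)
  expect_true(all(c("M", "K", "E") %in% flags))
  # three adjacent metabolic genes all carry B
  mids <- ctx[ctx$ordinal %in% 1:3, ]
  expect_true(all(purrr::map_lgl(mids$flags, ~ "B" %in% .x)))
  # short contig: every gene within 5000 bases of an end gets F
  expect_true(all(purrr::map_lgl(ctx$flags, ~ "F" %in% .x)))
  # hallmark genes with structural VOG hits carry V
  ends <- ctx[ctx$ordinal %in% c(0, 4), ]
  expect_true(all(purrr::map_lgl(ends$flags, ~ "V" %in% .x)))
})

test_that("the F flag respects the 5000-base end window strictly", {
  ctx <- tibble::tibble(
    contig_id = "c", gene_id = c("g1", "g2"), ordinal = 0:1,
    start = c(4000, 5500), end = c(5000, 5600)
  )
  raw <- tibble::tibble(
    gene_id = c("g1", "g2"), genome_id = "c", contig_id = "c",
    start = ctx$start, end = ctx$end, strand = "+", kegg_id = NA_character_
  )
  form <- read_distillate_form(
    system.file("extdata", "synthetic_distillate_form.tsv",
                package = "magdistill")
  )
  # contig long enough that only the left distance matters
  flags <- assign_flags(ctx, raw, form, c(c = 100000))
  # g1: distance 3999 -> F; g2: distance 5499 -> no F
  expect_true("F" %in% flags$flags[[1]])
  expect_false("F" %in% flags$flags[[2]])
  # exactly 5000 bases from the end is not within the window
  ctx$start <- c(5001, 6000)
  ctx$end <- c(5800, 6800)
  raw$start <- ctx$start
  raw$end <- ctx$end
  flags2 <- assign_flags(ctx, raw, form, c(c = 11800))
  expect_false("F" %in% flags2$flags[[1]])
})

test_that("default AMG rule keeps scores below 4 with M and no blockers", {
  cfg <- amg_call_config()
  ctx <- tibble::tibble(
    contig_id = "c", gene_id = paste0("g", 1:5), ordinal = 0:4,
    aux_score = 1:5, flags = rep(list("M"), 5)
  )
  called <- call_potential_amgs(ctx, cfg)
  expect_equal(called$aux_score, 1:3)
  # P flag blocks even a confident score
  ctx$flags[[2]] <- c("M", "P")
  expect_false("g2" %in% call_potential_amgs(ctx, cfg)$gene_id)
  ctx$flags[[1]] <- c("M", "B")
  expect_false("g1" %in% call_potential_amgs(ctx, cfg)$gene_id)
  # every called AMG carries M and no forbidden flag
  out <- call_potential_amgs(ctx, cfg)
  expect_true(all(purrr::map_lgl(out$flags, ~ "M" %in% .x)))
  expect_true(all(purrr::map_lgl(
    out$flags, ~ length(intersect(.x, cfg$forbidden_flags)) == 0
  )))
})

test_that("raising the score threshold never removes a called AMG", {
  fx <- viral_fixture("H P X P H")
  ctx <- fx$res$contexts
  prev <- character()
  for (thr in 1:6) {
    cfg <- amg_call_config_from_lists(max_aux_score_exclusive = thr)
    now <- call_potential_amgs(ctx, cfg)$gene_id
    expect_true(all(prev %in% now), info = paste("threshold", thr))
    prev <- now
  }
})

test_that("vMAG summary counts genes, strand switches and AMGs", {
  v <- generate_mock_viral_contig("H P X P H", seed = 2)
  v$affi$strand <- c("+", "+", "-", "-", "+")
  cfg <- amg_call_config_from_lists()
  res <- annotate_viral_contigs(v$affi, v$raw_table, v$form, v$contig_lengths,
                        config = cfg)
  s <- res$vmag_summary
  expect_equal(s$gene_count, 5)
  expect_equal(s$strand_switches, 2)
  expect_equal(s$amg_count, 1)

  meta <- tibble::tibble(
    contig_id = v$affi$contig_id[1], virsorter_category = 2L,
    is_circular = FALSE, is_prophage = FALSE
  )
  s2 <- summarize_vmag(res$contexts, meta, cfg)
  expect_equal(s2$virsorter_category, 2L)

  single <- generate_mock_viral_contig("X", seed = 3)
  res1 <- annotate_viral_contigs(single$affi, single$raw_table, single$form,
                         single$contig_lengths, config = cfg)
  expect_equal(res1$vmag_summary$strand_switches, 0)
})

test_that("AMG product counts calls per distillate category per contig", {
  fx <- viral_fixture("H P X P H")
  tab <- fx$res$amg_product$table
  # K00001 maps to the energy category
  expect_equal(tab$energy, 1)
  expect_equal(sum(tab[, setdiff(names(tab), c("contig_id", "energy"))]), 0)

  # a contig with no AMGs keeps an all-zero row
  fx5 <- viral_fixture("P X P P")
  tab5 <- fx5$res$amg_product$table
  expect_equal(nrow(tab5), 1)
  expect_true(all(tab5[, -1] == 0))

  p <- tempfile(fileext = ".html")
  render_amg_product_html(fx$res$amg_product, p)
  expect_true(file.exists(p))
})

test_that("viral tidy/glance report flags and call counts", {
  fx <- viral_fixture("H P X P H")
  t <- tidy(fx$res)
  expect_type(t$flags, "character")
  expect_equal(sum(t$is_amg), 1)
  g <- glance(fx$res)
  expect_equal(g$n_amgs, 1)
  expect_s3_class(ggplot2::autoplot(fx$res), "ggplot")
})
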