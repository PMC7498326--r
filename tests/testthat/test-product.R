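load_forms <- function() {
  modules <- read_module_table(
    system.file("extdata", "synthetic_modules.tsv", package = "magdistill")
  )
  list(
    pathways = modules[modules$block == "pathway", ],
    complexes = modules[modules$block == "complex", ],
    rules = read_function_rules(
      system.file("extdata", "synthetic_function_rules.tsv",
                  package = "magdistill")
    )
  )
}

raw_with_ids <- function(genome, kos) {
  tibble::tibble(
    gene_id = paste0(genome, "_g", seq_along(kos)),
    genome_id = genome, contig_id = paste0(genome, "_c"),
    start = seq_along(kos), end = seq_along(kos) + 1, strand = "+",
    rank = "C", status = "annotated", kegg_id = kos
  )
}

test_that("product table computes coverage, completion and presence", {
  f <- load_forms()
  raw <- dplyr::bind_rows(
    raw_with_ids("full", c("K00001", "K00002", "K00003", "K10944",
                           "K10945", "K10946", "K00399")),
    raw_with_ids("empty", NA_character_)
  )
  prod <- build_product_table(raw, f$pathways, f$complexes, f$rules)
  tab <- prod$table
  expect_equal(tab$module_M90001[tab$genome_id == "full"], 1)
  expect_equal(tab$complex_C90001[tab$genome_id == "full"], 1)
  expect_true(tab$function_methanogenesis_mcrA[tab$genome_id == "full"])
  expect_true(tab$function_ammonia_oxidation[tab$genome_id == "full"])
  empty <- tab[tab$genome_id == "empty", ]
  expect_true(all(as.numeric(empty[, -1]) == 0))
  # fractions stay within [0, 1] and every genome appears exactly once
  frac_cols <- prod$columns$column[prod$columns$block != "function_presence"]
  expect_true(all(as.matrix(tab[frac_cols]) >= 0 &
                    as.matrix(tab[frac_cols]) <= 1))
  expect_equal(anyDuplicated(tab$genome_id), 0)
})

test_that("genomes differing by one KO differ only in that KO's columns", {
  f <- load_forms()
  base_kos <- c("K00001", "K00002")
  raw <- dplyr::bind_rows(
    raw_with_ids("gA", base_kos),
    raw_with_ids("gB", c(base_kos, "K00003"))
  )
  prod <- build_product_table(raw, f$pathways, f$complexes, f$rules)
  tab <- prod$table
  differing <- names(tab)[-1][as.vector(
    tab[1, -1] != tab[2, -1]
  )]
  # every differing column must involve K00003
  defs <- c(
    setNames(f$pathways$definition, paste0("module_", f$pathways$module_id)),
    setNames(f$complexes$definition,
             paste0("complex_", f$complexes$module_id))
  )
  for (col in differing) {
    if (startsWith(col, "function_")) {
      rule <- f$rules[paste0("function_", f$rules$function_name) == col, ]
      expect_true("K00003" %in% unlist(rule$required_sets), info = col)
    } else {
      expect_true(grepl("K00003", defs[[col]]), info = col)
    }
  }
})

test_that("HTML heatmap is a view of the table, chunked at 1000 genomes", {
  f <- load_forms()
  raw <- raw_with_ids("g1", c("K00001", "K00002"))
  prod <- build_product_table(raw, f$pathways, f$complexes, f$rules)
  dir <- tempfile()
  paths <- render_product_html(prod, dir)
  expect_equal(length(paths), 1)
  html <- paste(readLines(paths[1]), collapse = "\n")
  vals <- as.numeric(regmatches(
    html, gregexpr("(?<=data-value=')[0-9.]+(?=')", html, perl = TRUE)
  )[[1]])
  expect_equal(sort(vals), sort(as.numeric(prod$table[1, -1])))
  # hover titles report percent completion
  expect_match(html, "% complete")
})

test_that("product chunking splits genome lists in order without overlap", {
  f <- load_forms()
  prod <- build_product_table(
    raw_with_ids("g1", "K00001"), f$pathways[1, ], f$complexes[1, ],
    f$rules[1, ]
  )
  big <- prod
  big$table <- tibble::tibble(
    genome_id = sprintf("g%04d", 1:2500),
    module_M90001 = runif(2500),
    complex_C90001 = runif(2500),
    function_methanogenesis_mcrA = FALSE
  )
  big$columns <- tibble::tibble(
    column = names(big$table)[-1],
    block = c("pathway_coverage", "complex_completion",
              "function_presence"),
    category = "x", name = names(big$table)[-1]
  )
  dir <- tempfile()
  paths <- render_product_html(big, dir)
  expect_equal(length(paths), 3)
  sizes <- vapply(paths, function(p) {
    length(grep("<text x='4'",
                readLines(p), fixed = TRUE, value = TRUE))
  }, integer(1))
  row_counts <- vapply(paths, function(p) {
    sum(grepl("genome g", readLines(p), fixed = FALSE))
  }, integer(1))
  genomes_seen <- unlist(lapply(paths, function(p) {
    html <- paste(readLines(p), collapse = "\n")
    regmatches(html, gregexpr("g[0-9]{4}", html))[[1]]
  }))
  expect_equal(unname(vapply(paths, function(p) {
    html <- paste(readLines(p), collapse = "\n")
    length(unique(regmatches(html, gregexpr("g[0-9]{4}", html))[[1]]))
  }, integer(1))), c(1000, 1000, 500))
  expect_equal(unique(genomes_seen), big$table$genome_id)

  # exactly 1000 genomes stays a single file
  one <- big
  one$table <- big$table[1:1000, ]
  expect_equal(length(render_product_html(one, tempfile())), 1)
})

test_that("empty product renders a valid page stating no genomes", {
  f <- load_forms()
  prod <- build_product_table(
    raw_with_ids("g1", "K00001")[0, ], f$pathways, f$complexes, f$rules,
    genome_ids = character()
  )
  path <- render_product_html(prod, tempfile())
  expect_match(paste(readLines(path), collapse = ""), "No genomes")
})

test_that("product tidy/autoplot expose the long table", {
  f <- load_forms()
  prod <- build_product_table(
    raw_with_ids("g1", c("K00001", "K00399")), f$pathways, f$complexes,
    f$rules
  )
  long <- tidy(prod)
  expect_equal(nrow(long), nrow(prod$columns))
  expect_s3_class(ggplot2::autoplot(prod), "ggplot")
})
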