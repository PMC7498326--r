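# Seeded generators for miniature, fully self-contained inputs: mock
# genomes with planted annotations, viral contigs with prescribed evidence
# layouts, and random module definitions with a brute-force completion
# oracle. Everything downstream is testable with no external database.

# Run code under a fixed seed without disturbing the caller's RNG state.
with_fixture_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())
    ), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Default plant plan for mock genomes
#'
#' One row per planted annotation: which gene of which genome receives a
#' hit, in which database, at which strength. `rbh` plants a forward hit
#' above the bit-score floor plus a reverse top hit above the reciprocal
#' threshold; `hit` plants a forward hit only; `weak` plants a hit below
#' the reporting thresholds (recovered by no rank).
#'
#' @return Tibble with `genome`, `gene_index`, `database`, `identifier`,
#'   `strength`, `description`.
#' @export
default_plant_plan <- function() {
  tibble::tribble(
    ~genome, ~gene_index, ~database, ~identifier, ~strength, ~description,
    1L, 1L, "kegg", "K00001", "rbh", "hexokinase",
    1L, 2L, "kegg", "K00002", "hit", "alcohol dehydrogenase",
    1L, 3L, "pfam", "PF00001", "hit", "7 transmembrane receptor",
    1L, 4L, "vogdb", "VOG00001", "hit", "sp|P03705 tail protein",
    2L, 1L, "kegg", "K00003", "rbh", "homoserine dehydrogenase",
    2L, 2L, "dbcan", "GH13", "hit", "alpha-amylase family",
    2L, 3L, "merops", "C26", "hit", "gamma-glutamyl hydrolase",
    2L, 4L, "kegg", "K00099", "weak", "hypothetical protein"
  )
}

#' Generate mock genomes with planted, recoverable annotations
#'
#' Builds contigs, gene calls and per-database hit tables whose downstream
#' annotation is known by construction: `rbh`-strength plants yield rank A
#' (KEGG) with forward bit scores above 60 and reverse scores above 350;
#' `hit` plants fall between the two thresholds; `weak` plants fall below
#' 60 (or below the model-coverage floor for profile databases); unplanted
#' genes come out rank E. The same seed reproduces identical output.
#'
#' @param n_genomes Number of genomes.
#' @param genes_per_genome Genes called per genome (one contig each).
#' @param plant_plan Tibble as in [default_plant_plan()].
#' @param seed Integer seed.
#' @param contig_length Contig length in bases (default 3000, above the
#'   2500 bp retention cutoff).
#' @return List with `contigs`, `genes`, `hits`, `reverse_hits`,
#'   `plant_plan`.
#' @export
generate_mock_genomes <- function(n_genomes = 2, genes_per_genome = 5,
                                  plant_plan = default_plant_plan(),
                                  seed = 1, contig_length = 3000) {
  with_fixture_seed(seed, {
    genomes <- sprintf("genome_%02d", seq_len(n_genomes))
    contigs <- tibble::tibble(
      id = sprintf("%s_contig_1", genomes),
      description = paste("mock contig of", genomes),
      sequence = vapply(genomes, function(g) random_seq(contig_length),
                        character(1), USE.NAMES = FALSE),
      genome_id = genomes
    )
    gene_len <- 300
    spacing <- floor(contig_length / genes_per_genome)
    genes <- tidyr::expand_grid(
      genome_id = genomes, index = seq_len(genes_per_genome)
    ) %>%
      mutate(
        gene_id = sprintf("%s_gene_%d", .data$genome_id, .data$index),
        contig_id = sprintf("%s_contig_1", .data$genome_id),
        start = (.data$index - 1) * spacing + 1,
        end = (.data$index - 1) * spacing + gene_len,
        strand = sample(c("+", "-"), dplyr::n(), replace = TRUE),
        protein = vapply(seq_len(dplyr::n()), function(i) {
          random_seq(gene_len / 3, AA_ALPHABET)
        }, character(1))
      ) %>%
      select(-"index", "gene_id", dplyr::everything())

    hmm_dbs <- HMM_DATABASES
    hits <- list()
    reverse <- list()
    for (i in seq_len(nrow(plant_plan))) {
      p <- plant_plan[i, ]
      gene <- sprintf("genome_%02d_gene_%d", p$genome, p$gene_index)
      is_hmm <- p$database %in% hmm_dbs
      bit <- switch(p$strength,
        rbh = round(runif(1, 380, 450), 1),
        hit = round(runif(1, 70, 300), 1),
        weak = round(runif(1, 20, 55), 1)
      )
      hits[[i]] <- tibble::tibble(
        query_id = gene, target_id = p$identifier,
        database = p$database, bit_score = bit,
        e_value = if (p$strength == "weak" && is_hmm) 1e-5 else 1e-30,
        model_coverage = if (is_hmm) {
          if (p$strength == "weak") 0.2 else round(runif(1, 0.5, 1), 2)
        } else {
          NA_real_
        },
        description = p$description
      )
      if (p$strength == "rbh") {
        reverse[[length(reverse) + 1]] <- tibble::tibble(
          query_id = p$identifier, target_id = gene,
          database = p$database, bit_score = round(runif(1, 360, 450), 1),
          e_value = 1e-40
        )
      }
    }
    list(
      contigs = contigs,
      genes = genes %>% select(
        "gene_id", "genome_id", "contig_id", "start", "end", "strand",
        "protein"
      ),
      hits = dplyr::bind_rows(hits),
      reverse_hits = dplyr::bind_rows(reverse),
      plant_plan = plant_plan
    )
  })
}

# Layout token -> (evidence code, metabolic?, target?)
parse_viral_layout <- function(layout) {
  tokens <- if (length(layout) == 1) {
    strsplit(gsub("[. ]+", " ", trimws(layout)), " ")[[1]]
  } else {
    layout
  }
  if (!all(tokens %in% c("H", "L", "M", "P", "X"))) {
    md_abort("Layout tokens must be H, L, M, P or X", "layout_error")
  }
  if (sum(tokens == "X") != 1) {
    md_abort("Layout must contain exactly one target gene X",
             "layout_error")
  }
  tokens
}

#' Generate a mock viral contig from an evidence layout
#'
#' The layout is a string over `H` (hallmark-evidence gene), `L`
#' (viral-like), `M` (plain metabolic gene), `P` (plain gene, no evidence,
#' no metabolism) and exactly one `X` (the target gene, metabolic, no
#' viral evidence), e.g. `"H X H"`. Evidence codes are chosen so the
#' default evidence map reproduces the layout, and the target/metabolic
#' genes carry an identifier present in the bundled distillate form, so
#' the target's expected auxiliary score and flags follow from the layout
#' by the published scoring rules.
#'
#' @param layout Layout string (or character vector of tokens).
#' @param contig_id Contig name.
#' @param seed Integer seed.
#' @param gene_length,spacing Gene span and start-to-start distance in
#'   bases.
#' @return List with `affi` (affiliation rows), `raw_table` (annotations
#'   for these genes), `contig_lengths`, `form` (the bundled synthetic
#'   form), `target_gene_id` and `tokens`.
#' @export
generate_mock_viral_contig <- function(layout, contig_id = "vcontig_1",
                                       seed = 1, gene_length = 900,
                                       spacing = 1000) {
  tokens <- parse_viral_layout(layout)
  with_fixture_seed(seed, {
    n <- length(tokens)
    gene_ids <- sprintf("%s_gene_%d", contig_id, seq_len(n))
    start <- (seq_len(n) - 1) * spacing + 1
    end <- start + gene_length - 1
    affi <- tibble::tibble(
      contig_id = contig_id,
      gene_id = gene_ids,
      ordinal = seq_len(n) - 1L,
      start = start, end = end,
      strand = sample(c("+", "-"), n, replace = TRUE),
      evidence_code = dplyr::case_when(
        tokens == "H" ~ "0",
        tokens == "L" ~ "1",
        TRUE ~ "-"
      )
    )
    metabolic <- tokens %in% c("M", "X")
    raw_table <- tibble::tibble(
      gene_id = gene_ids,
      genome_id = contig_id,
      contig_id = contig_id,
      start = start, end = end, strand = affi$strand,
      rank = if_else(metabolic, "A", "E"),
      status = if_else(metabolic, "annotated", "unannotated"),
      kegg_id = if_else(metabolic, "K00001", NA_character_),
      kegg_description = if_else(metabolic, "hexokinase", NA_character_),
      kegg_bit_score = if_else(metabolic, 400, NA_real_),
      kegg_e_value = if_else(metabolic, 1e-40, NA_real_),
      vogdb_id = if_else(tokens == "H", "VOG00002", NA_character_),
      vogdb_description = if_else(
        tokens == "H", "sp|P03711 major capsid protein [Xs] structure",
        NA_character_
      ),
      vogdb_bit_score = if_else(tokens == "H", 120, NA_real_),
      vogdb_e_value = if_else(tokens == "H", 1e-30, NA_real_)
    )
    contig_lengths <- setNames(n * spacing + 200, contig_id)
    list(
      affi = affi,
      raw_table = raw_table,
      contig_lengths = contig_lengths,
      form = read_distillate_form(
        system.file("extdata", "synthetic_distillate_form.tsv",
                    package = "magdistill")
      ),
      target_gene_id = gene_ids[tokens == "X"],
      tokens = tokens
    )
  })
}

#' Brute-force best-path completion by exhaustive path enumeration
#'
#' Enumerates every simple source-to-sink path of the module network and
#' returns the maximum fraction of present weight — the reference answer
#' the dynamic-programming scorer must reproduce on small modules.
#'
#' @param network A `module_network` (or module tree / definition string).
#' @param present Character vector of observed identifiers.
#' @return Fraction in `[0, 1]`.
#' @export
brute_force_completion <- function(network, present) {
  if (!inherits(network, "module_network")) {
    network <- build_module_network(network)
  }
  g <- as_igraph(network)
  paths <- igraph::all_simple_paths(
    g,
    from = as.character(network$source), to = as.character(network$sink),
    mode = "out"
  )
  if (length(paths) == 0) {
    md_abort("Network has no source-to-sink path", "network_error")
  }
  best <- 0
  any_weighted <- FALSE
  for (p in paths) {
    idx <- as.integer(names(p))
    subs <- network$nodes$subunits[idx]
    total <- sum(lengths(subs))
    if (total == 0) next
    any_weighted <- TRUE
    got <- sum(vapply(subs, function(s) sum(s %in% present), numeric(1)))
    best <- max(best, got / total)
  }
  if (!any_weighted) {
    md_abort("Network has no weighted path", "network_error")
  }
  best
}

random_module_tree <- function(budget, ko_pool, allow_seq = TRUE) {
  take_ko <- function() {
    ko <- ko_pool$ids[ko_pool$next_i]
    ko_pool$next_i <- ko_pool$next_i + 1
    ko
  }
  if (budget <= 1) {
    return(module_node("LEAF", ko = take_ko()))
  }
  kind <- sample(
    c(if (allow_seq) "STEP_SEQUENCE", "ALTERNATIVE", "COMPLEX", "LEAF"),
    1,
    prob = c(if (allow_seq) 0.35, 0.3, 0.2,
             if (allow_seq) 0.15 else 0.5)
  )
  if (kind == "LEAF") {
    return(module_node("LEAF", ko = take_ko()))
  }
  if (kind == "COMPLEX") {
    k <- sample(2:min(3, budget), 1)
    return(module_node(
      "COMPLEX",
      lapply(seq_len(k), function(i) module_node("LEAF", ko = take_ko()))
    ))
  }
  k <- sample(2:min(3, budget), 1)
  shares <- rep(1L, k)
  extra <- budget - k
  while (extra > 0) {
    j <- sample(k, 1)
    shares[j] <- shares[j] + 1L
    extra <- extra - 1L
  }
  children <- lapply(shares, function(b) {
    random_module_tree(b, ko_pool, allow_seq = kind == "STEP_SEQUENCE")
  })
  module_node(kind, children)
}

#' Generate random module definitions with oracle completion answers
#'
#' Emits grammar-valid random module definitions of bounded size together
#' with exhaustive-path completion answers for sampled presence sets, so
#' the dynamic-programming scorer can be validated case by case.
#'
#' @param n Number of modules.
#' @param max_kos Maximum orthology identifiers per module (<= 12 keeps
#'   exhaustive enumeration cheap).
#' @param seed Integer seed.
#' @param presence_sets_per_module Presence sets sampled per module.
#' @param optional_prob Probability of appending an optional trailing
#'   component to a definition.
#' @return List with `modules` (tibble `module_id`, `name`, `definition`)
#'   and `answers` (tibble `module_id`, `present` comma-joined,
#'   `completion` from [brute_force_completion()]).
#' @export
generate_mini_module_set <- function(n = 200, max_kos = 12, seed = 7,
                                     presence_sets_per_module = 1,
                                     optional_prob = 0.15) {
  stopifnot(max_kos <= 12)
  with_fixture_seed(seed, {
    modules <- vector("list", n)
    answers <- list()
    for (i in seq_len(n)) {
      budget <- sample(2:max_kos, 1)
      pool <- new.env(parent = emptyenv())
      pool$ids <- sprintf("K%05d", sample(99999, max_kos + 1))
      pool$next_i <- 1
      tree <- random_module_tree(budget, pool)
      def <- deparse_module_definition(tree)
      if (runif(1) < optional_prob) {
        def <- paste0(def, " -", pool$ids[pool$next_i])
      }
      module_id <- sprintf("MF%04d", i)
      modules[[i]] <- tibble::tibble(
        module_id = module_id,
        name = paste("random module", i),
        definition = def
      )
      kos <- module_leaves(parse_module_definition(def))
      for (j in seq_len(presence_sets_per_module)) {
        k <- sample(0:length(kos), 1)
        present <- sample(kos, k)
        completion <- brute_force_completion(def, present)
        answers[[length(answers) + 1]] <- tibble::tibble(
          module_id = module_id,
          present = paste(sort(present), collapse = ","),
          completion = completion
        )
      }
    }
    list(
      modules = dplyr::bind_rows(modules),
      answers = dplyr::bind_rows(answers)
    )
  })
}

#' Generate a tRNA/rRNA feature table for mock genomes
#'
#' @param genome_ids Genomes to cover.
#' @param n_trna tRNAs per genome.
#' @param rrnas rRNA types present in every genome.
#' @param seed Integer seed.
#' @return RNA feature tibble (`genome_id`, `contig_id`, `type`, `start`,
#'   `end`).
#' @export
generate_mock_rna_table <- function(genome_ids, n_trna = 20,
                                    rrnas = c("5S", "16S", "23S"),
                                    seed = 1) {
  with_fixture_seed(seed, {
    purrr::map_dfr(genome_ids, function(g) {
      types <- c(
        paste0("tRNA-", sample(c(
          "Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
          "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
          "Tyr", "Val"
        ), n_trna, replace = n_trna > 20)),
        rrnas
      )
      starts <- sort(sample(10000, length(types)))
      tibble::tibble(
        genome_id = g,
        contig_id = paste0(g, "_contig_1"),
        type = types,
        start = starts,
        end = starts + if_else(grepl("^tRNA", types), 75L, 1500L)
      )
    })
  })
}

#' Write a complete miniature test workspace
#'
#' Materializes every input file the pipeline consumes — genome FASTA,
#' gene-call protein FASTA, per-database hit tables, reverse-search hits,
#' per-model thresholds, a viral affiliation table, module and form
#' tables, RNA features and user taxonomy/quality tables — generated from
#' one seed.
#'
#' @param dir Destination directory (created).
#' @param seed Integer seed.
#' @return Named list of the paths written, invisibly.
#' @export
generate_fixture_workspace <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mock <- generate_mock_genomes(seed = seed)
  paths <- list()
  paths$genomes <- file.path(dir, "genomes.fna")
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(setNames(
      mock$contigs$sequence,
      paste(mock$contigs$id, mock$contigs$description)
    )),
    paths$genomes
  )
  paths$genes <- file.path(dir, "genes.tsv")
  readr::write_tsv(mock$genes, paths$genes)
  paths$proteins <- file.path(dir, "genes.faa")
  write_gene_fasta(mock$genes, paths$proteins)
  for (db in unique(mock$hits$database)) {
    sub <- mock$hits[mock$hits$database == db, ]
    p <- file.path(dir, paste0("hits_", db, ".tsv"))
    if (db %in% HMM_DATABASES) {
      # re-derive model coordinates consistent with the planted coverage
      model_length <- 100L
      aln_len <- pmax(1L, round(sub$model_coverage * model_length))
      readr::write_tsv(
        tibble::tibble(
          query_id = sub$query_id, model_id = sub$target_id,
          model_length = model_length, model_from = 1L,
          model_to = aln_len, e_value = sub$e_value,
          bit_score = sub$bit_score, description = sub$description
        ),
        p
      )
    } else {
      # 12-column alignment dialect plus a 13th description column
      readr::write_tsv(
        tibble::tibble(
          query = sub$query_id, target = sub$target_id,
          identity = 90, length = 100, mismatches = 10, gaps = 0,
          qstart = 1, qend = 100, tstart = 1, tend = 100,
          e_value = sub$e_value, bit_score = sub$bit_score,
          description = sub$description
        ),
        p, col_names = FALSE
      )
    }
    paths[[paste0("hits_", db)]] <- p
  }
  paths$reverse_hits <- file.path(dir, "reverse_hits.tsv")
  readr::write_tsv(mock$reverse_hits, paths$reverse_hits)

  # one contig with a callable AMG, one whose metabolic stretch blocks it
  viral1 <- generate_mock_viral_contig("H P X P H", contig_id = "vcontig_1",
                                       seed = seed)
  viral2 <- generate_mock_viral_contig("H M X M H", contig_id = "vcontig_2",
                                       seed = seed + 1)
  paths$affi <- file.path(dir, "affi_contigs.tab")
  affi_block <- function(v) {
    c(
      paste0(">", v$affi$contig_id[1]),
      sprintf(
        "%s|%d|%d|%s|%s",
        v$affi$gene_id, v$affi$start, v$affi$end,
        v$affi$strand, v$affi$evidence_code
      )
    )
  }
  writeLines(c(affi_block(viral1), affi_block(viral2)), paths$affi)
  paths$viral_raw <- file.path(dir, "viral_annotations.tsv")
  readr::write_tsv(
    dplyr::bind_rows(viral1$raw_table, viral2$raw_table),
    paths$viral_raw, na = ""
  )

  rna <- generate_mock_rna_table(unique(mock$contigs$genome_id),
                                 seed = seed)
  paths$rna <- file.path(dir, "rna_features.tsv")
  readr::write_tsv(rna, paths$rna)

  paths$quality <- file.path(dir, "user_quality.tsv")
  readr::write_tsv(
    tibble::tibble(
      genome_id = unique(mock$contigs$genome_id),
      completeness = c(95, 60)[seq_along(unique(mock$contigs$genome_id))],
      contamination = c(2, 4)[seq_along(unique(mock$contigs$genome_id))]
    ),
    paths$quality
  )
  paths$taxonomy <- file.path(dir, "user_taxonomy.tsv")
  readr::write_tsv(
    tibble::tibble(
      genome_id = unique(mock$contigs$genome_id),
      taxonomy = paste0("d__Bacteria;g__Mock", seq_along(
        unique(mock$contigs$genome_id)
      ))
    ),
    paths$taxonomy
  )

  for (f in c("synthetic_distillate_form.tsv", "synthetic_modules.tsv",
              "synthetic_function_rules.tsv", "synthetic_amg_lists.tsv",
              "synthetic_kofam_thresholds.tsv")) {
    file.copy(system.file("extdata", f, package = "magdistill"),
              file.path(dir, f), overwrite = TRUE)
    paths[[f]] <- file.path(dir, f)
  }
  invisible(paths)
}
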