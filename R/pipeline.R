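# End-to-end convenience wrappers: AMG list loading and the full
# annotate -> distill -> product -> viral pipeline over a fixture
# workspace or user files.

#' Read curated AMG identifier lists
#'
#' The list file is tab-delimited with columns `identifier` and `list`
#' (`known`, `verified`, `attachment`, `peptidase`, `transposon`); the
#' bundled copy is a synthetic stand-in with the same schema as the
#' published curated lists.
#'
#' @param path List TSV; defaults to the bundled synthetic lists.
#' @return Named list of character vectors (`known`, `verified`,
#'   `attachment`, `peptidase`, `transposon`).
#' @export
read_amg_lists <- function(path = system.file(
                             "extdata", "synthetic_amg_lists.tsv",
                             package = "magdistill"
                           )) {
  raw <- readr::read_tsv(
    path, col_types = readr::cols(.default = readr::col_character())
  )
  lapply(
    setNames(nm = c("known", "verified", "attachment", "peptidase",
                    "transposon")),
    function(l) raw$identifier[raw$list == l]
  )
}

#' Build an AMG-calling config from a list file
#'
#' @param path AMG list TSV (see [read_amg_lists()]).
#' @param ... Further arguments passed to [amg_call_config()].
#' @return An [amg_call_config()].
#' @export
amg_call_config_from_lists <- function(path = system.file(
                                         "extdata",
                                         "synthetic_amg_lists.tsv",
                                         package = "magdistill"
                                       ), ...) {
  lists <- read_amg_lists(path)
  amg_call_config(
    known_amg_ids = lists$known,
    verified_amg_ids = lists$verified,
    attachment_ids = lists$attachment,
    viral_peptidase_families = lists$peptidase,
    transposon_ids = lists$transposon,
    ...
  )
}

#' Run the full pipeline over a fixture workspace
#'
#' Reads every file of a workspace written by
#' [generate_fixture_workspace()] and chains the four stages: annotation
#' (contig filtering, best hits, reciprocal confirmation, ranks),
#' distillation (genome stats and identifier counts), product (coverage,
#' completion, presence, HTML heatmap) and viral AMG calling.
#'
#' @param dir Workspace directory.
#' @param output_dir Where outputs are written (default
#'   `file.path(dir, "output")`).
#' @param config An [annotation_config()].
#' @return List with `annotation`, `stats`, `distillate`, `product`,
#'   `viral` and `paths`.
#' @export
run_pipeline <- function(dir, output_dir = file.path(dir, "output"),
                         config = annotation_config()) {
  contigs_all <- read_fasta(file.path(dir, "genomes.fna"))
  genome_of <- sub("_contig_.*$", "", contigs_all$id)
  contigs_all$genome_id <- genome_of
  contigs <- filter_contigs(contigs_all, config)
  genes <- readr::read_tsv(
    file.path(dir, "genes.tsv"),
    col_types = readr::cols(
      start = readr::col_double(), end = readr::col_double(),
      .default = readr::col_character()
    )
  ) %>% filter(.data$contig_id %in% contigs$id)

  hit_files <- list.files(dir, pattern = "^hits_.*\\.tsv$",
                          full.names = TRUE)
  hits <- purrr::map_dfr(hit_files, function(p) {
    db <- sub("^hits_(.*)\\.tsv$", "\\1", basename(p))
    if (db %in% HMM_DATABASES) {
      read_hmm_hits(p, db)
    } else {
      read_hit_table(
        p, db,
        col_map = c(default_hit_col_map()[1:4], list(description = 13L))
      )
    }
  })
  reverse_path <- file.path(dir, "reverse_hits.tsv")
  reverse_hits <- if (file.exists(reverse_path)) {
    readr::read_tsv(reverse_path, col_types = readr::cols(
      bit_score = readr::col_double(), e_value = readr::col_double(),
      .default = readr::col_character()
    ))
  }
  thresholds <- read_kofam_thresholds(
    file.path(dir, "synthetic_kofam_thresholds.tsv")
  )
  annotation <- annotate_genes(genes, hits, reverse_hits, thresholds,
                               config)

  rna <- readr::read_tsv(
    file.path(dir, "rna_features.tsv"),
    col_types = readr::cols(
      start = readr::col_double(), end = readr::col_double(),
      .default = readr::col_character()
    )
  )
  quality <- readr::read_tsv(
    file.path(dir, "user_quality.tsv"),
    col_types = readr::cols(
      genome_id = readr::col_character(),
      .default = readr::col_double()
    )
  )
  taxonomy <- readr::read_tsv(
    file.path(dir, "user_taxonomy.tsv"),
    col_types = readr::cols(.default = readr::col_character())
  )
  stats <- summarize_genome_stats(contigs, rna, quality, taxonomy)

  form <- read_distillate_form(
    file.path(dir, "synthetic_distillate_form.tsv")
  )
  distillate <- build_distillate(annotation, form)

  modules_all <- read_module_table(file.path(dir, "synthetic_modules.tsv"))
  rules <- read_function_rules(
    file.path(dir, "synthetic_function_rules.tsv")
  )
  product <- build_product_table(
    annotation,
    modules = modules_all %>% filter(.data$block == "pathway"),
    complexes = modules_all %>% filter(.data$block == "complex"),
    function_rules = rules
  )

  affi <- read_virsorter_affi(file.path(dir, "affi_contigs.tab"))
  viral_raw <- read_raw_table(file.path(dir, "viral_annotations.tsv"))
  amg_config <- amg_call_config_from_lists(
    file.path(dir, "synthetic_amg_lists.tsv")
  )
  contig_lengths <- setNames(
    vapply(split(affi$end, affi$contig_id), max, numeric(1)) + 200,
    names(split(affi$end, affi$contig_id))
  )
  viral <- annotate_viral_contigs(affi, viral_raw, form, contig_lengths,
                          config = amg_config)

  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_annotation_outputs(
    annotation$raw, genes, contigs, output_dir, rna
  )
  paths$distillate <- write_distillate(distillate, stats,
                                       file.path(output_dir, "distillate"))
  paths$product_html <- render_product_html(
    product, file.path(output_dir, "product")
  )
  paths$product_tsv <- write_product_table(
    product, file.path(output_dir, "product", "product.tsv")
  )
  paths$vmag_summary <- file.path(output_dir, "vmag_summary.tsv")
  readr::write_tsv(viral$vmag_summary, paths$vmag_summary)
  paths$amg_product <- file.path(output_dir, "amg_product.html")
  render_amg_product_html(viral$amg_product, paths$amg_product)

  list(
    annotation = annotation, stats = stats, distillate = distillate,
    product = product, viral = viral, paths = paths
  )
}
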