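# Distillate: per-genome statistics with MIMAG-style quality ranks, and
# per-genome function-identifier counts organized by metabolic category.

#' Extract function identifiers from a raw annotation table
#'
#' Scans the KO (KEGG/KOfam), CAZyme-family (dbCAN), peptidase-family
#' (MEROPS) and Pfam accession fields of the merged annotation and returns
#' one row per distinct (gene, identifier) pair. Identifiers are normalized
#' by stripping a trailing version suffix (`PF00001.21` -> `PF00001`); case
#' is preserved.
#'
#' @param raw_table Raw annotation tibble ([merge_raw_table()]).
#' @return Tibble with `genome_id`, `gene_id`, `identifier`.
#' @export
gene_identifiers <- function(raw_table) {
  id_cols <- intersect(
    c("kegg_id", "kofam_id", "dbcan_id", "merops_id", "pfam_id"),
    names(raw_table)
  )
  raw_table %>%
    select("genome_id", "gene_id", all_of(id_cols)) %>%
    tidyr::pivot_longer(
      all_of(id_cols),
      names_to = "source", values_to = "identifier"
    ) %>%
    filter(!is.na(.data$identifier) & nzchar(.data$identifier)) %>%
    mutate(identifier = sub("\\.\\d+$", "", .data$identifier)) %>%
    distinct(.data$genome_id, .data$gene_id, .data$identifier)
}

#' Per-genome assembly and RNA statistics
#'
#' Collects the genome-size and RNA metrics needed for MIMAG-style quality
#' reporting: contig count, total assembly length, tRNA count and rRNA
#' (5S/16S/23S) positions, plus user-provided completeness, contamination
#' and taxonomy passed through unmodified. RNA features come from external
#' detectors as a feature table.
#'
#' @param contigs Contig tibble with `genome_id` (and `sequence`).
#' @param rna_table Optional tibble with `genome_id`, `contig_id`, `type`
#'   (`tRNA-*` or `5S`/`16S`/`23S`), `start`, `end`.
#' @param user_quality Optional tibble `genome_id`, `completeness`,
#'   `contamination` (percent). Unknown genome ids warn and are ignored.
#' @param user_taxonomy Optional tibble `genome_id`, `taxonomy`.
#' @return Tibble with one row per genome: `genome_id`, `contig_count`,
#'   `total_length`, `n_trna`, `rrna_5s`, `rrna_16s`, `rrna_23s` (counts),
#'   `completeness`, `contamination`, `taxonomy`, `quality`.
#' @export
summarize_genome_stats <- function(contigs, rna_table = NULL,
                                   user_quality = NULL,
                                   user_taxonomy = NULL) {
  stats <- contigs %>%
    group_by(genome_id = .data$genome_id) %>%
    summarise(
      contig_count = dplyr::n(),
      total_length = sum(nchar(.data$sequence)),
      .groups = "drop"
    )
  count_rna <- function(pattern) {
    if (is.null(rna_table)) {
      return(rep(0L, nrow(stats)))
    }
    sub <- rna_table[grepl(pattern, rna_table$type), ]
    counts <- table(sub$genome_id)
    as.integer(counts[stats$genome_id]) %>% tidyr::replace_na(0L)
  }
  stats <- stats %>% mutate(
    n_trna = count_rna("^tRNA"),
    rrna_5s = count_rna("^5S"),
    rrna_16s = count_rna("^16S"),
    rrna_23s = count_rna("^23S"),
    completeness = NA_real_,
    contamination = NA_real_,
    taxonomy = NA_character_
  )
  merge_user <- function(stats, user, cols, what) {
    if (is.null(user)) {
      return(stats)
    }
    unknown <- setdiff(user$genome_id, stats$genome_id)
    if (length(unknown) > 0) {
      rlang::warn(paste0(
        "Unknown genome id(s) in user ", what, " table: ",
        paste(unknown, collapse = ", ")
      ))
    }
    idx <- match(stats$genome_id, user$genome_id)
    for (cl in cols) {
      stats[[cl]] <- dplyr::coalesce(user[[cl]][idx], stats[[cl]])
    }
    stats
  }
  stats <- merge_user(stats, user_quality,
                      c("completeness", "contamination"), "quality")
  stats <- merge_user(stats, user_taxonomy, "taxonomy", "taxonomy")
  assign_quality(stats)
}

#' Assign the MIMAG-style quality rank
#'
#' High-quality draft: completeness above 90%, contamination below 5%, at
#' least one each of the 5S, 16S and 23S rRNAs, and 18 or more tRNAs.
#' Medium-quality draft: completeness at least 50% and contamination below
#' 10%. Everything else (including genomes with no completeness estimate)
#' is low quality.
#'
#' @param stats Genome-stats tibble ([summarize_genome_stats()] schema).
#' @param thresholds Threshold list from [mimag_thresholds()].
#' @return `stats` with the `quality` column (re)computed.
#' @export
assign_quality <- function(stats, thresholds = mimag_thresholds()) {
  stats %>% mutate(
    quality = dplyr::case_when(
      !is.na(.data$completeness) & !is.na(.data$contamination) &
        .data$completeness > thresholds$high_completeness &
        .data$contamination < thresholds$high_contamination &
        .data$rrna_5s > 0 & .data$rrna_16s > 0 & .data$rrna_23s > 0 &
        .data$n_trna >= thresholds$high_min_trna ~ "high",
      !is.na(.data$completeness) & !is.na(.data$contamination) &
        .data$completeness >= thresholds$medium_completeness &
        .data$contamination < thresholds$medium_contamination ~ "medium",
      TRUE ~ "low"
    )
  )
}

#' Build the distillate: per-genome function-identifier counts
#'
#' For every row of the distillate form, counts the genes in each genome
#' whose merged annotation carries that identifier (once per gene and
#' identifier, however many databases agree). An identifier mapped to
#' several form rows — e.g. a CAZyme family promiscuous for multiple
#' substrates — is counted in each of them. Identifiers observed in no
#' genome keep their all-zero row.
#'
#' @param raw_table Raw annotation tibble, or a `mag_annotation`.
#' @param form Distillate form tibble ([read_distillate_form()]).
#' @param genome_ids Optional genome ordering; defaults to order of first
#'   appearance in `raw_table`.
#' @return An object of class `mag_distillate`: tibble with `identifier`,
#'   `description`, `category`, `subcategory` and one count column per
#'   genome.
#' @export
build_distillate <- function(raw_table, form, genome_ids = NULL) {
  if (inherits(raw_table, "mag_annotation")) raw_table <- raw_table$raw
  if (any(is.na(form$identifier) | !nzchar(form$identifier))) {
    md_abort("Form row with empty identifier", "form_error")
  }
  genome_ids <- genome_ids %||% unique(raw_table$genome_id)
  ids <- gene_identifiers(raw_table)
  counts <- ids %>%
    dplyr::count(.data$genome_id, .data$identifier, name = "count")
  out <- form %>%
    select("identifier", "description", "category", "subcategory")
  for (g in genome_ids) {
    sub <- counts[counts$genome_id == g, ]
    out[[g]] <- dplyr::coalesce(
      sub$count[match(out$identifier, sub$identifier)], 0L
    )
  }
  structure(out, class = c("mag_distillate", class(out)))
}

#' Split a distillate into per-category sheets
#'
#' @param distillate A `mag_distillate`.
#' @return Named list of tibbles, one per category.
#' @export
distillate_sheets <- function(distillate) {
  split(
    tibble::as_tibble(distillate), distillate$category
  )
}

#' Write distillate outputs
#'
#' Writes the genome-stats TSV and one TSV per distillate category.
#'
#' @param distillate A `mag_distillate`.
#' @param stats Genome-stats tibble.
#' @param dir Output directory.
#' @return Character vector of paths written, invisibly.
#' @export
write_distillate <- function(distillate, stats, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "genome_stats.tsv")
  readr::write_tsv(stats, paths)
  for (nm in names(distillate_sheets(distillate))) {
    p <- file.path(
      dir, paste0("distillate_", gsub("[^A-Za-z0-9]+", "_", nm), ".tsv")
    )
    readr::write_tsv(distillate_sheets(distillate)[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
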