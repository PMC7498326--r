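# Viral annotation engine: classify per-gene viral evidence, assign
# auxiliary scores 1-5 and curation flags, call potential auxiliary
# metabolic genes (AMGs), and summarize viral contigs.

VALID_FLAGS <- c("V", "M", "K", "E", "A", "P", "F", "T", "B")

#' Classify per-gene viral evidence
#'
#' Maps the raw evidence-code tokens of an affiliation table through a
#' configurable table to `hallmark`, `viral_like` or `none`. Unmapped codes
#' classify as `none` with a warning, so new upstream tokens degrade
#' conservatively instead of failing.
#'
#' @param affi Tibble from [read_virsorter_affi()].
#' @param evidence_map Named character vector (see
#'   [default_evidence_map()]).
#' @return `affi` with an `evidence` column added.
#' @export
classify_viral_evidence <- function(affi,
                                    evidence_map = default_evidence_map()) {
  mapped <- unname(evidence_map[affi$evidence_code])
  unmapped <- unique(affi$evidence_code[is.na(mapped)])
  if (length(unmapped) > 0) {
    rlang::warn(paste0(
      "Unmapped evidence code(s) classified as 'none': ",
      paste(unmapped, collapse = ", ")
    ))
  }
  affi %>% mutate(evidence = dplyr::coalesce(mapped, "none"))
}

# Runs of >= k consecutive TRUE values -> logical membership vector.
in_run_of <- function(x, k) {
  if (length(x) == 0) {
    return(logical())
  }
  r <- rle(x)
  rep(r$values & r$lengths >= k, r$lengths)
}

score_one_contig <- function(evidence, metabolic, stretch_min) {
  n <- length(evidence)
  lev <- c(hallmark = 2L, viral_like = 1L, none = 0L)[evidence]
  has_viral <- any(lev > 0)
  flank_max <- function(idx) if (length(idx) == 0) 0L else max(lev[idx])
  base <- vapply(seq_len(n), function(i) {
    if (!has_viral) {
      return(5L)
    }
    if (i == 1L || i == n) {
      return(5L)
    }
    left <- flank_max(seq_len(i - 1L))
    right <- flank_max(seq((i + 1L), n))
    if (left > 0 && right > 0) {
      if (left == 2L && right == 2L) 1L
      else if (min(left, right) == 1L && max(left, right) == 2L) 2L
      else 3L
    } else if (left > 0 || right > 0) {
      4L
    } else {
      5L
    }
  }, integer(1))
  # Genes inside a stretch of >= stretch_min adjacent metabolic (non-viral)
  # genes are raised to 4; a 5 is never lowered.
  stretch <- in_run_of(metabolic, stretch_min)
  pmax(base, if_else(stretch, 4L, 1L))
}

#' Assign auxiliary scores 1-5 along viral contigs
#'
#' The auxiliary score expresses confidence (1 best) that a gene is
#' genuinely virally encoded, from the viral evidence on its flanks — all
#' genes strictly left and strictly right of it on the contig. Score 1: at
#' least one hallmark gene on both flanks. 2: hallmark on one flank,
#' viral-like on the other. 3: viral-like on both flanks. 4: viral evidence
#' on exactly one flank, or membership in a stretch of three or more
#' adjacent non-viral metabolic genes (which can only worsen a score to 4).
#' 5: contigs without any viral evidence, terminal genes, and genes with no
#' viral evidence on either flank. When several rules apply the worst
#' (largest) applicable score wins.
#'
#' @param evidence Tibble with `contig_id`, `ordinal` and `evidence`
#'   columns ([classify_viral_evidence()]).
#' @param metabolic Optional logical vector (parallel to `evidence` rows):
#'   gene has non-viral metabolic function (flag M and not V). Default: no
#'   gene is.
#' @param config An [amg_call_config()] (supplies
#'   `metabolic_stretch_min`).
#' @return `evidence` with an `aux_score` integer column added.
#' @export
assign_auxiliary_score <- function(evidence, metabolic = NULL,
                                   config = amg_call_config()) {
  metabolic <- metabolic %||% rep(FALSE, nrow(evidence))
  stopifnot(length(metabolic) == nrow(evidence))
  ord <- order(evidence$contig_id, evidence$ordinal)
  if (is.unsorted(ord)) {
    md_abort("evidence must be ordered by contig and ordinal",
             "contract_error")
  }
  evidence$.metabolic <- metabolic
  out <- evidence %>%
    group_by(.data$contig_id) %>%
    mutate(aux_score = score_one_contig(
      .data$evidence, .data$.metabolic, config$metabolic_stretch_min
    )) %>%
    ungroup()
  out$.metabolic <- NULL
  out
}

# Identifiers per gene as a named list, from the raw annotation table.
identifiers_by_gene <- function(raw_table) {
  ids <- gene_identifiers(raw_table)
  split(ids$identifier, ids$gene_id)
}

#' Assign AMG curation flags
#'
#' Flags qualify each gene on a viral contig: `V` viral function (a VOGDB
#' hit with a replication or structure category), `M` metabolic (any
#' identifier present in the distillate form), `K` known AMG, `E`
#' experimentally verified AMG, `A` viral host attachment/entry, `P`
#' viral-associated peptidase family, `F` within `end_window` (default
#' 5000) bases of a contig end, `T` on a contig that contains a transposon,
#' `B` inside a run of three or more consecutive `M`-flagged genes.
#'
#' @param contexts Tibble of viral gene contexts: `contig_id`, `gene_id`,
#'   `ordinal`, `start`, `end`.
#' @param raw_table Raw annotation tibble for these genes (supplies
#'   identifiers, VOGDB and MEROPS fields).
#' @param form Distillate form tibble (defines which identifiers are
#'   metabolic).
#' @param contig_lengths Named numeric vector: contig id -> length in
#'   bases.
#' @param config An [amg_call_config()].
#' @return `contexts` with a `flags` list-column of character vectors.
#' @export
assign_flags <- function(contexts, raw_table, form, contig_lengths,
                         config = amg_call_config()) {
  ids_of <- identifiers_by_gene(raw_table)
  gene_ids <- lapply(contexts$gene_id, function(g) ids_of[[g]] %||%
                       character())
  vog_desc <- setNames(
    if ("vogdb_description" %in% names(raw_table)) {
      raw_table$vogdb_description
    } else {
      rep(NA_character_, nrow(raw_table))
    },
    raw_table$gene_id
  )
  merops <- setNames(
    if ("merops_id" %in% names(raw_table)) {
      sub("\\.\\d+$", "", raw_table$merops_id)
    } else {
      rep(NA_character_, nrow(raw_table))
    },
    raw_table$gene_id
  )
  form_ids <- unique(form$identifier)

  has_any <- function(ids, set) length(intersect(ids, set)) > 0
  v_flag <- vapply(contexts$gene_id, function(g) {
    d <- vog_desc[g]
    !is.na(d) && grepl("\\[X[rs]\\]|replication|structure", d,
                       ignore.case = TRUE)
  }, logical(1), USE.NAMES = FALSE)
  m_flag <- vapply(gene_ids, has_any, logical(1), set = form_ids)
  k_flag <- vapply(gene_ids, has_any, logical(1),
                   set = config$known_amg_ids)
  e_flag <- vapply(gene_ids, has_any, logical(1),
                   set = config$verified_amg_ids)
  a_flag <- vapply(gene_ids, has_any, logical(1),
                   set = config$attachment_ids)
  p_flag <- vapply(contexts$gene_id, function(g) {
    fam <- merops[g]
    # family = id up to the first dot already stripped; match on prefix too
    !is.na(fam) && (fam %in% config$viral_peptidase_families ||
      sub("[0-9.]+$", "", fam) %in% config$viral_peptidase_families)
  }, logical(1), USE.NAMES = FALSE)

  clen <- contig_lengths[contexts$contig_id]
  if (anyNA(clen)) {
    md_abort("Missing contig length for a viral gene", "contract_error")
  }
  dist_end <- pmin(contexts$start - 1, clen - contexts$end)
  f_flag <- dist_end < config$end_window

  transposon_gene <- vapply(gene_ids, has_any, logical(1),
                            set = config$transposon_ids)
  t_contigs <- unique(contexts$contig_id[transposon_gene])
  t_flag <- contexts$contig_id %in% t_contigs

  ctx <- contexts %>% mutate(
    .v = v_flag, .m = m_flag, .k = k_flag, .e = e_flag, .a = a_flag,
    .p = p_flag, .f = f_flag, .t = t_flag,
    distance_to_contig_end = dist_end
  ) %>%
    group_by(.data$contig_id) %>%
    arrange(.data$ordinal, .by_group = TRUE) %>%
    mutate(.b = in_run_of(.data$.m, 3L)) %>%
    ungroup()

  ctx$flags <- purrr::pmap(
    list(ctx$.v, ctx$.m, ctx$.k, ctx$.e, ctx$.a, ctx$.p, ctx$.f, ctx$.t,
         ctx$.b),
    function(v, m, k, e, a, p, f, t, b) {
      VALID_FLAGS[c(v, m, k, e, a, p, f, t, b)]
    }
  )
  ctx %>% select(-dplyr::starts_with("."))
}

#' Call potential auxiliary metabolic genes
#'
#' Default rule: a gene is a potential AMG when its auxiliary score is
#' strictly below `max_aux_score_exclusive` (default 4), it carries every
#' required flag (default `M`), and none of the forbidden flags (default
#' `V`, `A`, `P`, `B`). Thresholds and flag sets are user-overridable
#' through the config.
#'
#' @param contexts Tibble with `aux_score` and `flags` columns
#'   ([assign_auxiliary_score()], [assign_flags()]).
#' @param config An [amg_call_config()].
#' @return The rows of `contexts` called as potential AMGs.
#' @export
call_potential_amgs <- function(contexts, config = amg_call_config()) {
  keep <- purrr::map2_lgl(
    contexts$aux_score, contexts$flags,
    function(score, flags) {
      score < config$max_aux_score_exclusive &&
        all(config$required_flags %in% flags) &&
        length(intersect(config$forbidden_flags, flags)) == 0
    }
  )
  contexts[keep, ]
}

#' Summarize viral contigs (vMAG summary)
#'
#' One row per viral contig: upstream category, circularity and prophage
#' status passed through from the detector's metadata, gene count, number
#' of strand switches (adjacent gene pairs on opposite strands), presence
#' of a transposase, and the number of potential AMGs called.
#'
#' @param contexts Flagged, scored gene contexts (must carry `strand`,
#'   `flags`, `aux_score`).
#' @param virsorter_metadata Optional tibble `contig_id`,
#'   `virsorter_category`, `is_circular`, `is_prophage`.
#' @param config An [amg_call_config()].
#' @return Tibble with one row per contig.
#' @export
summarize_vmag <- function(contexts, virsorter_metadata = NULL,
                           config = amg_call_config()) {
  amgs <- call_potential_amgs(contexts, config)
  out <- contexts %>%
    group_by(contig_id = .data$contig_id) %>%
    arrange(.data$ordinal, .by_group = TRUE) %>%
    summarise(
      gene_count = dplyr::n(),
      strand_switches = sum(
        .data$strand != lag(.data$strand), na.rm = TRUE
      ),
      has_transposase = any(purrr::map_lgl(.data$flags, ~ "T" %in% .x)),
      .groups = "drop"
    ) %>%
    left_join(
      amgs %>% dplyr::count(.data$contig_id, name = "amg_count"),
      by = "contig_id"
    ) %>%
    mutate(amg_count = dplyr::coalesce(.data$amg_count, 0L))
  if (!is.null(virsorter_metadata)) {
    out <- left_join(out, virsorter_metadata, by = "contig_id")
  }
  out
}

#' Build the AMG product
#'
#' Rows are viral contigs (contigs without AMGs keep an all-zero row),
#' columns are distillate categories, and each cell counts the contig's
#' called AMGs mapping to that category. An AMG whose identifier maps to
#' several categories is counted in each.
#'
#' @param contexts Scored, flagged viral gene contexts.
#' @param raw_table Raw annotation tibble for the viral genes.
#' @param form Distillate form tibble.
#' @param config An [amg_call_config()].
#' @return An object of class `mag_amg_product`: list with `table` (tibble,
#'   one row per contig) and `calls` (the called AMGs joined with their
#'   categories).
#' @export
build_amg_product <- function(contexts, raw_table, form,
                              config = amg_call_config()) {
  amgs <- call_potential_amgs(contexts, config)
  ids <- gene_identifiers(raw_table) %>%
    dplyr::inner_join(
      form %>% select("identifier", "category") %>% distinct(),
      by = "identifier"
    )
  calls <- amgs %>%
    select("contig_id", "gene_id", "aux_score") %>%
    left_join(
      ids %>% distinct(.data$gene_id, .data$category),
      by = "gene_id"
    )
  categories <- sort(unique(form$category))
  tab <- tibble::tibble(contig_id = unique(contexts$contig_id))
  for (cat in categories) {
    counts <- calls %>%
      filter(.data$category == cat) %>%
      dplyr::count(.data$contig_id)
    tab[[cat]] <- dplyr::coalesce(
      counts$n[match(tab$contig_id, counts$contig_id)], 0L
    )
  }
  structure(list(table = tab, calls = calls), class = "mag_amg_product")
}

#' Render the AMG product heatmap as HTML
#'
#' @param amg_product A `mag_amg_product`.
#' @param path Destination HTML file.
#' @return `path`, invisibly.
#' @export
render_amg_product_html <- function(amg_product, path) {
  tab <- amg_product$table
  cats <- setdiff(names(tab), "contig_id")
  if (nrow(tab) == 0) {
    writeLines(c(
      "<!DOCTYPE html><html><head><meta charset='utf-8'/></head>",
      "<body><p>No viral contigs.</p></body></html>"
    ), path)
    return(invisible(path))
  }
  maxn <- max(1, max(as.matrix(tab[cats])))
  fake_product <- list(
    table = tab %>%
      rename(genome_id = "contig_id") %>%
      mutate(across(all_of(cats), ~ .x / maxn)),
    columns = tibble::tibble(
      column = cats, block = "pathway_coverage", category = cats,
      name = cats
    )
  )
  svg <- render_heatmap_svg(fake_product$table, fake_product$columns)
  writeLines(c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'/>",
    "<title>Potential AMGs</title></head><body>",
    "<h2>Potential AMGs per viral contig by metabolic category</h2>",
    svg, "</body></html>"
  ), path)
  invisible(path)
}

#' Run the full viral annotation and AMG-calling stage
#'
#' Chains evidence classification, flag assignment, auxiliary scoring (the
#' metabolic-stretch rule uses the `M`/`V` flags, so flags are assigned
#' first), AMG calling and vMAG summarization.
#'
#' @param affi Tibble from [read_virsorter_affi()].
#' @param raw_table Raw annotation tibble for the viral genes.
#' @param form Distillate form tibble.
#' @param contig_lengths Named numeric vector of contig lengths.
#' @param virsorter_metadata Optional per-contig metadata.
#' @param config An [amg_call_config()].
#' @return An object of class `viral_annotation`: list with `contexts` (scored,
#'   flagged genes), `amgs` (called potential AMGs), `vmag_summary` and
#'   `amg_product`.
#' @export
annotate_viral_contigs <- function(affi, raw_table, form, contig_lengths,
                           virsorter_metadata = NULL,
                           config = amg_call_config()) {
  ev <- classify_viral_evidence(affi, config$evidence_map)
  ev <- ev %>% arrange(.data$contig_id, .data$ordinal)
  ctx <- assign_flags(ev, raw_table, form, contig_lengths, config)
  metabolic <- purrr::map_lgl(
    ctx$flags, ~ "M" %in% .x && !"V" %in% .x
  )
  ctx <- assign_auxiliary_score(ctx, metabolic, config)
  structure(
    list(
      contexts = ctx,
      amgs = call_potential_amgs(ctx, config),
      vmag_summary = summarize_vmag(ctx, virsorter_metadata, config),
      amg_product = build_amg_product(ctx, raw_table, form, config),
      config = config
    ),
    class = "viral_annotation"
  )
}

#' @export
print.viral_annotation <- function(x, ...) {
  cat("<viral_annotation> ", nrow(x$contexts), " gene(s) on ",
      length(unique(x$contexts$contig_id)), " viral contig(s); ",
      nrow(x$amgs), " potential AMG(s)\n", sep = "")
  invisible(x)
}
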