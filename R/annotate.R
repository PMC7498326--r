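# Annotation engine: merge per-database hits into one annotation per gene
# with a confidence rank (A-E) and an annotated/hypothetical/unannotated
# status.

# Databases searched with profile HMMs (carry model coverage).
HMM_DATABASES <- c("pfam", "dbcan", "vogdb", "kofam")
# Databases whose presence alone yields rank D.
D_RANK_DATABASES <- c("pfam", "dbcan", "merops")
# Databases consulted for annotated/hypothetical/unannotated status. VOGDB is
# deliberately excluded: a VOGDB-only gene is unannotated.
STATUS_DATABASES <- c("kegg", "kofam", "uniref", "merops", "pfam", "dbcan")

#' Drop contigs shorter than the configured minimum
#'
#' @param contigs Tibble from [read_fasta()].
#' @param config An [annotation_config()]; contigs shorter than
#'   `min_contig_length` (default 2500 bp) are removed, so a 2500 bp contig
#'   is retained.
#' @return The retained rows, input order preserved.
#' @export
filter_contigs <- function(contigs, config = annotation_config()) {
  contigs[nchar(contigs$sequence) >= config$min_contig_length, ]
}

hit_sort_order <- function(hits) {
  order(-hits$bit_score, hits$e_value, hits$target_id)
}

#' Select the best hit for one gene in one database
#'
#' The best hit is the maximum-bit-score hit, provided its score strictly
#' exceeds `min_bit_score`; otherwise the gene is unannotated in that
#' database. Ties on bit score break by lower e-value, then lexicographically
#' smallest target id, so the result is invariant to input order.
#'
#' @param hits Hit tibble in which all rows share one `query_id` and one
#'   `database`.
#' @param config An [annotation_config()].
#' @return A one-row tibble, or a zero-row tibble when no hit qualifies.
#' @export
select_best_hit <- function(hits, config = annotation_config()) {
  if (nrow(hits) == 0) {
    return(hits)
  }
  if (length(unique(hits$database)) > 1) {
    md_abort("select_best_hit requires a single database", "contract_error")
  }
  if (length(unique(hits$query_id)) > 1) {
    md_abort("select_best_hit requires a single query gene", "contract_error")
  }
  best <- hits[hit_sort_order(hits)[1], ]
  if (best$bit_score > config$min_bit_score) best else hits[0, ]
}

#' Confirm a reciprocal best hit
#'
#' A forward best hit is reciprocal when the reverse search of its database
#' target against all input genes ranks the original query gene first with a
#' bit score strictly above `rbh_reverse_bit_score` (default 350).
#'
#' @param forward One-row tibble: the forward best hit.
#' @param reverse_hits Hits of `forward$target_id` against the input genes
#'   (`query_id` = database entry, `target_id` = gene).
#' @param config An [annotation_config()].
#' @return `TRUE` or `FALSE`.
#' @export
confirm_rbh <- function(forward, reverse_hits,
                        config = annotation_config()) {
  rev <- reverse_hits[reverse_hits$query_id == forward$target_id, ]
  if (nrow(rev) == 0) {
    return(FALSE)
  }
  top <- rev[hit_sort_order(rev)[1], ]
  top$target_id == forward$query_id &&
    top$bit_score > config$rbh_reverse_bit_score
}

#' Filter profile-HMM hits
#'
#' For Pfam/dbCAN/VOGDB-style searches a hit is kept when it covers strictly
#' more than `hmm_min_model_coverage` of the model (default 35%) at an
#' e-value strictly below `hmm_max_evalue` (default 1e-15). For KOfam models
#' with a per-model score threshold the hit is kept when its bit score meets
#' (>=) that threshold; KOfam models with no threshold fall back to the
#' generic coverage/e-value rule.
#'
#' @param hits Hit tibble with `model_coverage` populated.
#' @param thresholds Optional tibble from [read_kofam_thresholds()].
#' @param config An [annotation_config()].
#' @return Logical vector, one element per row of `hits`.
#' @export
filter_profile_hit <- function(hits, thresholds = NULL,
                               config = annotation_config()) {
  if (nrow(hits) == 0) {
    return(logical())
  }
  if (!"model_coverage" %in% names(hits) || anyNA(hits$model_coverage)) {
    md_abort("model_coverage missing from profile hits", "contract_error")
  }
  generic <- hits$model_coverage > config$hmm_min_model_coverage &
    hits$e_value < config$hmm_max_evalue
  if (is.null(thresholds)) {
    return(generic)
  }
  thr <- thresholds$score_threshold[match(hits$target_id,
                                          thresholds$model_id)]
  use_thr <- hits$database == "kofam" & !is.na(thr)
  if_else(use_thr, hits$bit_score >= thr, generic)
}

#' Rank annotation confidence from evidence booleans
#'
#' Vectorized core of the A-E rank system: A for a KEGG reciprocal best hit,
#' B for a UniRef reciprocal best hit, C for a plain KEGG or UniRef hit, D
#' for genes with only Pfam/dbCAN/MEROPS evidence, E for genes with no
#' significant hits (a VOGDB-only gene is rank E).
#'
#' @param kegg_rbh,uniref_rbh,kegg_hit,uniref_hit,d_hit Logical vectors of
#'   equal length.
#' @return Character vector of ranks.
#' @export
rank_from_evidence <- function(kegg_rbh, uniref_rbh, kegg_hit, uniref_hit,
                               d_hit) {
  dplyr::case_when(
    kegg_rbh ~ "A",
    uniref_rbh ~ "B",
    kegg_hit | uniref_hit ~ "C",
    d_hit ~ "D",
    TRUE ~ "E"
  )
}

#' Assign the A-E confidence rank per gene
#'
#' Databases absent from `config$databases_in_use` are treated as having no
#' hits, so dropping a database can only keep a rank equal or make it worse.
#' KOfam KO assignments stand in for KEGG gene hits at the C level (a profile
#' search cannot be reciprocal, so it never yields rank A).
#'
#' @param best_hits Long tibble of per-gene best hits with columns
#'   `query_id`, `database`, `bit_score`, `is_rbh`.
#' @param gene_ids Character vector of all gene ids (genes with no hits rank
#'   E).
#' @param config An [annotation_config()].
#' @return Tibble with `gene_id`, `rank`.
#' @export
assign_rank <- function(best_hits, gene_ids,
                        config = annotation_config()) {
  bh <- best_hits[best_hits$database %in% config$databases_in_use, ]
  ev <- tibble::tibble(gene_id = gene_ids)
  has <- function(dbs, rbh_only = FALSE) {
    sub <- bh[bh$database %in% dbs, ]
    if (rbh_only) sub <- sub[sub$is_rbh, ]
    ev$gene_id %in% sub$query_id
  }
  ev %>% mutate(
    rank = rank_from_evidence(
      kegg_rbh = has("kegg", rbh_only = TRUE),
      uniref_rbh = has("uniref", rbh_only = TRUE),
      kegg_hit = has(c("kegg", "kofam")),
      uniref_hit = has("uniref"),
      d_hit = has(D_RANK_DATABASES)
    )
  )
}

#' Classify genes as annotated, hypothetical or unannotated
#'
#' A gene is annotated when at least one best hit among
#' KEGG/KOfam/UniRef/MEROPS/Pfam/dbCAN has a description free of the
#' hypothetical keywords (case-insensitive substring match on
#' "hypothetical", "uncharacterized", "domain of unknown function");
#' hypothetical when such hits exist but every description matches a keyword
#' (or is blank); unannotated when none of those databases hit at all.
#'
#' @param best_hits Long per-gene best-hit tibble with `query_id`,
#'   `database`, `description`.
#' @param gene_ids All gene ids.
#' @param config An [annotation_config()].
#' @return Tibble with `gene_id`, `status`.
#' @export
classify_status <- function(best_hits, gene_ids,
                            config = annotation_config()) {
  bh <- best_hits[
    best_hits$database %in%
      intersect(STATUS_DATABASES, config$databases_in_use),
  ]
  is_hypo <- function(desc) {
    if (is.na(desc) || !nzchar(desc)) {
      return(TRUE)
    }
    any(stringr::str_detect(
      tolower(desc), stringr::fixed(config$hypothetical_keywords)
    ))
  }
  hypo <- vapply(bh$description, is_hypo, logical(1), USE.NAMES = FALSE)
  informative <- unique(bh$query_id[!hypo])
  any_hit <- unique(bh$query_id)
  tibble::tibble(
    gene_id = gene_ids,
    status = dplyr::case_when(
      gene_ids %in% informative ~ "annotated",
      gene_ids %in% any_hit ~ "hypothetical",
      TRUE ~ "unannotated"
    )
  )
}

#' Merge per-gene best hits into the raw annotation table
#'
#' One row per gene with coordinates, rank, status and per-database
#' id/description/bit-score/e-value columns (plus an `_rbh` column for KEGG
#' and UniRef). Columns follow a fixed database order and rows sort by
#' genome, contig, start, so output is deterministic.
#'
#' @param genes Gene tibble.
#' @param best_hits Long per-gene best-hit tibble.
#' @param config An [annotation_config()].
#' @return The raw annotation tibble.
#' @export
merge_raw_table <- function(genes, best_hits,
                            config = annotation_config()) {
  if (anyDuplicated(genes$gene_id)) {
    md_abort(
      paste0(
        "Duplicate gene id: ",
        genes$gene_id[duplicated(genes$gene_id)][1]
      ),
      "contract_error"
    )
  }
  ranks <- assign_rank(best_hits, genes$gene_id, config)
  statuses <- classify_status(best_hits, genes$gene_id, config)
  out <- genes %>%
    select("gene_id", "genome_id", "contig_id", "start", "end", "strand") %>%
    left_join(ranks, by = "gene_id") %>%
    left_join(statuses, by = "gene_id")
  db_order <- intersect(
    c("kegg", "kofam", "uniref", "merops", "pfam", "dbcan", "vogdb",
      "refseq_viral"),
    unique(c(config$databases_in_use, best_hits$database))
  )
  for (db in db_order) {
    sub <- best_hits[best_hits$database == db, ]
    idx <- match(out$gene_id, sub$query_id)
    out[[paste0(db, "_id")]] <- sub$target_id[idx]
    out[[paste0(db, "_description")]] <-
      if ("description" %in% names(sub)) sub$description[idx] else
        NA_character_
    out[[paste0(db, "_bit_score")]] <- sub$bit_score[idx]
    out[[paste0(db, "_e_value")]] <- sub$e_value[idx]
    if (db %in% c("kegg", "uniref")) {
      out[[paste0(db, "_rbh")]] <- if_else(
        is.na(idx), NA, sub$is_rbh[idx]
      )
    }
  }
  out %>% arrange(.data$genome_id, .data$contig_id, .data$start)
}

#' Annotate genes from per-database search hits
#'
#' The full annotation stage: profile hits are filtered by model coverage,
#' e-value and per-model KOfam thresholds; sequence-search hits are reduced
#' to best hits above the bit-score floor; reciprocal best hits are
#' confirmed against the reverse search; and every gene receives a rank
#' (A-E) and a status.
#'
#' @param genes Gene tibble (`gene_id`, `genome_id`, `contig_id`, `start`,
#'   `end`, `strand`, `protein`).
#' @param hits Combined forward-hit tibble across databases; profile
#'   databases (`r paste(HMM_DATABASES, collapse = ", ")`) must carry
#'   `model_coverage`.
#' @param reverse_hits Optional reverse-search hits (database entries
#'   searched against the input genes) used to confirm KEGG/UniRef
#'   reciprocal best hits.
#' @param kofam_thresholds Optional per-model threshold tibble.
#' @param config An [annotation_config()].
#' @return An object of class `mag_annotation`: list with `raw` (the merged
#'   raw table), `best_hits`, `genes` and `config`. Use [tidy()] /
#'   [glance()] / [ggplot2::autoplot()] on it.
#' @export
annotate_genes <- function(genes, hits, reverse_hits = NULL,
                           kofam_thresholds = NULL,
                           config = annotation_config()) {
  hits <- hits[hits$database %in% config$databases_in_use, ]
  if (!"description" %in% names(hits)) {
    hits$description <- NA_character_
  }
  profile <- hits[hits$database %in% HMM_DATABASES, ]
  if (nrow(profile) > 0) {
    profile <- profile[
      filter_profile_hit(profile, kofam_thresholds, config),
    ]
  }
  sequence <- hits[!hits$database %in% HMM_DATABASES, ]
  pick_best <- function(h, apply_min) {
    if (nrow(h) == 0) {
      return(h)
    }
    h %>%
      group_by(.data$query_id, .data$database) %>%
      dplyr::group_modify(function(g, key) {
        g$database <- key$database
        g$query_id <- key$query_id
        best <- if (apply_min) {
          select_best_hit(g, config)
        } else {
          g[hit_sort_order(g)[1], ]
        }
        best %>% select(-"query_id", -"database")
      }) %>%
      ungroup()
  }
  best <- dplyr::bind_rows(
    pick_best(sequence, apply_min = TRUE),
    pick_best(profile, apply_min = FALSE)
  )
  best$is_rbh <- FALSE
  if (!is.null(reverse_hits) && nrow(best) > 0) {
    rbh_rows <- which(best$database %in% c("kegg", "uniref"))
    for (i in rbh_rows) {
      rev <- reverse_hits[
        reverse_hits$database == best$database[i],
      ]
      best$is_rbh[i] <- confirm_rbh(best[i, ], rev, config)
    }
  }
  structure(
    list(
      raw = merge_raw_table(genes, best, config),
      best_hits = best,
      genes = genes,
      config = config
    ),
    class = "mag_annotation"
  )
}

#' @export
print.mag_annotation <- function(x, ...) {
  cat("<mag_annotation> ", nrow(x$genes), " genes, ",
      length(unique(x$genes$genome_id)), " genome(s)\n", sep = "")
  print(table(rank = x$raw$rank))
  invisible(x)
}
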