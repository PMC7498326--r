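#' Annotation thresholds and database configuration
#'
#' Bundles every tunable threshold used while merging per-database search hits
#' into gene annotations. Defaults follow the conventional desk values for
#' metagenome annotation: short contigs below 2500 bp are discarded before
#' gene calling, sequence-search hits must exceed bit score 60, a reciprocal
#' best hit additionally needs a reverse bit score above 350, and profile-HMM
#' hits must cover more than 35% of the model at an e-value below 1e-15.
#'
#' @param min_contig_length Minimum contig length in bases retained by
#'   [filter_contigs()]. Contigs shorter than this are dropped.
#' @param min_bit_score Forward-search bit score that a best hit must exceed
#'   (strictly) to be reported.
#' @param rbh_reverse_bit_score Bit score the reverse-search top hit must
#'   exceed (strictly) for a reciprocal best hit.
#' @param hmm_min_model_coverage Fraction of the profile model that an HMM
#'   alignment must exceed (strictly).
#' @param hmm_max_evalue E-value an HMM hit must fall below (strictly).
#' @param hypothetical_keywords Lower-case substrings whose presence in every
#'   hit description marks a gene as hypothetical rather than annotated.
#' @param databases_in_use Character vector of database tags consulted when
#'   ranking. Databases not listed are treated as having no hits, so removing
#'   one can only lower (worsen) ranks.
#'
#' @return A list of class `annotation_config`.
#' @export
#' @examples
#' cfg <- annotation_config(min_bit_score = 50)
#' cfg$min_bit_score
annotation_config <- function(min_contig_length = 2500,
                              min_bit_score = 60,
                              rbh_reverse_bit_score = 350,
                              hmm_min_model_coverage = 0.35,
                              hmm_max_evalue = 1e-15,
                              hypothetical_keywords = c(
                                "hypothetical", "uncharacterized",
                                "domain of unknown function"
                              ),
                              databases_in_use = c(
                                "kegg", "kofam", "uniref", "merops",
                                "pfam", "dbcan", "vogdb"
                              )) {
  stopifnot(
    min_contig_length > 0, min_bit_score > 0, rbh_reverse_bit_score > 0,
    hmm_min_model_coverage > 0, hmm_max_evalue > 0
  )
  structure(
    list(
      min_contig_length = min_contig_length,
      min_bit_score = min_bit_score,
      rbh_reverse_bit_score = rbh_reverse_bit_score,
      hmm_min_model_coverage = hmm_min_model_coverage,
      hmm_max_evalue = hmm_max_evalue,
      hypothetical_keywords = tolower(hypothetical_keywords),
      databases_in_use = databases_in_use
    ),
    class = "annotation_config"
  )
}

#' AMG-calling thresholds and curated identifier lists
#'
#' Configuration for the viral auxiliary-metabolic-gene caller. Under the
#' default rule a gene is a potential AMG when its auxiliary score is below 4,
#' it carries the metabolism flag `M`, and it carries none of the
#' disqualifying flags `V` (viral replication/structure), `A` (host
#' attachment/entry), `P` (viral-associated peptidase) or `B` (inside a run of
#' three or more metabolic genes).
#'
#' @param max_aux_score_exclusive Genes with auxiliary score strictly below
#'   this value are eligible; the default 4 admits scores 1-3.
#' @param required_flags Flags every call must carry (default `"M"`).
#' @param forbidden_flags Flags that disqualify a gene (default
#'   `c("V","A","P","B")`).
#' @param end_window Distance in bases from a contig end inside which a gene
#'   receives the `F` (near contig end) flag.
#' @param metabolic_stretch_min Minimum length of a run of adjacent metabolic
#'   genes that triggers the stretch rules (`B` flag; auxiliary score raised
#'   to 4).
#' @param known_amg_ids,verified_amg_ids Identifier sets for the `K`
#'   (literature-reported AMG) and `E` (experimentally verified AMG) flags;
#'   `verified_amg_ids` must be a subset of `known_amg_ids`.
#' @param attachment_ids Identifiers associated with viral host attachment and
#'   entry (`A` flag).
#' @param viral_peptidase_families Peptidase families regarded as viral
#'   (`P` flag).
#' @param transposon_ids Identifiers marking transposons; any hit on a contig
#'   gives every gene on that contig the `T` flag.
#' @param evidence_map Named character vector mapping raw evidence-code tokens
#'   from the viral-affiliation table to `"hallmark"`, `"viral_like"` or
#'   `"none"`. Unmapped codes classify as `"none"` with a warning.
#'
#' @return A list of class `amg_call_config`.
#' @export
amg_call_config <- function(max_aux_score_exclusive = 4,
                            required_flags = "M",
                            forbidden_flags = c("V", "A", "P", "B"),
                            end_window = 5000,
                            metabolic_stretch_min = 3,
                            known_amg_ids = character(),
                            verified_amg_ids = character(),
                            attachment_ids = character(),
                            viral_peptidase_families = character(),
                            transposon_ids = character(),
                            evidence_map = default_evidence_map()) {
  stopifnot(
    max_aux_score_exclusive > 0, end_window > 0, metabolic_stretch_min > 0
  )
  if (!all(verified_amg_ids %in% known_amg_ids)) {
    md_abort(
      "verified_amg_ids must be a subset of known_amg_ids",
      "config_error"
    )
  }
  structure(
    list(
      max_aux_score_exclusive = max_aux_score_exclusive,
      required_flags = required_flags,
      forbidden_flags = forbidden_flags,
      end_window = end_window,
      metabolic_stretch_min = metabolic_stretch_min,
      known_amg_ids = known_amg_ids,
      verified_amg_ids = verified_amg_ids,
      attachment_ids = attachment_ids,
      viral_peptidase_families = viral_peptidase_families,
      transposon_ids = transposon_ids,
      evidence_map = evidence_map
    ),
    class = "amg_call_config"
  )
}

#' Default mapping from affiliation-table evidence codes to viral evidence
#'
#' The upstream viral-detection tool writes one category token per gene; the
#' tokens themselves are tool-version dependent, so the mapping is a plain
#' named vector the user can replace or extend. Category 0 and 3 tokens are
#' treated as hallmark, 1 and 4 as viral-like, and the dash as no evidence.
#'
#' @return Named character vector; names are raw tokens, values are one of
#'   `"hallmark"`, `"viral_like"`, `"none"`.
#' @export
default_evidence_map <- function() {
  c(
    "0" = "hallmark", "3" = "hallmark", "hallmark" = "hallmark",
    "1" = "viral_like", "4" = "viral_like", "viral" = "viral_like",
    "-" = "none", "none" = "none"
  )
}

#' MIMAG-style genome quality thresholds
#'
#' Numeric thresholds behind the high/medium/low genome quality rank.
#' High-quality draft: completeness above 90%, contamination below 5%, all
#' three rRNAs (5S, 16S, 23S) detected, and at least 18 distinct tRNAs.
#' Medium-quality draft: completeness at least 50% and contamination below
#' 10%. Anything else is low quality.
#'
#' @param high_completeness,high_contamination,high_min_trna Thresholds for
#'   the high tier.
#' @param medium_completeness,medium_contamination Thresholds for the medium
#'   tier.
#' @return A named list of thresholds.
#' @export
mimag_thresholds <- function(high_completeness = 90,
                             high_contamination = 5,
                             high_min_trna = 18,
                             medium_completeness = 50,
                             medium_contamination = 10) {
  list(
    high_completeness = high_completeness,
    high_contamination = high_contamination,
    high_min_trna = high_min_trna,
    medium_completeness = medium_completeness,
    medium_contamination = medium_contamination
  )
}
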