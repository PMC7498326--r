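# Shared builders for miniature in-memory fixtures.

make_hits <- function(query = "g1", db = "kegg", scores = 100,
                      evalues = NULL, targets = NULL, descriptions = NULL) {
  n <- length(scores)
  tibble::tibble(
    query_id = rep_len(query, n),
    target_id = targets %||% sprintf("t%d", seq_len(n)),
    database = rep_len(db, n),
    bit_score = scores,
    e_value = evalues %||% rep(1e-30, n),
    description = descriptions %||% rep(NA_character_, n)
  )
}

make_genes <- function(n = 3, genome = "gA", contig = "gA_c1") {
  tibble::tibble(
    gene_id = sprintf("%s_g%d", genome, seq_len(n)),
    genome_id = genome,
    contig_id = contig,
    start = (seq_len(n) - 1) * 400 + 1,
    end = (seq_len(n) - 1) * 400 + 300,
    strand = rep(c("+", "-"), length.out = n),
    protein = strrep("M", 10)
  )
}

# Long best-hit row used to drive rank/status rules directly.
best_hit_row <- function(gene, db, score = 100, rbh = FALSE,
                         desc = "some enzyme", target = "t1") {
  tibble::tibble(
    query_id = gene, target_id = target, database = db,
    bit_score = score, e_value = 1e-30, description = desc, is_rbh = rbh
  )
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Straight-line transcription of the five auxiliary-score rules, written
# independently of the engine: explicit flank scans and an explicit run
# scan for the metabolic-stretch rule.
oracle_aux_score <- function(evidence, metabolic) {
  n <- length(evidence)
  out <- integer(n)
  contig_has_viral <- any(evidence != "none")
  for (i in seq_len(n)) {
    left <- if (i > 1) evidence[1:(i - 1)] else character()
    right <- if (i < n) evidence[(i + 1):n] else character()
    hall_l <- any(left == "hallmark")
    hall_r <- any(right == "hallmark")
    viral_l <- any(left != "none")
    viral_r <- any(right != "none")
    score <- if (!contig_has_viral) {
      5L
    } else if (i == 1 || i == n) {
      5L
    } else if (hall_l && hall_r) {
      1L
    } else if ((hall_l && viral_r) || (hall_r && viral_l)) {
      2L
    } else if (viral_l && viral_r) {
      3L
    } else if (viral_l || viral_r) {
      4L
    } else {
      5L
    }
    # stretch rule: three or more adjacent non-viral metabolic genes
    if (metabolic[i]) {
      run <- 1L
      j <- i - 1L
      while (j >= 1 && metabolic[j]) {
        run <- run + 1L
        j <- j - 1L
      }
      j <- i + 1L
      while (j <= n && metabolic[j]) {
        run <- run + 1L
        j <- j + 1L
      }
      if (run >= 3 && score < 4L) score <- 4L
    }
    out[i] <- score
  }
  out
}

# Engine-facing wrapper: score a bare evidence/metabolic layout.
engine_aux_score <- function(evidence, metabolic = NULL) {
  n <- length(evidence)
  ev <- tibble::tibble(
    contig_id = "c1", gene_id = sprintf("g%d", seq_len(n)),
    ordinal = seq_len(n) - 1L, evidence = evidence
  )
  assign_auxiliary_score(ev, metabolic %||% rep(FALSE, n))$aux_score
}
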