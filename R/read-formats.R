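# Readers for the external formats the pipeline consumes. Downstream modules
# only ever see the tibbles produced here.

#' Read a FASTA file into a tibble of sequence records
#'
#' @param path Path to a FASTA file (nucleotide or amino acid).
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header), `description` (remainder of the header, `""` if none) and
#'   `sequence`, in file order. An empty file yields a zero-row tibble.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fna")
#' writeLines(c(">c1 a contig", "ACGT", ">c2", "GGCC"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    md_abort(paste0("No such file: ", path), "io_error")
  }
  lines <- readLines(path, warn = FALSE)
  first_content <- which(nzchar(trimws(lines)))[1]
  if (is.na(first_content)) {
    return(tibble::tibble(
      id = character(), description = character(), sequence = character()
    ))
  }
  if (!startsWith(lines[first_content], ">")) {
    md_abort(
      sprintf("Not FASTA: line %d does not start a record", first_content),
      "format_error"
    )
  }
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    md_abort(paste0("Duplicate FASTA id: ", dup), "format_error")
  }
  if (any(!nzchar(ids))) {
    md_abort("Empty FASTA id", "format_error")
  }
  desc <- ifelse(
    grepl("\\s", headers),
    sub("^\\S+\\s+", "", headers),
    ""
  )
  tibble::tibble(
    id = ids,
    description = desc,
    sequence = unname(as.character(seqs))
  )
}

#' Default column map for the 12-column tabular alignment dialect
#'
#' Column positions of query, target, e-value and bit score in the common
#' 12-column search export (query, target, identity, length, mismatches,
#' gaps, qstart, qend, tstart, tend, e-value, bit score). Extend with a
#' `description` index for exports carrying a 13th free-text column.
#'
#' @return Named list of 1-based column indices.
#' @export
default_hit_col_map <- function() {
  list(query_id = 1L, target_id = 2L, e_value = 11L, bit_score = 12L,
       description = NA_integer_)
}

#' Read a tab-delimited best-hit table
#'
#' Parses sequence-search results in the conventional 12-column tabular
#' layout (query, target, identity, alignment length, mismatches, gap opens,
#' query/target coordinates, e-value, bit score); a custom `col_map` supports
#' other layouts, including ones carrying a free-text description column.
#'
#' @param path Path to the tab-delimited table.
#' @param database_name Tag attached to every record (e.g. `"kegg"`).
#' @param col_map Named list of 1-based column indices for `query_id`,
#'   `target_id`, `e_value`, `bit_score` and optionally `description`.
#' @param header `"auto"` (default) drops a leading row whose bit-score and
#'   e-value fields are both non-numeric; `TRUE`/`FALSE` force the choice.
#' @return Tibble with columns `query_id`, `target_id`, `database`,
#'   `bit_score`, `e_value`, `description`.
#' @export
read_hit_table <- function(path, database_name,
                           col_map = default_hit_col_map(),
                           header = "auto") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  offset <- 0L
  if (length(lines) > 0 && !identical(header, FALSE)) {
    f <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    bits <- suppressWarnings(as.numeric(f[col_map$bit_score]))
    ev <- suppressWarnings(as.numeric(f[col_map$e_value]))
    drop <- if (identical(header, TRUE)) TRUE else is.na(bits) && is.na(ev)
    if (drop) {
      lines <- lines[-1]
      offset <- 1L
    }
  }
  if (length(lines) == 0) {
    return(tibble::tibble(
      query_id = character(), target_id = character(),
      database = character(), bit_score = double(), e_value = double(),
      description = character()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  pick <- function(i) vapply(fields, function(f) {
    if (is.na(i) || i > length(f)) NA_character_ else f[[i]]
  }, character(1))
  tibble::tibble(
    query_id = pick(col_map$query_id),
    target_id = pick(col_map$target_id),
    database = database_name,
    bit_score = parse_numeric_field(
      pick(col_map$bit_score), "bit score", line_offset = offset
    ),
    e_value = parse_numeric_field(
      pick(col_map$e_value), "e-value", line_offset = offset
    ),
    description = pick(col_map$description %||% NA_integer_)
  )
}

#' Read profile-HMM hits with model coverage
#'
#' Expects tab-delimited domain-table-style rows with columns `query_id`,
#' `model_id`, `model_length`, `model_from`, `model_to`, `e_value`,
#' `bit_score` and optionally `description` (a header row naming them is
#' allowed). Model coverage is computed model-side as
#' `(model_to - model_from + 1) / model_length`.
#'
#' @param path Path to the hit table.
#' @param database_name Tag attached to every record (e.g. `"pfam"`).
#' @return Tibble with `query_id`, `target_id`, `database`, `bit_score`,
#'   `e_value`, `model_coverage`, `description`.
#' @export
read_hmm_hits <- function(path, database_name = "pfam") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  offset <- 0L
  if (length(lines) > 0) {
    f1 <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(f1) >= 3 && is.na(suppressWarnings(as.numeric(f1[3])))) {
      lines <- lines[-1]
      offset <- 1L
    }
  }
  if (length(lines) == 0) {
    return(tibble::tibble(
      query_id = character(), target_id = character(),
      database = character(), bit_score = double(), e_value = double(),
      model_coverage = double(), description = character()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 7L)
  if (length(short) > 0) {
    md_abort(
      sprintf("Truncated HMM hit row at line %d", short[1] + offset),
      "row_error"
    )
  }
  pick <- function(i) vapply(
    fields, function(f) if (i > length(f)) NA_character_ else f[[i]],
    character(1)
  )
  model_length <- parse_numeric_field(pick(3), "model length", offset)
  model_from <- parse_numeric_field(pick(4), "model from", offset)
  model_to <- parse_numeric_field(pick(5), "model to", offset)
  tibble::tibble(
    query_id = pick(1),
    target_id = pick(2),
    database = database_name,
    bit_score = parse_numeric_field(pick(7), "bit score", offset),
    e_value = parse_numeric_field(pick(6), "e-value", offset),
    model_coverage = (model_to - model_from + 1) / model_length,
    description = pick(8)
  )
}

#' Read a per-model score threshold list
#'
#' Reads a KOfam-style threshold list: tab-delimited with columns `model_id`,
#' `threshold`, `score_type` (`full` or `domain`); a header row is allowed. A
#' blank threshold marks a model with no usable cutoff (`NA`), which is
#' distinct from a threshold of zero.
#'
#' @param path Path to the threshold list.
#' @return Tibble with `model_id`, `score_threshold` (`NA` when the model has
#'   no threshold), `score_type`.
#' @export
read_kofam_thresholds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0) {
    f1 <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(f1) >= 2 && f1[2] != "" &&
        is.na(suppressWarnings(as.numeric(f1[2])))) {
      lines <- lines[-1]
    }
  }
  if (length(lines) == 0) {
    return(tibble::tibble(
      model_id = character(), score_threshold = double(),
      score_type = character()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  model_id <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(model_id)) {
    md_abort(
      paste0("Duplicate model id: ", model_id[duplicated(model_id)][1]),
      "format_error"
    )
  }
  raw_thr <- vapply(
    fields, function(f) if (length(f) >= 2) f[[2]] else "", character(1)
  )
  thr <- suppressWarnings(as.numeric(raw_thr))
  bad <- which(is.na(thr) & nzchar(raw_thr))
  if (length(bad) > 0) {
    md_abort(
      sprintf("Unparseable threshold at line %d", bad[1]), "row_error"
    )
  }
  if (any(thr < 0, na.rm = TRUE)) {
    md_abort("Negative score threshold", "format_error")
  }
  tibble::tibble(
    model_id = model_id,
    score_threshold = thr,
    score_type = vapply(
      fields,
      function(f) if (length(f) >= 3 && nzchar(f[[3]])) f[[3]] else "full",
      character(1)
    )
  )
}

#' Read a viral-affiliation (affi-contigs) table
#'
#' Parses the per-gene affiliation dialect written by the upstream viral
#' detector: a `>`-prefixed contig header line followed by one pipe-delimited
#' row per gene (`gene_id|start|end|strand|evidence_code`). Evidence codes
#' are kept verbatim; mapping them to hallmark/viral-like classes happens
#' later via a configurable table.
#'
#' @param path Path to the affiliation table.
#' @return Tibble with `contig_id`, `gene_id`, `ordinal` (0-based position
#'   along the contig), `start`, `end`, `strand`, `evidence_code`, ordered by
#'   contig then ordinal.
#' @export
read_virsorter_affi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- list()
  contig <- NA_character_
  ordinal <- 0L
  last_start <- -Inf
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      contig <- strsplit(sub("^>", "", ln), "|", fixed = TRUE)[[1]][1]
      ordinal <- 0L
      last_start <- -Inf
      next
    }
    if (is.na(contig)) {
      md_abort(
        sprintf("Gene row before any contig header at line %d", i),
        "format_error"
      )
    }
    f <- strsplit(ln, "|", fixed = TRUE)[[1]]
    if (length(f) < 5) {
      md_abort(sprintf("Truncated gene row at line %d", i), "row_error")
    }
    start <- parse_numeric_field(f[2], "start", i - 1L)
    end <- parse_numeric_field(f[3], "end", i - 1L)
    if (start > end) {
      md_abort(sprintf("start > end at line %d", i), "format_error")
    }
    if (start < last_start) {
      md_abort(
        sprintf("Non-monotone gene order on contig %s at line %d", contig, i),
        "format_error"
      )
    }
    last_start <- start
    rows[[length(rows) + 1]] <- tibble::tibble(
      contig_id = contig, gene_id = f[1], ordinal = ordinal,
      start = start, end = end, strand = f[4], evidence_code = f[5]
    )
    ordinal <- ordinal + 1L
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      contig_id = character(), gene_id = character(), ordinal = integer(),
      start = double(), end = double(), strand = character(),
      evidence_code = character()
    ))
  }
  dplyr::bind_rows(rows)
}

#' Read a module-definition table
#'
#' @param path Tab-delimited file with columns `module_id`, `name`,
#'   `definition` (header required).
#' @return Tibble with those three character columns.
#' @export
read_module_table <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character())
  )
}

#' Read a distillate form table
#'
#' The form maps function identifiers (KOs, CAZyme families, peptidase
#' families, ...) to a human-readable description and a metabolic
#' category/subcategory used to organize the distillate sheets. One
#' identifier may appear in several rows (e.g. a CAZyme family promiscuous
#' for multiple substrates); it is then counted in each row.
#'
#' @param path Tab-delimited file with header columns `identifier`,
#'   `description`, `category`, `subcategory`.
#' @return Tibble with those columns.
#' @export
read_distillate_form <- function(path) {
  form <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character())
  )
  required <- c("identifier", "description", "category", "subcategory")
  missing <- setdiff(required, names(form))
  if (length(missing) > 0) {
    md_abort(
      paste0("Form is missing columns: ", paste(missing, collapse = ", ")),
      "form_error"
    )
  }
  if (any(is.na(form$identifier) | !nzchar(form$identifier))) {
    md_abort("Form row with empty identifier", "form_error")
  }
  form
}

#' Read a function-rule table
#'
#' Each row defines one named function as a conjunction of identifier sets:
#' the function is present in a genome when every set contributes at least
#' one observed identifier. Sets are separated by `;`, members within a set
#' by `,`.
#'
#' @param path Tab-delimited file with header columns `function_name`,
#'   `category`, `subcategory`, `required_sets`.
#' @return Tibble with `function_name`, `category`, `subcategory` and a
#'   list-column `required_sets` of character vectors.
#' @export
read_function_rules <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character())
  )
  parse_sets <- function(s) {
    sets <- strsplit(s, ";", fixed = TRUE)[[1]]
    lapply(sets, function(x) trimws(strsplit(x, ",", fixed = TRUE)[[1]]))
  }
  rules <- raw %>%
    mutate(required_sets = purrr::map(.data$required_sets, parse_sets))
  validate_function_rules(rules)
  rules
}

validate_function_rules <- function(rules) {
  ok <- purrr::map_lgl(rules$required_sets, function(sets) {
    length(sets) >= 1 &&
      all(vapply(sets, function(s) length(s) >= 1 && all(nzchar(s)),
                 logical(1)))
  })
  if (!all(ok)) {
    md_abort(
      paste0(
        "Function rule with empty identifier set: ",
        rules$function_name[!ok][1]
      ),
      "form_error"
    )
  }
  invisible(rules)
}
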