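# Parser for KEGG-style metabolic module definition strings.
#
# Grammar (loosest to tightest binding):
#   space  - separates sequential steps (ordered AND)
#   comma  - separates alternatives (OR)
#   plus   - joins complex subunits (AND within one node)
#   minus  - marks the following component optional (excluded from scoring)
#   parens - grouping, nesting unbounded
# Leaves are orthology identifiers.

module_node <- function(kind, children = NULL, ko = NULL) {
  structure(list(kind = kind, children = children, ko = ko),
            class = "module_node")
}

tokenize_module <- function(text) {
  chars <- strsplit(text, "")[[1]]
  tokens <- list()
  i <- 1
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t")) {
      # collapse runs of whitespace into one step separator
      while (i <= n && chars[i] %in% c(" ", "\t")) i <- i + 1
      tokens[[length(tokens) + 1]] <- list(type = "SPACE", pos = i)
      next
    }
    if (ch %in% c("(", ")", ",", "+", "-")) {
      tokens[[length(tokens) + 1]] <- list(type = ch, pos = i)
      i <- i + 1
      next
    }
    if (grepl("[A-Za-z0-9_.]", ch)) {
      j <- i
      while (j <= n && grepl("[A-Za-z0-9_.]", chars[j])) j <- j + 1
      tokens[[length(tokens) + 1]] <- list(
        type = "ID", value = paste(chars[i:(j - 1)], collapse = ""), pos = i
      )
      i <- j
      next
    }
    md_abort(
      sprintf("Unexpected character %s at position %d", dQuote(ch), i),
      "parse_error"
    )
  }
  tokens
}

#' Parse a module definition string
#'
#' Parses a metabolic module definition into a tree with node kinds
#' `STEP_SEQUENCE` (space-separated ordered steps), `ALTERNATIVE`
#' (comma-separated paths), `COMPLEX` (`+`-joined subunits), `OPTIONAL`
#' (`-`-prefixed components, excluded from scoring) and `LEAF` (orthology
#' identifiers). The canonical re-serialization
#' ([deparse_module_definition()]) of the result re-parses to an identical
#' tree.
#'
#' @param text Definition string, e.g. `"(K00001,K00002) K00003+K00004"`.
#' @return A `module_node` tree.
#' @export
#' @examples
#' tree <- parse_module_definition("(K1,K2) K3")
#' deparse_module_definition(tree)
parse_module_definition <- function(text) {
  tokens <- tokenize_module(trimws(text))
  if (length(tokens) == 0) {
    md_abort("Empty module definition", "parse_error")
  }
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$i <- 1

  peek <- function() {
    if (state$i <= length(state$tokens)) state$tokens[[state$i]] else NULL
  }
  advance <- function() {
    tok <- peek()
    state$i <- state$i + 1
    tok
  }
  expect_pos <- function() {
    tok <- peek()
    if (is.null(tok)) nchar(text) + 1 else tok$pos
  }

  parse_seq <- function() {
    parts <- list(parse_alt())
    while (!is.null(peek()) && peek()$type == "SPACE") {
      advance()
      if (is.null(peek()) || peek()$type == ")") break
      parts[[length(parts) + 1]] <- parse_alt()
    }
    if (length(parts) == 1) parts[[1]] else
      module_node("STEP_SEQUENCE", parts)
  }
  parse_alt <- function() {
    parts <- list(parse_cpx())
    while (!is.null(peek()) && peek()$type == ",") {
      advance()
      parts[[length(parts) + 1]] <- parse_cpx()
    }
    if (length(parts) == 1) parts[[1]] else module_node("ALTERNATIVE", parts)
  }
  parse_cpx <- function() {
    parts <- list()
    if (!is.null(peek()) && peek()$type == "-") {
      advance()
      parts[[1]] <- module_node("OPTIONAL", list(parse_atom()))
    } else {
      parts[[1]] <- parse_atom()
    }
    while (!is.null(peek()) && peek()$type %in% c("+", "-")) {
      op <- advance()$type
      nxt <- parse_atom()
      parts[[length(parts) + 1]] <-
        if (op == "-") module_node("OPTIONAL", list(nxt)) else nxt
    }
    if (length(parts) == 1) parts[[1]] else module_node("COMPLEX", parts)
  }
  parse_atom <- function() {
    tok <- peek()
    if (is.null(tok)) {
      md_abort(
        sprintf("Dangling operator at position %d", expect_pos()),
        "parse_error"
      )
    }
    if (tok$type == "ID") {
      advance()
      return(module_node("LEAF", ko = tok$value))
    }
    if (tok$type == "(") {
      open_pos <- tok$pos
      advance()
      inner <- parse_seq()
      closing <- peek()
      if (is.null(closing) || closing$type != ")") {
        md_abort(
          sprintf("Unbalanced parenthesis opened at position %d", open_pos),
          "parse_error"
        )
      }
      advance()
      return(inner)
    }
    md_abort(
      sprintf("Unexpected token at position %d", tok$pos), "parse_error"
    )
  }

  tree <- parse_seq()
  leftover <- peek()
  if (!is.null(leftover)) {
    md_abort(
      sprintf("Unexpected token at position %d", leftover$pos), "parse_error"
    )
  }
  tree
}

node_precedence <- function(node) {
  switch(node$kind,
    STEP_SEQUENCE = 1, ALTERNATIVE = 2, COMPLEX = 3, OPTIONAL = 3,
    LEAF = 4
  )
}

#' Serialize a module parse tree to its canonical definition string
#'
#' @param node A `module_node` from [parse_module_definition()].
#' @return Canonical definition string; parsing it reproduces the tree.
#' @export
deparse_module_definition <- function(node) {
  wrap <- function(child, min_prec) {
    s <- deparse_module_definition(child)
    if (node_precedence(child) < min_prec) paste0("(", s, ")") else s
  }
  switch(node$kind,
    LEAF = node$ko,
    OPTIONAL = paste0("-", wrap(node$children[[1]], 4)),
    COMPLEX = {
      parts <- vapply(node$children, function(ch) {
        if (ch$kind == "OPTIONAL") {
          paste0("-", wrap(ch$children[[1]], 4))
        } else {
          paste0("+", wrap(ch, 4))
        }
      }, character(1))
      sub("^\\+", "", paste(parts, collapse = ""))
    },
    ALTERNATIVE = paste(
      vapply(node$children, wrap, character(1), min_prec = 3),
      collapse = ","
    ),
    STEP_SEQUENCE = paste(
      vapply(node$children, wrap, character(1), min_prec = 2),
      collapse = " "
    )
  )
}

# Drop OPTIONAL components (excluded from both scoring metrics), collapsing
# nodes left with a single child. Returns NULL when nothing remains.
strip_optional <- function(node) {
  if (node$kind == "OPTIONAL") {
    return(NULL)
  }
  if (node$kind == "LEAF") {
    return(node)
  }
  kept <- purrr::compact(lapply(node$children, strip_optional))
  if (length(kept) == 0) {
    return(NULL)
  }
  if (length(kept) == 1) {
    return(kept[[1]])
  }
  module_node(node$kind, kept)
}

# All leaf identifiers under a node, optionally ignoring OPTIONAL subtrees.
module_leaves <- function(node, include_optional = TRUE) {
  if (node$kind == "LEAF") {
    return(node$ko)
  }
  if (node$kind == "OPTIONAL" && !include_optional) {
    return(character())
  }
  unlist(lapply(node$children, module_leaves,
                include_optional = include_optional))
}

#' Pathway step coverage
#'
#' Fraction of a module's top-level steps containing at least one observed,
#' non-optional gene. Substeps and subpaths are considered: a step counts as
#' covered when any non-optional leaf anywhere under it is present. Steps
#' consisting only of optional components are excluded from the denominator.
#'
#' @param module A `module_node` tree or a definition string.
#' @param present Character vector of observed orthology identifiers.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' step_coverage("K1 K2 K3 K4", c("K1", "K3"))
step_coverage <- function(module, present) {
  if (is.character(module)) module <- parse_module_definition(module)
  steps <- if (module$kind == "STEP_SEQUENCE") module$children else
    list(module)
  scoring <- purrr::keep(
    steps, ~ length(module_leaves(.x, include_optional = FALSE)) > 0
  )
  if (length(scoring) == 0) {
    md_abort("Module has no scorable steps", "empty_module_error")
  }
  covered <- purrr::map_lgl(
    scoring,
    ~ any(module_leaves(.x, include_optional = FALSE) %in% present)
  )
  mean(covered)
}
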