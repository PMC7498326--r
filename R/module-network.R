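# Directed-network representation of a metabolic module and the
# best-path completion metric.

# Resolve the subunit choice sets of a complex: each child contributes a
# list of alternative leaf sets; the complex expands to the cartesian
# product. Optional subunits are dropped before this is called.
complex_choices <- function(node) {
  child_sets <- lapply(node$children, function(ch) {
    switch(ch$kind,
      LEAF = list(ch$ko),
      ALTERNATIVE = {
        unlist(lapply(ch$children, function(alt) {
          switch(alt$kind,
            LEAF = list(alt$ko),
            COMPLEX = complex_choices(alt),
            md_abort(
              "Step sequences inside complexes are not supported",
              "network_error"
            )
          )
        }), recursive = FALSE)
      },
      COMPLEX = complex_choices(ch),
      md_abort(
        "Step sequences inside complexes are not supported", "network_error"
      )
    )
  })
  combos <- list(character())
  for (cs in child_sets) {
    combos <- unlist(
      lapply(combos, function(acc) lapply(cs, function(s) c(acc, s))),
      recursive = FALSE
    )
  }
  combos
}

#' Build the directed KO network of a module
#'
#' Represents a parsed module as a directed acyclic network: orthology
#' identifiers are nodes and outgoing edges connect each node to the next
#' one in the module. Alternatives become parallel branches, sequences
#' chain, and complexes collapse to composite nodes carrying their subunit
#' set (a complex over alternatives expands into one composite node per
#' subunit combination). Optional components are excluded. Unique source and
#' sink nodes bracket the network.
#'
#' @param module A `module_node` tree or definition string.
#' @return An object of class `module_network`: list with `nodes` (tibble
#'   `node`, `label`, `subunits` list-column, `weight`) and `edges` (tibble
#'   `from`, `to`).
#' @export
#' @examples
#' net <- build_module_network("(K1,K2) K3")
#' net$nodes
build_module_network <- function(module) {
  if (is.character(module)) module <- parse_module_definition(module)
  module <- strip_optional(module)
  if (is.null(module)) {
    md_abort("Module has no non-optional content", "empty_module_error")
  }
  env <- new.env(parent = emptyenv())
  env$labels <- character()
  env$subunits <- list()
  env$edges_from <- integer()
  env$edges_to <- integer()

  add_node <- function(label, subunits) {
    id <- length(env$labels) + 1L
    env$labels[id] <- label
    env$subunits[[id]] <- subunits
    id
  }
  add_edges <- function(from, to) {
    grid <- expand.grid(from = from, to = to)
    env$edges_from <- c(env$edges_from, grid$from)
    env$edges_to <- c(env$edges_to, grid$to)
  }

  build <- function(node) {
    switch(node$kind,
      LEAF = {
        id <- add_node(node$ko, node$ko)
        list(entry = id, exit = id)
      },
      COMPLEX = {
        ids <- vapply(complex_choices(node), function(subs) {
          add_node(paste(subs, collapse = "+"), subs)
        }, integer(1))
        list(entry = ids, exit = ids)
      },
      ALTERNATIVE = {
        frags <- lapply(node$children, build)
        list(
          entry = unlist(lapply(frags, `[[`, "entry")),
          exit = unlist(lapply(frags, `[[`, "exit"))
        )
      },
      STEP_SEQUENCE = {
        frags <- lapply(node$children, build)
        for (i in seq_len(length(frags) - 1)) {
          add_edges(frags[[i]]$exit, frags[[i + 1]]$entry)
        }
        list(entry = frags[[1]]$entry, exit = frags[[length(frags)]]$exit)
      }
    )
  }

  frag <- build(module)
  source_id <- add_node("source", character())
  sink_id <- add_node("sink", character())
  add_edges(source_id, frag$entry)
  add_edges(frag$exit, sink_id)

  nodes <- tibble::tibble(
    node = seq_along(env$labels),
    label = env$labels,
    subunits = env$subunits,
    weight = lengths(env$subunits)
  )
  structure(
    list(
      nodes = nodes,
      edges = tibble::tibble(from = env$edges_from, to = env$edges_to),
      source = source_id,
      sink = sink_id
    ),
    class = "module_network"
  )
}

#' @export
print.module_network <- function(x, ...) {
  cat("<module_network> ", nrow(x$nodes) - 2, " KO node(s), ",
      nrow(x$edges), " edge(s)\n", sep = "")
  invisible(x)
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges, directed = TRUE,
    vertices = data.frame(name = network$nodes$node)
  )
}

#' Best-path completion of a module network
#'
#' The completion of a module is the coverage of the source-to-sink path
#' with the largest fraction of its genes present. A composite complex node
#' weighs as many units as it has subunits and contributes fractionally
#' (subunits present / subunits total), so a partially present complex adds
#' partial credit. Computed exactly by dynamic programming over the DAG,
#' carrying the Pareto frontier of (present weight, total weight) pairs per
#' node and maximizing the ratio at the sink.
#'
#' @param network A `module_network`, `module_node` tree, or definition
#'   string.
#' @param present Character vector of observed orthology identifiers.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' best_path_completion("(K1 K2),(K3)", "K3")
best_path_completion <- function(network, present) {
  if (!inherits(network, "module_network")) {
    network <- build_module_network(network)
  }
  nodes <- network$nodes
  gains <- purrr::map2(
    nodes$subunits, nodes$weight,
    function(subs, w) c(p = sum(subs %in% present), t = w)
  )
  g <- as_igraph(network)
  topo <- as.integer(igraph::topo_sort(g, mode = "out")$name)
  preds <- lapply(
    igraph::adjacent_vertices(g, v = as.character(nodes$node),
                              mode = "in"),
    function(v) as.integer(names(v))
  )
  names(preds) <- nodes$node

  # Pareto frontier per node: keep (present, total) pairs not dominated by
  # another pair with >= present and <= total.
  prune <- function(mat) {
    if (nrow(mat) <= 1) {
      return(mat)
    }
    mat <- unique(mat)
    ord <- order(mat[, "t"], -mat[, "p"])
    mat <- mat[ord, , drop = FALSE]
    best_p <- -Inf
    keep <- logical(nrow(mat))
    for (i in seq_len(nrow(mat))) {
      if (mat[i, "p"] > best_p) {
        keep[i] <- TRUE
        best_p <- mat[i, "p"]
      }
    }
    mat[keep, , drop = FALSE]
  }

  frontier <- vector("list", nrow(nodes))
  for (v in topo) {
    gain <- gains[[v]]
    pv <- preds[[as.character(v)]]
    if (length(pv) == 0) {
      frontier[[v]] <- matrix(gain, nrow = 1,
                              dimnames = list(NULL, c("p", "t")))
      next
    }
    incoming <- do.call(rbind, frontier[pv])
    incoming[, "p"] <- incoming[, "p"] + gain["p"]
    incoming[, "t"] <- incoming[, "t"] + gain["t"]
    frontier[[v]] <- prune(incoming)
  }
  at_sink <- frontier[[network$sink]]
  if (is.null(at_sink) || nrow(at_sink) == 0) {
    md_abort("Network has no source-to-sink path", "network_error")
  }
  valid <- at_sink[at_sink[, "t"] > 0, , drop = FALSE]
  if (nrow(valid) == 0) {
    md_abort("Network has no weighted path", "network_error")
  }
  max(valid[, "p"] / valid[, "t"])
}

#' Evaluate a function-presence rule
#'
#' A function is present when every required identifier set contributes at
#' least one observed identifier: single-gene functions need that one gene,
#' while set-based functions accept any member of each set.
#'
#' @param rule Either a list of character vectors (the required sets) or a
#'   one-row tibble from [read_function_rules()].
#' @param observed Character vector of observed identifiers.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' evaluate_function_rule(list(c("x", "y")), "y")
evaluate_function_rule <- function(rule, observed) {
  sets <- if (is.data.frame(rule)) rule$required_sets[[1]] else rule
  all(vapply(sets, function(s) any(s %in% observed), logical(1)))
}
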