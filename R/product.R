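# Product: one machine-readable per-genome table and an HTML heatmap with
# three blocks — pathway coverage, complex completion and function presence.

#' Build the product table
#'
#' Computes, per genome: step coverage for each metabolic module
#' ([step_coverage()]), best-path completion for each electron-transport
#' style complex module ([best_path_completion()]), and presence for each
#' named function rule ([evaluate_function_rule()]).
#'
#' @param raw_table Raw annotation tibble or a `mag_annotation`.
#' @param modules Tibble `module_id`, `name`, `definition` scored by step
#'   coverage.
#' @param complexes Tibble `module_id`, `name`, `definition` scored by
#'   best-path completion.
#' @param function_rules Tibble from [read_function_rules()].
#' @param genome_ids Optional genome ordering (default: input order of first
#'   appearance; pass `sort(unique(...))` for lexicographic).
#' @return An object of class `mag_product`: list with `table` (tibble,
#'   rows = genomes) and `columns` (tibble `column`, `block`, `category`,
#'   `name` metadata).
#' @export
build_product_table <- function(raw_table, modules, complexes,
                                function_rules, genome_ids = NULL) {
  if (inherits(raw_table, "mag_annotation")) raw_table <- raw_table$raw
  genome_ids <- genome_ids %||% unique(raw_table$genome_id)
  ids <- gene_identifiers(raw_table)
  observed <- split(ids$identifier, ids$genome_id)

  parsed_mod <- purrr::map(modules$definition, parse_module_definition)
  networks <- purrr::map(complexes$definition, build_module_network)

  tab <- tibble::tibble(genome_id = genome_ids)
  meta <- list()
  obs_of <- function(g) observed[[g]] %||% character()

  for (i in seq_len(nrow(modules))) {
    col <- paste0("module_", modules$module_id[i])
    tab[[col]] <- purrr::map_dbl(
      genome_ids, ~ step_coverage(parsed_mod[[i]], obs_of(.x))
    )
    meta[[length(meta) + 1]] <- tibble::tibble(
      column = col, block = "pathway_coverage",
      category = modules$module_id[i], name = modules$name[i]
    )
  }
  for (i in seq_len(nrow(complexes))) {
    col <- paste0("complex_", complexes$module_id[i])
    tab[[col]] <- purrr::map_dbl(
      genome_ids, ~ best_path_completion(networks[[i]], obs_of(.x))
    )
    meta[[length(meta) + 1]] <- tibble::tibble(
      column = col, block = "complex_completion",
      category = complexes$module_id[i], name = complexes$name[i]
    )
  }
  for (i in seq_len(nrow(function_rules))) {
    col <- paste0("function_", function_rules$function_name[i])
    tab[[col]] <- purrr::map_lgl(
      genome_ids,
      ~ evaluate_function_rule(function_rules$required_sets[[i]], obs_of(.x))
    )
    meta[[length(meta) + 1]] <- tibble::tibble(
      column = col, block = "function_presence",
      category = function_rules$category[i],
      name = function_rules$function_name[i]
    )
  }
  structure(
    list(table = tab, columns = dplyr::bind_rows(meta)),
    class = "mag_product"
  )
}

#' @export
print.mag_product <- function(x, ...) {
  cat("<mag_product> ", nrow(x$table), " genome(s) x ",
      nrow(x$columns), " column(s)\n", sep = "")
  invisible(x)
}

product_cell_fill <- function(value) {
  pal <- grDevices::colorRamp(c("#FFFFFF", "#2171B5"))
  rgbm <- pal(pmin(pmax(as.numeric(value), 0), 1))
  grDevices::rgb(rgbm[, 1], rgbm[, 2], rgbm[, 3], maxColorValue = 255)
}

render_heatmap_svg <- function(table, columns) {
  cell <- 14
  label_w <- 140
  header_h <- 150
  n_r <- nrow(table)
  n_c <- nrow(columns)
  width <- label_w + n_c * cell + 20
  height <- header_h + n_r * cell + 20
  svg <- c(sprintf(
    "<svg xmlns='http://www.w3.org/2000/svg' width='%d' height='%d'>",
    width, height
  ))
  svg <- c(svg, sprintf(
    paste0("<text x='%d' y='%d' font-size='9' text-anchor='start' ",
           "transform='rotate(-60 %d %d)'>%s</text>"),
    label_w + seq_len(n_c) * cell - cell %/% 2, header_h - 4,
    label_w + seq_len(n_c) * cell - cell %/% 2, header_h - 4,
    columns$name
  ))
  rows <- character(n_r)
  for (r in seq_len(n_r)) {
    y <- header_h + (r - 1) * cell
    vals <- as.numeric(table[r, columns$column])
    is_bool <- columns$block == "function_presence"
    fill <- ifelse(
      is_bool,
      ifelse(vals > 0, "#238B45", "#F0F0F0"),
      product_cell_fill(vals)
    )
    tips <- ifelse(
      is_bool,
      paste0(table$genome_id[r], " | ", columns$name, ": ",
             ifelse(vals > 0, "present", "absent")),
      paste0(table$genome_id[r], " | ", columns$name, ": ",
             round(vals * 100, 1), "% complete")
    )
    rects <- sprintf(
      paste0("<rect x='%d' y='%d' width='%d' height='%d' fill='%s' ",
             "stroke='#DDD' data-value='%s'><title>%s</title></rect>"),
      label_w + (seq_len(n_c) - 1) * cell, y, cell, cell, fill,
      format(vals, trim = TRUE, digits = 17), tips
    )
    rows[r] <- paste0(
      sprintf("<text x='%d' y='%d' font-size='9'>%s</text>",
              4L, y + cell - 4L, table$genome_id[r]),
      paste(rects, collapse = "")
    )
  }
  c(svg, rows, "</svg>")
}

#' Render the product heatmap as HTML
#'
#' Writes self-contained HTML heatmap pages for a product table: pathway
#' coverage and complex completion cells on a continuous 0-1 color scale,
#' function presence as a binary palette; hovering a cell reports the
#' genome, column and percent completion. Tables with more than
#' `chunk_size` genomes are split, in row order, into successive files of
#' at most `chunk_size` rows each. Every cell value is copied from the
#' table — the HTML is a view, never a recomputation.
#'
#' @param product A `mag_product`.
#' @param dir Output directory.
#' @param chunk_size Maximum genomes per HTML file (default 1000).
#' @return Character vector of the HTML paths written (one per chunk).
#' @export
render_product_html <- function(product, dir, chunk_size = 1000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- product$table
  n <- nrow(tab)
  if (n == 0) {
    path <- file.path(dir, "product_1.html")
    writeLines(c(
      "<!DOCTYPE html><html><head><meta charset='utf-8'/>",
      "<title>Metabolism product</title></head><body>",
      "<p>No genomes to display.</p></body></html>"
    ), path)
    return(path)
  }
  starts <- seq(1, n, by = chunk_size)
  paths <- character(length(starts))
  for (k in seq_along(starts)) {
    idx <- starts[k]:min(starts[k] + chunk_size - 1, n)
    path <- file.path(dir, sprintf("product_%d.html", k))
    body <- render_heatmap_svg(tab[idx, ], product$columns)
    writeLines(c(
      "<!DOCTYPE html><html><head><meta charset='utf-8'/>",
      "<title>Metabolism product</title></head><body>",
      sprintf("<h2>Genome metabolism summary (%d-%d of %d)</h2>",
              idx[1], idx[length(idx)], n),
      body,
      "</body></html>"
    ), path)
    paths[k] <- path
  }
  paths
}

#' Write the product data table
#'
#' @param product A `mag_product`.
#' @param path Destination TSV.
#' @return `path`, invisibly.
#' @export
write_product_table <- function(product, path) {
  readr::write_tsv(product$table, path)
  invisible(path)
}
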