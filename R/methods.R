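# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Turn a result object into a tidy tibble
#'
#' @param x A `mag_annotation`, `mag_product`, `mag_distillate` or
#'   `viral_annotation`.
#' @param ... Unused.
#' @return A tibble: the merged raw table for annotations, the long
#'   (genome, column, value) table for products, the long per-genome count
#'   table for distillates, and the per-gene context table (flags collapsed
#'   to a string) for viral results.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
tidy.mag_annotation <- function(x, ...) x$raw

#' @rdname tidy
#' @export
tidy.mag_product <- function(x, ...) {
  x$table %>%
    tidyr::pivot_longer(
      -"genome_id", names_to = "column", values_to = "value",
      values_transform = as.numeric
    ) %>%
    left_join(x$columns, by = "column")
}

#' @rdname tidy
#' @export
tidy.mag_distillate <- function(x, ...) {
  meta <- c("identifier", "description", "category", "subcategory")
  tibble::as_tibble(x) %>%
    tidyr::pivot_longer(
      -all_of(meta), names_to = "genome_id", values_to = "count"
    )
}

#' @rdname tidy
#' @export
tidy.viral_annotation <- function(x, ...) {
  x$contexts %>%
    mutate(
      flags = purrr::map_chr(.data$flags, paste, collapse = ""),
      is_amg = .data$gene_id %in% x$amgs$gene_id
    )
}

#' One-row summary of a result object
#'
#' @param x A `mag_annotation` or `viral_annotation`.
#' @param ... Unused.
#' @return One-row tibble of headline counts.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname glance
#' @export
glance.mag_annotation <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$raw),
    n_genomes = length(unique(x$raw$genome_id)),
    n_rank_a = sum(x$raw$rank == "A"),
    n_rank_e = sum(x$raw$rank == "E"),
    n_annotated = sum(x$raw$status == "annotated"),
    n_hypothetical = sum(x$raw$status == "hypothetical"),
    n_unannotated = sum(x$raw$status == "unannotated")
  )
}

#' @rdname glance
#' @export
glance.viral_annotation <- function(x, ...) {
  tibble::tibble(
    n_contigs = length(unique(x$contexts$contig_id)),
    n_genes = nrow(x$contexts),
    n_amgs = nrow(x$amgs),
    median_aux_score = stats::median(x$contexts$aux_score)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the rank distribution of an annotation
#'
#' @param object A `mag_annotation`.
#' @param ... Unused.
#' @return A ggplot: genes per confidence rank, per genome.
#' @method autoplot mag_annotation
#' @export
autoplot.mag_annotation <- function(object, ...) {
  ggplot2::ggplot(
    object$raw,
    ggplot2::aes(x = .data$rank, fill = .data$genome_id)
  ) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(
      x = "annotation confidence rank", y = "genes", fill = "genome",
      title = "Annotation confidence ranks"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a product table as a static heatmap
#'
#' @param object A `mag_product`.
#' @param ... Unused.
#' @return A ggplot tile heatmap mirroring the HTML product view.
#' @method autoplot mag_product
#' @export
autoplot.mag_product <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$name, y = .data$genome_id, fill = .data$value)
  ) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient(
      low = "white", high = "#2171B5", limits = c(0, 1)
    ) +
    ggplot2::facet_grid(. ~ block, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = NULL, fill = "fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 60, hjust = 1)
    )
}

#' Plot auxiliary-score distribution of a viral annotation
#'
#' @param object A `viral_annotation`.
#' @param ... Unused.
#' @return A ggplot bar chart of auxiliary scores, AMG calls highlighted.
#' @method autoplot viral_annotation
#' @export
autoplot.viral_annotation <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = factor(.data$aux_score), fill = .data$is_amg)
  ) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#D7301F", `FALSE` = "grey70")
    ) +
    ggplot2::labs(
      x = "auxiliary score", y = "genes", fill = "potential AMG",
      title = "Viral gene auxiliary scores"
    ) +
    ggplot2::theme_minimal()
}
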