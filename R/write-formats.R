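# Writers for the annotation outputs: merged raw table, GFF3, GenBank,
# per-gene FASTA files and RNA count/position tables.

#' Write the merged raw annotation table
#'
#' @param raw_table Tibble as produced by [merge_raw_table()].
#' @param path Destination TSV path.
#' @return `path`, invisibly.
#' @export
write_raw_table <- function(raw_table, path) {
  readr::write_tsv(raw_table, path, na = "")
  invisible(path)
}

#' Read back a merged raw annotation table
#'
#' @param path TSV written by [write_raw_table()].
#' @return Tibble with the raw-table schema; empty hit fields come back as
#'   `NA`.
#' @export
read_raw_table <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      start = readr::col_double(),
      end = readr::col_double(),
      .default = readr::col_guess()
    ),
    na = ""
  )
}

genes_to_granges <- function(genes, annotations = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  meta <- tibble::tibble(
    source = "magdistill", type = "CDS",
    ID = genes$gene_id, genome = genes$genome_id
  )
  if (!is.null(annotations)) {
    ann_cols <- annotations %>%
      select(
        "gene_id", dplyr::any_of("rank"), dplyr::any_of("status"),
        dplyr::ends_with("_id") & !dplyr::any_of(
          c("gene_id", "genome_id", "contig_id")
        )
      )
    meta <- dplyr::left_join(
      meta, ann_cols, by = c("ID" = "gene_id")
    )
  }
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(as.data.frame(meta))
  gr
}

#' Write gene annotations as GFF3
#'
#' Coordinates are 1-based inclusive; per-database identifiers, rank and
#' status travel as GFF3 attributes. A genome with zero genes yields a valid
#' header-only file.
#'
#' @param genes Gene tibble (`gene_id`, `genome_id`, `contig_id`, `start`,
#'   `end`, `strand`, ...).
#' @param path Destination `.gff` path.
#' @param annotations Optional merged annotation tibble; its rank, status and
#'   `*_id` columns become attributes.
#' @param contigs Optional contig tibble (from [read_fasta()]); when given,
#'   genes referencing unknown contigs raise a consistency error.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, annotations = NULL, contigs = NULL) {
  if (!is.null(contigs)) {
    unknown <- setdiff(genes$contig_id, contigs$id)
    if (length(unknown) > 0) {
      md_abort(
        paste0("Gene references unknown contig: ", unknown[1]),
        "consistency_error"
      )
    }
  }
  if (nrow(genes) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- genes_to_granges(genes, annotations)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file of gene features into a tibble
#'
#' @param path GFF3 path.
#' @return Tibble with `gene_id`, `contig_id`, `start`, `end`, `strand` and
#'   any attribute columns present.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- as.data.frame(S4Vectors::mcols(gr))
  out <- tibble::tibble(
    gene_id = if ("ID" %in% names(md)) as.character(md$ID) else
      NA_character_,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  extra <- md[setdiff(names(md), c("ID", "source", "type", "score", "phase"))]
  if (ncol(extra) > 0) {
    extra[] <- lapply(extra, function(x) as.character(unlist(x)))
    out <- dplyr::bind_cols(out, tibble::as_tibble(extra))
  }
  out
}

# Wrap a sequence into fixed-width GenBank ORIGIN lines.
format_origin <- function(seq) {
  n <- nchar(seq)
  starts <- seq(1, n, by = 60)
  vapply(starts, function(s) {
    chunk <- substr(seq, s, min(s + 59, n))
    blocks <- substring(
      chunk,
      seq(1, nchar(chunk), 10),
      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk))
    )
    sprintf("%9d %s", s, paste(blocks, collapse = " "))
  }, character(1))
}

#' Write one GenBank-format flat file per genome
#'
#' Emits a minimal GenBank record per contig (LOCUS, FEATURES with one CDS
#' per gene carrying locus_tag and product qualifiers, ORIGIN with the
#' contig sequence), grouped into one file per genome.
#'
#' @param genes Gene tibble.
#' @param contigs Contig tibble from [read_fasta()] with a `genome_id`
#'   column.
#' @param dir Output directory; files are named `<genome_id>.gbk`.
#' @param annotations Optional merged annotations supplying product
#'   descriptions.
#' @return Character vector of the files written, invisibly.
#' @export
write_genbank <- function(genes, contigs, dir, annotations = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  unknown <- setdiff(genes$contig_id, contigs$id)
  if (length(unknown) > 0) {
    md_abort(
      paste0("Gene references unknown contig: ", unknown[1]),
      "consistency_error"
    )
  }
  products <- character()
  if (!is.null(annotations)) {
    desc_col <- intersect(
      c("kegg_description", "product", "description"), names(annotations)
    )[1]
    if (!is.na(desc_col)) {
      products <- setNames(
        as.character(annotations[[desc_col]]), annotations$gene_id
      )
    }
  }
  files <- character()
  for (gid in unique(contigs$genome_id)) {
    path <- file.path(dir, paste0(gid, ".gbk"))
    con <- file(path, "w")
    gcontigs <- contigs[contigs$genome_id == gid, ]
    for (i in seq_len(nrow(gcontigs))) {
      ctg <- gcontigs[i, ]
      writeLines(sprintf(
        "LOCUS       %s %d bp    DNA     linear   ENV %s",
        ctg$id, nchar(ctg$sequence), format(Sys.Date(), "%d-%b-%Y")
      ), con)
      writeLines(sprintf("DEFINITION  %s", ctg$description), con)
      writeLines("FEATURES             Location/Qualifiers", con)
      cg <- genes[genes$contig_id == ctg$id, ]
      cg <- cg[order(cg$start), ]
      for (j in seq_len(nrow(cg))) {
        g <- cg[j, ]
        loc <- sprintf("%d..%d", g$start, g$end)
        if (g$strand == "-") loc <- sprintf("complement(%s)", loc)
        writeLines(sprintf("     CDS             %s", loc), con)
        writeLines(sprintf("                     /locus_tag=\"%s\"",
                           g$gene_id), con)
        prod <- products[g$gene_id]
        if (!is.na(prod) && length(prod) == 1 && nzchar(prod)) {
          writeLines(sprintf("                     /product=\"%s\"", prod),
                     con)
        }
      }
      writeLines("ORIGIN", con)
      writeLines(format_origin(tolower(ctg$sequence)), con)
      writeLines("//", con)
    }
    close(con)
    files <- c(files, path)
  }
  invisible(files)
}

#' Write amino-acid (and optionally nucleotide) FASTA of all genes
#'
#' @param genes Gene tibble with a `protein` column and optionally a
#'   `nucleotide` column.
#' @param faa_path Destination for the protein FASTA.
#' @param fna_path Optional destination for the nucleotide FASTA.
#' @return Invisibly, the paths written.
#' @export
write_gene_fasta <- function(genes, faa_path, fna_path = NULL) {
  aa <- Biostrings::BStringSet(setNames(genes$protein, genes$gene_id))
  Biostrings::writeXStringSet(aa, faa_path)
  paths <- faa_path
  if (!is.null(fna_path) && "nucleotide" %in% names(genes)) {
    nt <- Biostrings::BStringSet(setNames(genes$nucleotide, genes$gene_id))
    Biostrings::writeXStringSet(nt, fna_path)
    paths <- c(paths, fna_path)
  }
  invisible(paths)
}

#' Write tRNA/rRNA count and position tables
#'
#' @param rna_table Tibble with `genome_id`, `contig_id`, `type` (e.g.
#'   `tRNA-Ala` or `16S`), `start`, `end`.
#' @param counts_path,positions_path Destination TSVs.
#' @return Invisibly, the paths written.
#' @export
write_rna_tables <- function(rna_table, counts_path, positions_path) {
  counts <- rna_table %>%
    group_by(.data$genome_id, .data$type) %>%
    summarise(n = dplyr::n(), .groups = "drop")
  readr::write_tsv(counts, counts_path)
  readr::write_tsv(
    rna_table %>% arrange(.data$genome_id, .data$contig_id, .data$start),
    positions_path
  )
  invisible(c(counts_path, positions_path))
}

#' Write the full set of annotation outputs
#'
#' One call emitting everything the annotation stage produces: the merged
#' raw table, a GFF3 of all genes, one GenBank file per genome, protein (and
#' nucleotide, when available) FASTA of all genes, and tRNA/rRNA tables when
#' an RNA table is supplied.
#'
#' @param annotations Merged raw annotation tibble ([merge_raw_table()]).
#' @param genes Gene tibble.
#' @param contigs Contig tibble with `genome_id`.
#' @param dir Output directory (created if needed).
#' @param rna_table Optional RNA feature tibble for [write_rna_tables()].
#' @return Named list of the paths written, invisibly.
#' @export
write_annotation_outputs <- function(annotations, genes, contigs, dir,
                                     rna_table = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(
    raw = write_raw_table(annotations, file.path(dir, "annotations.tsv")),
    gff3 = write_gff3(
      genes, file.path(dir, "genes.gff"), annotations, contigs
    ),
    genbank = write_genbank(genes, contigs, file.path(dir, "genbank"),
                            annotations),
    faa = file.path(dir, "genes.faa")
  )
  write_gene_fasta(
    genes, out$faa,
    fna_path = if ("nucleotide" %in% names(genes)) {
      file.path(dir, "genes.fna")
    }
  )
  if (!is.null(rna_table)) {
    write_rna_tables(
      rna_table,
      file.path(dir, "rna_counts.tsv"),
      file.path(dir, "rna_positions.tsv")
    )
    out$rna_counts <- file.path(dir, "rna_counts.tsv")
    out$rna_positions <- file.path(dir, "rna_positions.tsv")
  }
  invisible(out)
}
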