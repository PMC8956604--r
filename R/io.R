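# Plain-text readers/writers for the pipeline's tabular formats.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a guide library manifest TSV
#'
#' Columns: `guide_id`, `target_id`, `gene_symbol`, `is_negative_control`.
#' @param library An `sgrna_library`.
#' @param path File path.
#' @return `path` (write) or an `sgrna_library` (read).
#' @export
write_library_tsv <- function(library, path) {
  write_tsv(as.data.frame(library), path)
}

#' @rdname write_library_tsv
#' @export
read_library_tsv <- function(path) {
  lib <- read.delim(path, stringsAsFactors = FALSE)
  lib$is_negative_control <- as.logical(lib$is_negative_control)
  class(lib) <- c("sgrna_library", "data.frame")
  attr(lib, "negative_control_genes") <-
    sort(unique(lib$gene_symbol[lib$is_negative_control]))
  attr(lib, "guides_per_target") <- as.integer(max(table(lib$target_id)))
  lib
}

#' Write / read a guide count TSV
#'
#' `guide_id`, `target_id`, `gene_symbol`, then one column per sample named
#' `arm_repR_roundK`.
#' @param screen An `sgrna_screen` or a count data.frame.
#' @param path File path.
#' @return `path` (write) or a count data.frame (read).
#' @export
write_counts_tsv <- function(screen, path) {
  df <- if (inherits(screen, "sgrna_screen")) screen$counts else screen
  write_tsv(df, path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write an expression cohort to TSV files
#'
#' The expression table is gene x sample with a leading `gene_symbol`
#' column; the metadata table has `sample_id`, `dataset_id` and optional
#' `response`.
#' @param cohort An [expression_cohort()].
#' @param expr_path,meta_path File paths.
#' @return `expr_path`, invisibly.
#' @export
write_expression_tsv <- function(cohort, expr_path, meta_path) {
  expr <- data.frame(gene_symbol = rownames(cohort$values),
                     cohort$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
  write_tsv(expr, expr_path)
  write_tsv(cohort$metadata, meta_path)
  invisible(expr_path)
}

#' Read an expression cohort from TSV files
#' @param expr_path,meta_path Paths written by [write_expression_tsv()].
#' @param scale Stored scale flag, `"log2"` or `"linear"`.
#' @return An [expression_cohort()].
#' @export
read_expression_tsv <- function(expr_path, meta_path,
                                scale = c("log2", "linear")) {
  expr <- read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(expr[, -1, drop = FALSE])
  rownames(vals) <- expr$gene_symbol
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  expression_cohort(vals, meta, scale = match.arg(scale))
}

#' Read / write GMT gene-set collections
#'
#' GMT is tab-separated: set id, description, then member gene symbols.
#' Reading is delegated to [fgsea::gmtPathways()].
#' @param path File path.
#' @param collection Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @return Named list of gene sets (read) or `path` (write).
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  abort_if(is.null(names(collection)), "collection must be named")
  desc <- descriptions %||% rep("na", length(collection))
  lines <- vapply(seq_along(collection), function(i)
    paste(c(names(collection)[i], desc[i], collection[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene list (one symbol per line)
#' @param path File path.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Read peak intervals from a BED file
#'
#' BED is 0-based half-open; import (via [rtracklayer::import()]) converts to
#' the 1-based closed convention used internally.
#' @param path Path to a BED file.
#' @return data.frame with `chrom`, `start`, `end` (1-based closed).
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}
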