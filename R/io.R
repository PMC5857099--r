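## Plain-text IO: TSV matrices and tables, gene lists, BED6 peaks, and a
## minimal gene/exon/CDS GTF. All coordinates are 0-based half-open
## internally; BED is passed through unchanged, GTF is converted on read and
## write (GTF is 1-based closed).

#' Write / read a genes-by-samples matrix as TSV
#'
#' Genes in rows, header row of sample ids, first column `gene`.
#'
#' @param mat numeric matrix with dimnames.
#' @param path file path.
#' @return `read_matrix_tsv` returns the matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  mat
}

#' Write / read a two-column sample-group TSV
#'
#' @param group factor of group labels, named by sample id (or with `samples`
#'   given separately).
#' @param samples sample ids (defaults to `names(group)`).
#' @param path file path.
#' @return `read_groups_tsv` returns a named factor.
#' @export
write_groups_tsv <- function(group, path, samples = names(group)) {
  utils::write.table(data.frame(sample = samples, group = as.character(group)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_groups_tsv
#' @export
read_groups_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(factor(df$group, levels = unique(df$group)), df$sample)
}

#' Read a one-id-per-line gene list
#'
#' @param path file path; blank lines and `#` comments are ignored.
#' @return character vector of ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write / read peaks as BED6
#'
#' Columns chrom, start, end, name, score, strand; 0-based half-open, no
#' header, passed through without coordinate conversion.
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param path file path.
#' @return `read_peaks_bed` returns the peaks data.frame.
#' @export
write_peaks_bed <- function(peaks, path) {
  bed <- data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
                    name = if ("name" %in% names(peaks)) peaks$name else ".",
                    score = if ("score" %in% names(peaks)) peaks$score else 0L,
                    strand = if ("strand" %in% names(peaks)) peaks$strand else ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks_bed
#' @export
read_peaks_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:min(6L, ncol(df))] <-
    c("chrom", "start", "end", "name", "score", "strand")[1:min(6L, ncol(df))]
  df
}

#' Write / read simplified gene models as GTF
#'
#' Only `exon` and `CDS` features are written/kept; attributes carry
#' `transcript_id`. Internal coordinates are 0-based half-open; GTF on disk
#' is 1-based closed. Reading uses rtracklayer when available and falls back
#' to an error otherwise.
#'
#' @param models gene-model data.frame (see [annotate_peak_region()]).
#' @param path file path.
#' @return `read_gene_models_gtf` returns the gene-model data.frame.
#' @export
write_gene_models_gtf <- function(models, path) {
  lines <- sprintf(
    '%s\trbpscreen\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    models$chrom, models$feature, models$start + 1L, models$end,
    models$strand, models$transcript_id, models$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gene_models_gtf
#' @export
read_gene_models_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop_invalid("reading GTF requires the rtracklayer package")
  gr <- as.data.frame(rtracklayer::import(path, format = "gtf"))
  gr <- gr[as.character(gr$type) %in% c("exon", "CDS"), , drop = FALSE]
  data.frame(transcript_id = as.character(gr$transcript_id),
             chrom = as.character(gr$seqnames),
             strand = as.character(gr$strand),
             feature = as.character(gr$type),
             start = gr$start - 1L,
             end = gr$end,
             stringsAsFactors = FALSE)
}

#' Write a target-call summary as JSON
#'
#' @param calls a `target_calls` object from [intersect_targets()].
#' @param path file path.
#' @return the path, invisibly. `pct_of_bound` is rounded to 2 decimals in
#'   the report (full precision is retained in the object).
#' @export
write_target_summary_json <- function(calls, path) {
  stopifnot(inherits(calls, "target_calls"))
  s <- calls$summary
  s$pct_of_bound <- if (is.na(s$pct_of_bound)) NA else
    round(s$pct_of_bound, 2)
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
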