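## Readers/writers for the pipeline's tabular interfaces. Count tables are
## TSV with header contig, pos0, strand, a_count, g_count (0-based positions).

#' Read / write per-site conversion-count tables
#'
#' @param path TSV file with columns contig, pos0, strand, a_count, g_count.
#' @return data.frame of counts.
#' @export
read_counts_tsv <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  assert_columns(df, c("contig", "pos0", "strand", "a_count", "g_count"),
                 "count table")
  df
}

#' @rdname read_counts_tsv
#' @param counts count data.frame.
#' @export
write_counts_tsv <- function(counts, path) {
  assert_columns(counts, c("contig", "pos0", "strand", "a_count", "g_count"),
                 "count table")
  data.table::fwrite(counts[, c("contig", "pos0", "strand", "a_count", "g_count")],
                     path, sep = "\t")
  invisible(path)
}

#' Read / write called-site tables
#'
#' @param path TSV file.
#' @return data.frame of sites.
#' @export
read_sites_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' @rdname read_sites_tsv
#' @param sites called (optionally annotated) site data.frame.
#' @export
write_sites_tsv <- function(sites, path) {
  data.table::fwrite(as.data.frame(sites), path, sep = "\t")
  invisible(path)
}

#' Export called sites as BED6 (score = round(1000 x level)) or bedGraph
#'
#' Both formats are 0-based half-open on output.
#'
#' @param sites called sites (needs contig, pos0, strand, level).
#' @param path output file (`.bed` / `.bedGraph`).
#' @return the path, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = sites$contig,
    ranges = IRanges::IRanges(start = sites$pos0 + 1L, width = 1L),
    strand = sites$strand)
  gr$name <- site_key(sites$contig, sites$pos0, sites$strand)
  gr$score <- as.integer(round(1000 * sites$level))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_sites_bed
#' @export
write_sites_bedgraph <- function(sites, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = sites$contig,
    ranges = IRanges::IRanges(start = sites$pos0 + 1L, width = 1L))
  gr$score <- sites$level
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a transcript-by-sample table (expression counts, TPM, or PDUI)
#'
#' @param path TSV with a `transcript_id` column and one column per sample.
#' @return data.frame with transcript_id and numeric sample columns.
#' @export
read_matrix_tsv <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"), check.names = FALSE)
  assert_columns(df, "transcript_id", "matrix table")
  df
}
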