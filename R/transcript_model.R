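#' Strand-aware transcript models
#'
#' The pipeline represents each (single-exon) transcript by its genomic
#' footprint and its UTR5/CDS/UTR3 segmentation. `transcript_model()`
#' validates a data.frame of models; `read_annotation()` builds one from a
#' GTF or BED12 file. The CDS includes the stop codon; the first base after
#' the CDS belongs to the 3'-UTR.
#'
#' @param df data.frame with columns `transcript_id`, `contig`, `strand`
#'   (`+`/`-`), `start0` (0-based genomic start), `utr5_len`, `cds_len`,
#'   `utr3_len`.
#' @return data.frame of class `glorid_transcript_model` with added
#'   `tx_len` and `end0` (exclusive) columns.
#' @export
transcript_model <- function(df) {
  assert_columns(df, c("transcript_id", "contig", "strand", "start0",
                       "utr5_len", "cds_len", "utr3_len"))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (any(!df$strand %in% c("+", "-")))
    stop_glorid("strand must be '+' or '-'", "glorid_input_error")
  if (any(df$utr5_len <= 0 | df$cds_len <= 0 | df$utr3_len <= 0))
    stop_glorid("region lengths must be positive", "glorid_input_error")
  if (anyDuplicated(df$transcript_id))
    stop_glorid("duplicated transcript_id in model", "glorid_input_error")
  df$tx_len <- df$utr5_len + df$cds_len + df$utr3_len
  df$end0 <- df$start0 + df$tx_len
  class(df) <- c("glorid_transcript_model", "data.frame")
  df
}

## genomic 0-based position -> transcript-orientation offset (0-based);
## arguments recycle against each other
genomic_to_transcript <- function(pos0, strand, start0, end0) {
  n <- max(length(pos0), length(strand), length(start0), length(end0))
  pos0 <- rep_len(pos0, n); strand <- rep_len(strand, n)
  start0 <- rep_len(start0, n); end0 <- rep_len(end0, n)
  out <- pos0 - start0
  m <- strand == "-"
  out[m] <- end0[m] - 1L - pos0[m]
  out
}

transcript_to_genomic <- function(tpos, strand, start0, end0) {
  n <- max(length(tpos), length(strand), length(start0), length(end0))
  tpos <- rep_len(tpos, n); strand <- rep_len(strand, n)
  start0 <- rep_len(start0, n); end0 <- rep_len(end0, n)
  out <- start0 + tpos
  m <- strand == "-"
  out[m] <- end0[m] - 1L - tpos[m]
  out
}

## region of a transcript-orientation offset
region_of_tpos <- function(tpos, utr5_len, cds_len) {
  ifelse(tpos < utr5_len, "UTR5",
         ifelse(tpos < utr5_len + cds_len, "CDS", "UTR3"))
}

model_to_granges <- function(model) {
  GenomicRanges::GRanges(
    seqnames = model$contig,
    ranges = IRanges::IRanges(start = model$start0 + 1L, end = model$end0),
    strand = model$strand,
    transcript_id = model$transcript_id
  )
}

#' Read a transcript annotation (GTF or BED12) into a transcript model
#'
#' GTF input must carry one `exon` and one `CDS` feature per transcript
#' (single-exon models); BED12 input must have a `thick` (CDS) block.
#' GTF coordinates are 1-based inclusive and converted on ingest.
#'
#' @param path annotation file (`.gtf` or `.bed`).
#' @return a [transcript_model()] data.frame.
#' @export
read_annotation <- function(path) {
  fmt <- tolower(tools::file_ext(path))
  gr <- rtracklayer::import(path)
  if (fmt %in% c("gtf", "gff", "gff2")) {
    exons <- gr[gr$type == "exon"]
    cds <- gr[gr$type == "CDS"]
    if (any(duplicated(exons$transcript_id)) || any(duplicated(cds$transcript_id)))
      stop_glorid("multi-exon transcripts are not supported", "glorid_input_error")
    m <- match(exons$transcript_id, cds$transcript_id)
    if (anyNA(m))
      stop_glorid("every transcript needs a CDS feature", "glorid_input_error")
    cds <- cds[m]
    strand <- as.character(BiocGenerics::strand(exons))
    ex_start0 <- BiocGenerics::start(exons) - 1L
    ex_end0 <- BiocGenerics::end(exons)
    cds_start0 <- BiocGenerics::start(cds) - 1L
    cds_end0 <- BiocGenerics::end(cds)
    utr5 <- ifelse(strand == "+", cds_start0 - ex_start0, ex_end0 - cds_end0)
    df <- data.frame(
      transcript_id = exons$transcript_id,
      contig = as.character(GenomicRanges::seqnames(exons)),
      strand = strand,
      start0 = ex_start0,
      utr5_len = utr5,
      cds_len = cds_end0 - cds_start0,
      utr3_len = (ex_end0 - ex_start0) - utr5 - (cds_end0 - cds_start0),
      stringsAsFactors = FALSE
    )
  } else if (fmt == "bed") {
    strand <- as.character(BiocGenerics::strand(gr))
    start0 <- BiocGenerics::start(gr) - 1L
    end0 <- BiocGenerics::end(gr)
    th <- gr$thick
    th_start0 <- BiocGenerics::start(th) - 1L
    th_end0 <- BiocGenerics::end(th)
    utr5 <- ifelse(strand == "+", th_start0 - start0, end0 - th_end0)
    df <- data.frame(
      transcript_id = gr$name,
      contig = as.character(GenomicRanges::seqnames(gr)),
      strand = strand,
      start0 = start0,
      utr5_len = utr5,
      cds_len = th_end0 - th_start0,
      utr3_len = (end0 - start0) - utr5 - (th_end0 - th_start0),
      stringsAsFactors = FALSE
    )
  } else {
    stop_glorid(sprintf("unsupported annotation format: %s", fmt),
                "glorid_input_error")
  }
  transcript_model(df)
}

#' Write a transcript model as GTF (1-based) or BED12 (0-based half-open)
#'
#' @param model a [transcript_model()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_annotation_gtf <- function(model, path) {
  mk <- function(type, s0, e0) GenomicRanges::GRanges(
    seqnames = model$contig,
    ranges = IRanges::IRanges(start = s0 + 1L, end = e0),
    strand = model$strand,
    source = "glorid", type = type,
    phase = if (type == "CDS") 0L else NA_integer_,
    gene_id = model$transcript_id, transcript_id = model$transcript_id
  )
  cds_s0 <- ifelse(model$strand == "+",
                   model$start0 + model$utr5_len,
                   model$start0 + model$utr3_len)
  gr <- c(mk("exon", model$start0, model$end0),
          mk("CDS", cds_s0, cds_s0 + model$cds_len))
  gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname write_annotation_gtf
#' @export
write_annotation_bed12 <- function(model, path) {
  cds_s0 <- ifelse(model$strand == "+",
                   model$start0 + model$utr5_len,
                   model$start0 + model$utr3_len)
  gr <- GenomicRanges::GRanges(
    seqnames = model$contig,
    ranges = IRanges::IRanges(start = model$start0 + 1L, end = model$end0),
    strand = model$strand
  )
  gr$name <- model$transcript_id
  gr$score <- 0L
  gr$thick <- IRanges::IRanges(start = cds_s0 + 1L, end = cds_s0 + model$cds_len)
  gr$blocks <- IRanges::IRangesList(lapply(model$tx_len, function(w)
    IRanges::IRanges(start = 1L, width = w)))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
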