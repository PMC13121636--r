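#' Site-calling thresholds
#'
#' Defaults follow the standard GLORI calling criteria: at least 15 reads of
#' combined A+G coverage, at least 5 unconverted-A reads, and a
#' non-conversion rate (methylation level) of at least 10%. The level
#' boundary is inclusive (`>= 0.10`).
#'
#' @param min_coverage minimum A+G coverage per site.
#' @param min_a_reads minimum unconverted-A reads.
#' @param min_level minimum methylation level (`a / (a + g)`).
#' @return a `glorid_call_thresholds` list.
#' @export
call_thresholds <- function(min_coverage = 15L, min_a_reads = 5L,
                            min_level = 0.10) {
  if (min_coverage < 0 || min_a_reads < 0 || min_level < 0)
    stop_glorid("thresholds must be nonnegative", "glorid_config_error")
  structure(list(min_coverage = min_coverage, min_a_reads = min_a_reads,
                 min_level = min_level),
            class = "glorid_call_thresholds")
}

#' Call m6A sites from a conversion-count table
#'
#' A site is called iff `a_count + g_count >= min_coverage`,
#' `a_count >= min_a_reads` and `a_count / (a_count + g_count) >= min_level`.
#' Output rows are sorted by (contig, pos0, strand).
#'
#' @param counts count data.frame (contig, pos0, strand, a_count, g_count).
#' @param thresholds a [call_thresholds()].
#' @return data.frame of called sites with `coverage` and `level` columns.
#' @export
call_sites <- function(counts, thresholds = call_thresholds()) {
  assert_columns(counts, c("contig", "pos0", "strand", "a_count", "g_count"),
                 "count table")
  if (any(counts$a_count < 0) || any(counts$g_count < 0))
    stop_glorid("negative counts in input", "glorid_input_error")
  cov <- counts$a_count + counts$g_count
  lvl <- ifelse(cov > 0, counts$a_count / cov, NA_real_)
  keep <- cov >= thresholds$min_coverage &
    counts$a_count >= thresholds$min_a_reads &
    !is.na(lvl) & lvl >= thresholds$min_level
  out <- counts[keep, , drop = FALSE]
  out$coverage <- cov[keep]
  out$level <- lvl[keep]
  out <- out[order(out$contig, out$pos0, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Conversion QC from spike-in positions
#'
#' Reports the median per-site A-to-G conversion ratio `g / (a + g)` over
#' spike-in (known-unmethylated) positions and compares it to a pass
#' threshold (default 0.99, the conversion efficiency expected of a
#' successful deamination reaction).
#'
#' @param counts count data.frame for one sample.
#' @param spikein_sites data.frame with contig, pos0, strand of spike-in
#'   positions.
#' @param threshold pass threshold on the median conversion ratio.
#' @param sample_id optional label carried into the result.
#' @return a `glorid_conversion_qc` list: `sample_id`, `n_sites`,
#'   `median_conversion`, `pass`.
#' @export
conversion_qc <- function(counts, spikein_sites, threshold = 0.99,
                          sample_id = NA_character_) {
  assert_columns(counts, c("contig", "pos0", "strand", "a_count", "g_count"),
                 "count table")
  keys <- site_key(counts$contig, counts$pos0, counts$strand)
  want <- site_key(spikein_sites$contig, spikein_sites$pos0,
                   spikein_sites$strand)
  sub <- counts[keys %in% want, , drop = FALSE]
  cov <- sub$a_count + sub$g_count
  sub <- sub[cov > 0, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop_glorid("no spike-in position has coverage; conversion QC impossible",
                "glorid_qc_error")
  conv <- sub$g_count / (sub$a_count + sub$g_count)
  med <- median(conv)
  structure(list(sample_id = sample_id, n_sites = nrow(sub),
                 median_conversion = med, pass = med >= threshold),
            class = "glorid_conversion_qc")
}

#' Intersect per-sample site calls and stratify by detection count
#'
#' Sites are keyed by (contig, pos0, strand); a site absent from any sample
#' (for whatever reason it failed the filters there) is non-shared. For each
#' detection count `k` the stratum summary reports the number of sites and
#' the median (over sites) of the per-site median coverage and level across
#' the samples detecting it.
#'
#' @param call_list named list of called-site data.frames (one per sample).
#' @return list with `shared` (data.frame of keys detected in all samples)
#'   and `strata` (per-`k` summary data.frame).
#' @export
shared_sites <- function(call_list) {
  if (length(call_list) < 1L)
    stop_glorid("need at least one sample", "glorid_input_error")
  dt <- data.table::rbindlist(lapply(call_list, function(df)
    data.table::data.table(contig = df$contig, pos0 = df$pos0,
                           strand = df$strand, coverage = df$coverage,
                           level = df$level)))
  per_site <- dt[, .(n_detected = .N, med_cov = median(coverage),
                     med_level = median(level)),
                 by = .(contig, pos0, strand)]
  n <- length(call_list)
  shared <- as.data.frame(per_site[n_detected == n,
                                   .(contig, pos0, strand)])
  strata <- per_site[, .(n_sites = .N,
                         median_coverage = median(med_cov),
                         median_level = median(med_level)),
                     by = n_detected][order(n_detected)]
  list(shared = shared[order(shared$contig, shared$pos0, shared$strand), ,
                       drop = FALSE],
       strata = as.data.frame(strata))
}

#' Annotate sites with pentamer, motif class, transcript, and region
#'
#' Pentamers are extracted strand-aware (reverse complement for minus-strand
#' sites) with the site adenosine at the center. Sites within 2 nt of a
#' contig edge have no defined pentamer and are dropped with a warning.
#' Sites overlapping no transcript (on the matching strand) are labeled
#' `intergenic` and are excluded by downstream stages.
#'
#' @param sites called sites (contig, pos0, strand, ... columns kept).
#' @param model a [transcript_model()].
#' @param reference a [Biostrings::DNAStringSet] covering all site contigs.
#' @return the input with `pentamer`, `motif_class`, `transcript_id`,
#'   `tpos` and `region` columns added.
#' @export
annotate_sites <- function(sites, model, reference) {
  assert_columns(sites, c("contig", "pos0", "strand"), "site table")
  if (!all(sites$contig %in% names(reference)))
    stop_glorid("reference does not cover all site contigs",
                "glorid_input_error")
  widths <- setNames(Biostrings::width(reference), names(reference))
  w <- widths[sites$contig]
  ok <- sites$pos0 >= 2L & sites$pos0 <= w - 3L
  if (any(!ok)) {
    warning(sprintf("%d site(s) within 2 nt of a contig edge dropped (pentamer undefined)",
                    sum(!ok)))
    sites <- sites[ok, , drop = FALSE]
  }
  if (nrow(sites) == 0L) {
    sites$pentamer <- character(0); sites$motif_class <- character(0)
    sites$transcript_id <- character(0); sites$tpos <- integer(0)
    sites$region <- character(0)
    return(sites)
  }

  seq_chr <- as.character(reference[unique(sites$contig)])
  ## pentamer spans pos0-2 .. pos0+2 (0-based) = pos0-1 .. pos0+3 (1-based)
  pent <- substring(seq_chr[sites$contig], sites$pos0 - 1L, sites$pos0 + 3L)
  minus <- sites$strand == "-"
  pent[minus] <- revcomp(pent[minus])
  sites$pentamer <- pent
  sites$motif_class <- classify_motif(pent, strict = FALSE)

  ## strand-matched transcript overlap; ties broken by transcript_id order
  sites$transcript_id <- NA_character_
  sites$tpos <- NA_integer_
  sites$region <- "intergenic"
  if (nrow(model) > 0) {
    txgr <- model_to_granges(model[order(model$transcript_id), , drop = FALSE])
    sgr <- GenomicRanges::GRanges(
      seqnames = sites$contig,
      ranges = IRanges::IRanges(start = sites$pos0 + 1L, width = 1L),
      strand = sites$strand)
    hits <- GenomicRanges::findOverlaps(sgr, txgr, ignore.strand = FALSE)
    first <- !duplicated(S4Vectors::queryHits(hits))
    qi <- S4Vectors::queryHits(hits)[first]
    ti <- S4Vectors::subjectHits(hits)[first]
    mdl <- model[order(model$transcript_id), , drop = FALSE]
    sites$transcript_id[qi] <- mdl$transcript_id[ti]
    sites$tpos[qi] <- genomic_to_transcript(sites$pos0[qi], sites$strand[qi],
                                            mdl$start0[ti], mdl$end0[ti])
    sites$region[qi] <- region_of_tpos(sites$tpos[qi], mdl$utr5_len[ti],
                                       mdl$cds_len[ti])
  }
  rownames(sites) <- NULL
  sites
}
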