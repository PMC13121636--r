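#' Metagene coordinates of sites on transcripts
#'
#' Maps a transcript-orientation position to the region-normalized metagene
#' scale: 5'-UTR to `[0, 1)`, CDS to `[1, 2)`, 3'-UTR to `[2, 3)`, each
#' region stretched to unit length
#' (`x = region_index + offset_within_region / region_length`).
#'
#' @param sites annotated sites (needs `transcript_id`, `tpos`).
#' @param model a [transcript_model()].
#' @return the input with an `x` column (sites off any transcript raise an
#'   error).
#' @export
metagene_coordinate <- function(sites, model) {
  assert_columns(sites, c("transcript_id", "tpos"), "site table")
  m <- match(sites$transcript_id, model$transcript_id)
  if (anyNA(m) || anyNA(sites$tpos))
    stop_glorid("site not on an annotated transcript", "glorid_input_error")
  tpos <- sites$tpos
  u5 <- model$utr5_len[m]; cd <- model$cds_len[m]; u3 <- model$utr3_len[m]
  if (any(tpos < 0 | tpos >= u5 + cd + u3))
    stop_glorid("site outside its transcript", "glorid_input_error")
  x <- ifelse(tpos < u5, tpos / u5,
              ifelse(tpos < u5 + cd, 1 + (tpos - u5) / cd,
                     2 + (tpos - u5 - cd) / u3))
  sites$x <- x
  sites
}

#' Binned metagene density over [0, 3)
#'
#' Histogram of metagene coordinates normalized so the density integrates
#' to 1 over the metagene axis.
#'
#' @param x metagene coordinates in `[0, 3)` (or a data.frame with an `x`
#'   column).
#' @param n_bins number of equal-width bins (default 90: 30 per region).
#' @return data.frame with `bin_start`, `bin_end`, `count`, `density`.
#' @export
metagene_density <- function(x, n_bins = 90L) {
  if (is.data.frame(x)) x <- x$x
  if (length(x) == 0L)
    stop_glorid("need at least one coordinate", "glorid_input_error")
  edges <- seq(0, 3, length.out = n_bins + 1L)
  bin <- findInterval(x, edges, rightmost.closed = FALSE)
  bin[bin > n_bins] <- n_bins
  counts <- tabulate(bin, n_bins)
  width <- 3 / n_bins
  data.frame(bin_start = edges[-(n_bins + 1L)], bin_end = edges[-1L],
             count = counts, density = counts / (sum(counts) * width))
}

#' Stop-codon-centered profile of differential methylation
#'
#' Offsets each site from the CDS/3'-UTR junction (offset 0 = first 3'-UTR
#' base, offset -1 = last CDS base, i.e. the third base of the stop codon),
#' keeps sites within `window` nt of the junction, and reports per-bin mean
#' methylation difference and site count. Bins tile
#' `[-window, +window)` exactly.
#'
#' @param diff_sites differential sites (needs `transcript_id`, `tpos`,
#'   `delta`).
#' @param model a [transcript_model()].
#' @param window half-width of the window in nt.
#' @param bin_width bin width in nt (must divide `2 * window`).
#' @return data.frame with `bin_start`, `bin_end`, `n`, `mean_delta`
#'   (`NA` for empty bins).
#' @export
stop_codon_profile <- function(diff_sites, model, window = 400L,
                               bin_width = 20L) {
  assert_columns(diff_sites, c("transcript_id", "tpos", "delta"),
                 "differential sites")
  if ((2L * window) %% bin_width != 0L)
    stop_glorid("bin_width must divide 2 * window", "glorid_config_error")
  m <- match(diff_sites$transcript_id, model$transcript_id)
  offset <- diff_sites$tpos - (model$utr5_len[m] + model$cds_len[m])
  keep <- !is.na(offset) & offset >= -window & offset < window
  offset <- offset[keep]
  delta <- diff_sites$delta[keep]
  edges <- seq(-window, window, by = bin_width)
  n_bins <- length(edges) - 1L
  bin <- findInterval(offset, edges, rightmost.closed = FALSE)
  dt <- data.table::data.table(bin = bin, delta = delta)
  agg <- dt[, .(n = .N, mean_delta = mean(delta)), by = bin]
  out <- data.frame(bin_start = edges[-(n_bins + 1L)], bin_end = edges[-1L],
                    n = 0L, mean_delta = NA_real_)
  out$n[agg$bin] <- agg$n
  out$mean_delta[agg$bin] <- agg$mean_delta
  out
}
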