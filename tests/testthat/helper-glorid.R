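# shared fixtures and independent oracles

# small simulation used by several unit tests (fast: short transcripts)
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_transcripts = 30, utr5_len = 50, cds_len = 300, utr3_len = 150,
         stop_window_cds = 30, stop_window_utr3 = 60, hyper_window = 60,
         n_samples_per_group = 3, spikein_coverage_mean = 500),
    list(...))
  do.call(sim_config, args)
}

# hand-built two-transcript model on one contig pair, used for coordinate and
# annotation tests (plus strand and minus strand with known sequence content)
toy_model <- function() {
  transcript_model(data.frame(
    transcript_id = c("TXP", "TXM"),
    contig = c("ctgP", "ctgM"),
    strand = c("+", "-"),
    start0 = c(10L, 10L),
    utr5_len = c(100L, 100L),
    cds_len = c(300L, 300L),
    utr3_len = c(200L, 200L)))
}

# independent motif oracle: class by Hamming distance to the enumerated
# DRACH set (positions 1,2,4,5), not by per-position rule checks
oracle_drach_set <- function() {
  g <- expand.grid(c("A", "G", "T"), c("A", "G"), "A", "C", c("A", "C", "T"),
                   stringsAsFactors = FALSE)
  apply(g, 1, paste, collapse = "")
}

oracle_motif_class <- function(p) {
  drach <- oracle_drach_set()
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  d <- vapply(drach, ham, numeric(1), a = p)
  if (min(d) == 0) return("DRACH")
  if (min(d) >= 2) return("multi_mm")
  # distance 1: is the single mismatch at position 5 for some nearest member?
  nearest <- drach[d == 1]
  at5 <- vapply(nearest, function(m)
    substr(m, 1, 4) == substr(p, 1, 4), logical(1))
  if (any(at5)) "DRACN_1mm" else "nonDRACN_1mm"
}

all_center_a_pentamers <- function() {
  b <- c("A", "C", "G", "T")
  apply(expand.grid(b, b, "A", b, b, stringsAsFactors = FALSE),
        1, paste, collapse = "")
}

# brute-force site filter: the row-by-row oracle for call_sites
brute_force_call <- function(counts, min_coverage = 15, min_a = 5,
                             min_level = 0.10) {
  keep <- logical(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    a <- counts$a_count[i]; g <- counts$g_count[i]
    cov <- a + g
    keep[i] <- cov >= min_coverage && a >= min_a && cov > 0 &&
      (a / cov) >= min_level
  }
  out <- counts[keep, , drop = FALSE]
  out <- out[order(out$contig, out$pos0, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# reference step-up BH procedure (independent of stats::p.adjust)
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# two-sided Fisher p by hypergeometric enumeration
fisher_enum_p <- function(tab) {
  x <- tab[1, 1]; m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- dhyper(x, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
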