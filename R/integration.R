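#' TPM normalization from raw counts
#'
#' Standard transcripts-per-million: per-length read rates rescaled to sum
#' to 1e6 in every sample.
#'
#' @param counts matrix or data.frame of raw counts (transcripts x samples;
#'   a `transcript_id` column is used as rownames if present).
#' @param lengths named numeric vector of transcript effective lengths (nt).
#' @return numeric matrix of TPM values (columns each sum to 1e6).
#' @export
tpm_from_counts <- function(counts, lengths) {
  if (is.data.frame(counts) && "transcript_id" %in% names(counts)) {
    rn <- counts$transcript_id
    counts <- as.matrix(counts[, setdiff(names(counts), "transcript_id"),
                               drop = FALSE])
    rownames(counts) <- rn
  } else {
    counts <- as.matrix(counts)
  }
  len <- lengths[rownames(counts)]
  if (anyNA(len) || any(len <= 0))
    stop_glorid("every transcript needs a positive length", "glorid_input_error")
  rate <- counts / len
  tot <- colSums(rate)
  if (any(tot == 0))
    stop_glorid("a sample has zero total counts; TPM undefined",
                "glorid_input_error")
  sweep(rate, 2, tot, "/") * 1e6
}

#' Flag transcripts failing the expression count filter
#'
#' @param counts counts matrix/data.frame as in [tpm_from_counts()].
#' @param min_count exclusive lower bound; transcripts with any sample count
#'   at or below it are flagged excluded (default: count must exceed 10 in
#'   every sample).
#' @return logical vector, `TRUE` = transcript retained.
#' @export
expression_filter <- function(counts, min_count = 10) {
  if (is.data.frame(counts) && "transcript_id" %in% names(counts)) {
    rn <- counts$transcript_id
    counts <- as.matrix(counts[, setdiff(names(counts), "transcript_id"),
                               drop = FALSE])
    rownames(counts) <- rn
  }
  apply(counts > min_count, 1, all)
}

#' Aggregate site methylation per transcript
#'
#' The transcript aggregate is the **sum** of its called sites' methylation
#' levels (a unitless quantity that can exceed 1). Transcripts are classed
#' `unmethylated` (no called site), `high` (aggregate above
#' `high_cutoff`, default 2) or `low`.
#'
#' @param sites called, DRAC-restricted, annotated sites (needs
#'   `transcript_id`, `level`).
#' @param transcript_ids optional universe of transcripts to report
#'   (transcripts without sites get aggregate 0).
#' @param high_cutoff aggregate boundary of the `high` class (exclusive).
#' @return data.frame: `transcript_id`, `n_sites`, `aggregate_methylation`,
#'   `meth_class`.
#' @export
aggregate_methylation <- function(sites, transcript_ids = NULL,
                                  high_cutoff = 2) {
  assert_columns(sites, c("transcript_id", "level"), "site table")
  sites <- sites[!is.na(sites$transcript_id), , drop = FALSE]
  dt <- data.table::as.data.table(sites)
  agg <- dt[, .(n_sites = .N, aggregate_methylation = sum(level)),
            by = transcript_id]
  if (!is.null(transcript_ids)) {
    base <- data.table::data.table(transcript_id = transcript_ids)
    agg <- merge(base, agg, by = "transcript_id", all.x = TRUE)
    agg[is.na(n_sites), `:=`(n_sites = 0L, aggregate_methylation = 0)]
  }
  agg[, meth_class := ifelse(n_sites == 0L, "unmethylated",
                             ifelse(aggregate_methylation > high_cutoff,
                                    "high", "low"))]
  as.data.frame(agg[order(transcript_id)])
}

#' TPM-weighted global methylation level
#'
#' Per sample, `W = sum_t aggregate(t) * TPM(t) / 1e6`: an
#' expression-weighted mean of transcript aggregate methylation. Because
#' TPM is a relative measure, shifting expression mass toward unmethylated
#' transcripts dilutes W even when no site changes its methylation level.
#' Transcripts present in the TPM table but without called sites
#' contribute aggregate 0. Group means are compared with a two-sided
#' t-test.
#'
#' @param transcript_meth data.frame from [aggregate_methylation()].
#' @param tpm TPM matrix or data.frame (transcripts x samples).
#' @param samples data.frame with `sample_id`, `group`.
#' @return list with `per_sample` (sample, group, W), `group_means`, and
#'   `t_test` (two-sided, or NULL when a group has < 2 samples).
#' @export
weighted_global_methylation <- function(transcript_meth, tpm, samples) {
  if (is.data.frame(tpm) && "transcript_id" %in% names(tpm)) {
    rn <- tpm$transcript_id
    tpm <- as.matrix(tpm[, setdiff(names(tpm), "transcript_id"),
                         drop = FALSE])
    rownames(tpm) <- rn
  }
  agg <- setNames(transcript_meth$aggregate_methylation,
                  transcript_meth$transcript_id)
  if (nrow(transcript_meth) > 0 &&
      !any(rownames(tpm) %in% transcript_meth$transcript_id))
    stop_glorid("no overlap between methylation and expression transcripts",
                "glorid_input_error")
  av <- agg[rownames(tpm)]
  av[is.na(av)] <- 0
  W <- colSums(av * tpm) / 1e6
  per_sample <- data.frame(sample_id = names(W), W = unname(W),
                           stringsAsFactors = FALSE)
  per_sample$group <- samples$group[match(per_sample$sample_id,
                                          samples$sample_id)]
  gm <- tapply(per_sample$W, per_sample$group, mean)
  tt <- NULL
  if (all(table(per_sample$group) >= 2) &&
      length(unique(per_sample$group)) == 2) {
    tt <- t.test(W ~ group, data = per_sample)
  }
  list(per_sample = per_sample, group_means = gm, t_test = tt)
}

#' Cumulative abundance curve and k50
#'
#' Sorts transcripts by descending TPM and reports the cumulative share of
#' the transcriptome, plus `k50`: the smallest number of transcripts whose
#' cumulative share reaches 50% (inclusive).
#'
#' @param tpm nonnegative TPM vector (optionally named).
#' @return list with `curve` (rank, tpm, cum_share) and `k50`.
#' @export
cumulative_abundance <- function(tpm) {
  if (all(tpm == 0) || length(tpm) == 0L)
    stop_glorid("cumulative abundance undefined for all-zero TPM",
                "glorid_input_error")
  ord <- order(tpm, decreasing = TRUE)
  s <- tpm[ord]
  cum <- cumsum(s) / sum(s)
  list(curve = data.frame(rank = seq_along(s), tpm = unname(s),
                          cum_share = unname(cum)),
       k50 = unname(which(cum >= 0.5)[1]))
}

#' Expression shifts stratified by transcript methylation class
#'
#' Computes per-transcript log2 fold changes from mean group TPM with a
#' pseudocount of 1 TPM (or accepts an external table), and summarizes the
#' fold-change distribution per methylation class, both over all
#' transcripts and over the top-`top_k` most abundant (by mean TPM across
#' all samples).
#'
#' @param transcript_meth data.frame from [aggregate_methylation()].
#' @param tpm TPM matrix/data.frame (transcripts x samples).
#' @param samples data.frame with `sample_id`, `group`.
#' @param top_k abundance rank cutoff for the "highly abundant" scope.
#' @param log2fc optional external named vector of log2 fold changes
#'   (B vs A), bypassing the naive TPM ratio.
#' @return data.frame of per-class summaries for scopes `all` and `top_k`.
#' @export
stratified_expression_shift <- function(transcript_meth, tpm, samples,
                                        top_k = 500L, log2fc = NULL) {
  if (is.data.frame(tpm) && "transcript_id" %in% names(tpm)) {
    rn <- tpm$transcript_id
    tpm <- as.matrix(tpm[, setdiff(names(tpm), "transcript_id"),
                         drop = FALSE])
    rownames(tpm) <- rn
  }
  gA <- samples$sample_id[samples$group == "A"]
  gB <- samples$sample_id[samples$group == "B"]
  meanA <- rowMeans(tpm[, gA, drop = FALSE])
  meanB <- rowMeans(tpm[, gB, drop = FALSE])
  if (is.null(log2fc)) {
    log2fc <- log2((meanB + 1) / (meanA + 1))
  } else {
    log2fc <- log2fc[rownames(tpm)]
  }
  cls <- transcript_meth$meth_class[match(rownames(tpm),
                                          transcript_meth$transcript_id)]
  abundance <- rowMeans(tpm)
  top <- rank(-abundance, ties.method = "first") <= top_k

  summarize <- function(idx, scope) {
    dt <- data.table::data.table(class = cls[idx], fc = log2fc[idx])
    dt <- dt[!is.na(class) & !is.na(fc)]
    if (nrow(dt) == 0L) return(NULL)
    out <- dt[, .(n = .N, median_log2fc = median(fc),
                  q1 = unname(quantile(fc, 0.25)),
                  q3 = unname(quantile(fc, 0.75))), by = class]
    out[, scope := scope]
    out
  }
  res <- data.table::rbindlist(list(
    summarize(rep(TRUE, length(log2fc)), "all"),
    summarize(top, "top_k")))
  as.data.frame(res)
}

#' PCA sample coordinates and group silhouette from site-level matrices
#'
#' Centers each site (row) of the level matrix, takes a singular-value
#' decomposition, and reports sample coordinates on the first two
#' components plus the mean silhouette width of the group labeling on
#' those coordinates. A matrix with zero variance yields all-zero
#' coordinates and `NA` silhouette.
#'
#' @param level_matrix sites x samples matrix of methylation levels
#'   (complete cases; use the shared site universe).
#' @param groups group label per sample (column).
#' @return list with `coords` (samples x 2), `var_explained`, `silhouette`.
#' @export
pca_separation <- function(level_matrix, groups) {
  level_matrix <- as.matrix(level_matrix)
  if (ncol(level_matrix) < 3L)
    stop_glorid("PCA needs at least 3 samples", "glorid_input_error")
  x <- level_matrix - rowMeans(level_matrix)
  sv <- svd(x)
  d <- sv$d
  k <- min(2L, length(d))
  coords <- sv$v[, seq_len(k), drop = FALSE] %*% diag(d[seq_len(k)], k)
  if (k < 2L) coords <- cbind(coords, 0)
  rownames(coords) <- colnames(level_matrix)
  colnames(coords) <- c("PC1", "PC2")
  tot <- sum(d^2)
  sil <- NA_real_
  if (tot > 0) {
    coords_use <- coords
    gi <- as.integer(factor(groups))
    if (length(unique(gi)) > 1L) {
      sw <- cluster::silhouette(gi, dist(coords_use))
      sil <- mean(sw[, "sil_width"])
    }
  } else {
    coords[] <- 0
  }
  list(coords = as.data.frame(coords),
       var_explained = if (tot > 0) d^2 / tot else rep(0, length(d)),
       silhouette = sil)
}

#' Alternative-polyadenylation association with m6A status
#'
#' Per transcript, `delta_pdui = mean PDUI(group B) - mean PDUI(group A)`;
#' a two-sided Welch t-test per transcript with Benjamini-Hochberg FDR
#' across transcripts. Transcripts with `delta_pdui < -min_delta` and
#' `fdr < alpha` are `shortened`, with `delta_pdui > min_delta` and
#' `fdr < alpha` `lengthened`, otherwise `none`. The association between
#' 3'-UTR change direction and m6A status is a two-sided Fisher exact test
#' on the shortened/lengthened x methylated/unmethylated table.
#'
#' @param pdui PDUI matrix/data.frame (transcripts x samples, values in
#'   `[0, 1]`).
#' @param samples data.frame with `sample_id`, `group` (>= 2 samples per
#'   group).
#' @param m6a_status named logical vector: transcript is m6A-methylated.
#' @param min_delta class threshold on |delta PDUI| (exclusive).
#' @param alpha FDR cutoff.
#' @return list with `records` (per-transcript table) and `fisher`
#'   (`table`, `p_value`, `odds_ratio`; NULL if a margin is empty).
#' @export
apa_association <- function(pdui, samples, m6a_status,
                            min_delta = 0.1, alpha = 0.05) {
  if (is.data.frame(pdui) && "transcript_id" %in% names(pdui)) {
    rn <- pdui$transcript_id
    pdui <- as.matrix(pdui[, setdiff(names(pdui), "transcript_id"),
                           drop = FALSE])
    rownames(pdui) <- rn
  }
  gA <- samples$sample_id[samples$group == "A"]
  gB <- samples$sample_id[samples$group == "B"]
  if (length(gA) < 2L || length(gB) < 2L)
    stop_glorid("per-transcript PDUI test needs >= 2 samples per group",
                "glorid_input_error")
  mA <- pdui[, gA, drop = FALSE]
  mB <- pdui[, gB, drop = FALSE]
  delta <- rowMeans(mB) - rowMeans(mA)
  pv <- vapply(seq_len(nrow(pdui)), function(i) {
    tryCatch(t.test(mB[i, ], mA[i, ])$p.value,
             error = function(e) NA_real_)  # constant within both groups
  }, numeric(1))
  fdr <- p.adjust(pv, "BH")
  cls <- ifelse(!is.na(fdr) & fdr < alpha & delta < -min_delta, "shortened",
                ifelse(!is.na(fdr) & fdr < alpha & delta > min_delta,
                       "lengthened", "none"))
  status <- m6a_status[rownames(pdui)]
  records <- data.frame(
    transcript_id = rownames(pdui),
    mean_pdui_A = unname(rowMeans(mA)), mean_pdui_B = unname(rowMeans(mB)),
    delta_pdui = unname(delta), p_value = pv, fdr = fdr, class = cls,
    m6a_status = unname(status), stringsAsFactors = FALSE)

  fisher <- NULL
  sel <- records$class %in% c("shortened", "lengthened") &
    !is.na(records$m6a_status)
  if (any(sel)) {
    tab <- table(factor(records$class[sel], c("shortened", "lengthened")),
                 factor(records$m6a_status[sel], c(TRUE, FALSE),
                        labels = c("m6A", "non_m6A")))
    ft <- fisher.test(tab)
    fisher <- list(table = tab, p_value = ft$p.value,
                   odds_ratio = unname(ft$estimate))
  }
  list(records = records, fisher = fisher)
}
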