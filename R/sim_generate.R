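## Synthetic GLORI dataset generator: annotation + reference, planted truth,
## and seeded count/expression/PDUI tables.

DRACH_PENTAMERS <- {
  g <- expand.grid(p1 = c("A", "G", "T"), p2 = c("A", "G"),
                   p3 = "A", p4 = "C", p5 = c("A", "C", "T"),
                   stringsAsFactors = FALSE)
  sort(apply(g, 1, paste, collapse = ""))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## greedy placement of site positions with a minimum pairwise distance of 5 nt
## (pentamers must not overlap)
place_spaced <- function(candidates, n) {
  if (n == 0L || length(candidates) == 0L) return(integer(0))
  cand <- sample(candidates)
  kept <- integer(0)
  for (p in cand) {
    if (length(kept) == n) break
    if (all(abs(kept - p) >= 5L)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Generate a synthetic reference and transcript annotation
#'
#' Builds single-exon transcripts on individual contigs (strands alternate),
#' selects m6A site positions per transcript (a Poisson number per methylated
#' transcript, a configurable fraction placed in a window around the stop
#' codon), writes a DRACH pentamer into the transcript sequence at every
#' selected position, and adds an unmethylated "spikein" contig used for
#' conversion QC. The caller is responsible for seeding the RNG (see
#' [simulate_dataset()]).
#'
#' @param config a [sim_config()].
#' @return an object of class `glorid_sim_annotation`: a list with
#'   `reference` (a [Biostrings::DNAStringSet]), `model` (a
#'   [transcript_model()]), `sites` (planted site positions with pentamers),
#'   and `spikein` (contig name and 0-based adenosine positions).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "glorid_sim_config"))
  n <- config$n_transcripts
  utr5 <- config$utr5_len; cds <- config$cds_len; utr3 <- config$utr3_len
  tx_len <- utr5 + cds + utr3
  pad <- config$pad

  ids <- if (n > 0) sprintf("TX%04d", seq_len(n)) else character(0)
  contigs <- if (n > 0) sprintf("chrS%04d", seq_len(n)) else character(0)
  strands <- rep_len(c("+", "-"), n)

  stop_pos <- utr5 + cds                       # first 3'-UTR base (tpos)
  win <- seq.int(max(2L, stop_pos - config$stop_window_cds),
                 min(tx_len - 3L, stop_pos + config$stop_window_utr3 - 1L))
  all_pos <- seq.int(2L, tx_len - 3L)
  outside <- setdiff(all_pos, win)

  site_list <- vector("list", n)
  seqs <- character(n + 1L)
  for (i in seq_len(n)) {
    tx <- strsplit(random_dna(tx_len), "", fixed = TRUE)[[1]]
    unmeth <- runif(1) < config$unmethylated_fraction
    k <- if (unmeth) 0L else rpois(1L, config$sites_per_transcript_mean)
    k_win <- rbinom(1L, k, config$stop_proximal_fraction)
    pos <- sort(c(place_spaced(win, k_win),
                  place_spaced(outside, k - k_win)))
    ## enforce spacing across the merged window/outside sets
    if (length(pos) > 1L) {
      keep <- pos[1]
      for (p in pos[-1]) if (p - keep[length(keep)] >= 5L) keep <- c(keep, p)
      pos <- keep
    }
    pent <- character(length(pos))
    for (j in seq_along(pos)) {
      pent[j] <- sample(DRACH_PENTAMERS, 1L)
      tx[(pos[j] - 1L):(pos[j] + 3L)] <- strsplit(pent[j], "", fixed = TRUE)[[1]]
    }
    txs <- paste(tx, collapse = "")
    genomic <- if (strands[i] == "+") txs else revcomp(txs)
    seqs[i] <- paste0(random_dna(pad), genomic, random_dna(pad))
    if (length(pos) > 0L) {
      site_list[[i]] <- data.frame(
        transcript_id = ids[i], contig = contigs[i], strand = strands[i],
        tpos = pos, pentamer = pent, stringsAsFactors = FALSE)
    }
  }

  ## spike-in contig: random sequence, fully unmethylated
  spike <- strsplit(random_dna(config$spikein_len), "", fixed = TRUE)[[1]]
  if (!any(spike == "A")) spike[10] <- "A"
  seqs[n + 1L] <- paste(spike, collapse = "")
  spike_pos0 <- which(spike == "A") - 1L
  spike_pos0 <- spike_pos0[spike_pos0 >= 2L & spike_pos0 <= config$spikein_len - 3L]

  reference <- Biostrings::DNAStringSet(setNames(seqs, c(contigs, "spikein")))

  model <- transcript_model(data.frame(
    transcript_id = ids, contig = contigs, strand = strands,
    start0 = rep(pad, n), utr5_len = rep(utr5, n), cds_len = rep(cds, n),
    utr3_len = rep(utr3, n), stringsAsFactors = FALSE))

  sites <- if (length(site_list) > 0) do.call(rbind, site_list) else
    data.frame(transcript_id = character(0), contig = character(0),
               strand = character(0), tpos = integer(0),
               pentamer = character(0), stringsAsFactors = FALSE)
  if (nrow(sites) > 0) {
    m <- match(sites$transcript_id, model$transcript_id)
    sites$pos0 <- transcript_to_genomic(sites$tpos, sites$strand,
                                        model$start0[m], model$end0[m])
    sites$region <- region_of_tpos(sites$tpos, utr5, cds)
    sites$offset_stop <- sites$tpos - stop_pos
  } else {
    sites$pos0 <- integer(0); sites$region <- character(0)
    sites$offset_stop <- integer(0)
  }

  structure(list(reference = reference, model = model, sites = sites,
                 spikein = list(contig = "spikein", positions0 = spike_pos0),
                 config = config),
            class = "glorid_sim_annotation")
}

#' Plant ground-truth methylation, expression, and PDUI effects
#'
#' Baseline site levels are drawn from the two-component Beta mixture
#' (peaks near 20% and 95%). A configured fraction of stop-proximal 3'-UTR
#' sites is planted hypermethylated in group B (+`hyper_delta`, applied to a
#' low-methylation baseline so the full effect is observable before
#' clipping); a configured fraction of the remaining sites is planted
#' hypomethylated (high baseline, -`hyper_delta`). Transcript abundance in
#' group B is shifted by the dilution scheme (unmethylated up, highly
#' methylated down) and renormalized; methylated transcripts get a PDUI
#' decrease of `pdui_effect` in group B.
#'
#' @param annotation a [generate_annotation()] result.
#' @param config the same [sim_config()].
#' @return an object of class `glorid_sim_truth`: list with `sites`
#'   (per-site true levels per group and planted class), `transcripts`
#'   (true TPM per group, methylation class, true PDUI per group) and
#'   `spikein_sites`.
#' @export
plant_truth <- function(annotation, config) {
  stopifnot(inherits(annotation, "glorid_sim_annotation"))
  sites <- annotation$sites
  mx <- config$meth_mixture
  ns <- nrow(sites)

  draw_mix <- function(n, which = NULL) {
    hi <- if (is.null(which)) runif(n) < mx$weight_high else rep(which == "high", n)
    m <- ifelse(hi, mx$mean_high, mx$mean_low)
    conc <- ifelse(hi, mx$conc_high, mx$conc_low)
    rbeta(n, m * conc, (1 - m) * conc)
  }

  base <- draw_mix(ns)
  hyper_eligible <- sites$region == "UTR3" &
    sites$offset_stop >= 0L & sites$offset_stop < config$hyper_window
  is_hyper <- hyper_eligible & (runif(ns) < config$hyper_fraction_3utr)
  is_hypo <- !hyper_eligible & (runif(ns) < config$hypo_fraction)
  ## effects are planted on baselines that leave room for the full delta
  base[is_hyper] <- draw_mix(sum(is_hyper), which = "low")
  base[is_hypo] <- draw_mix(sum(is_hypo), which = "high")

  delta <- numeric(ns)
  delta[is_hyper] <- config$hyper_delta
  delta[is_hypo] <- -config$hyper_delta
  sites$base_level <- base
  sites$level_A <- clip01(base)
  sites$level_B <- clip01(base + delta)
  sites$planted_class <- ifelse(is_hyper, "hyper",
                                ifelse(is_hypo, "hypo", "unchanged"))

  model <- annotation$model
  nt <- nrow(model)
  agg <- setNames(numeric(nt), model$transcript_id)
  if (ns > 0) {
    s <- tapply(sites$level_A, sites$transcript_id, sum)
    agg[names(s)] <- s
  }
  n_sites <- setNames(integer(nt), model$transcript_id)
  if (ns > 0) {
    cnt <- table(sites$transcript_id)
    n_sites[names(cnt)] <- as.integer(cnt)
  }
  meth_class <- ifelse(n_sites == 0L, "unmethylated",
                       ifelse(agg > 2, "high", "low"))

  w <- rlnorm(nt, 0, config$tpm_lnorm_sigma)
  tpm_A <- if (nt > 0) 1e6 * w / sum(w) else numeric(0)
  wB <- w * unname(config$dilution_scheme[meth_class])
  tpm_B <- if (nt > 0) 1e6 * wB / sum(wB) else numeric(0)

  pdui_A <- runif(nt, 0.4, 0.9)
  bg <- (runif(nt) < config$apa_background_fraction) *
    sample(c(-1, 1), nt, replace = TRUE)
  pdui_B <- clip01(pdui_A - config$pdui_effect * (n_sites > 0) +
                     config$pdui_effect * bg)

  transcripts <- data.frame(
    transcript_id = model$transcript_id, length = model$tx_len,
    n_sites = as.integer(n_sites), agg_level_A = unname(agg),
    meth_class = meth_class, tpm_A = tpm_A, tpm_B = tpm_B,
    pdui_A = pdui_A, pdui_B = pdui_B, stringsAsFactors = FALSE)

  spikein_sites <- data.frame(
    contig = annotation$spikein$contig,
    pos0 = annotation$spikein$positions0,
    strand = "+", level = 0, stringsAsFactors = FALSE)

  structure(list(sites = sites, transcripts = transcripts,
                 spikein_sites = spikein_sites, config = config),
            class = "glorid_sim_truth")
}

## all adenosine positions of a transcript in transcript orientation
transcript_a_positions <- function(reference, model_row) {
  gseq <- as.character(Biostrings::subseq(
    reference[[model_row$contig]],
    start = model_row$start0 + 1L, end = model_row$end0))
  tx <- if (model_row$strand == "+") gseq else revcomp(gseq)
  which(strsplit(tx, "", fixed = TRUE)[[1]] == "A") - 1L
}

#' Simulate per-sample count, expression, and PDUI tables
#'
#' Emits one conversion-count row per adenosine position per sample:
#' coverage is negative-binomial with mean proportional to the transcript's
#' group TPM, and the unconverted-A count is binomial with
#' `p_obs = m + (1 - m) * (1 - conversion_rate)` where `m` is the true
#' methylation level (0 outside planted sites and on the spike-in).
#' Expression counts are negative-binomial with mean proportional to
#' TPM x length; the TPM table is recomputed from the simulated counts so
#' the two tables are consistent. Observed PDUI adds Gaussian noise to the
#' true PDUI, clipped to `[0, 1]`.
#'
#' @param truth a [plant_truth()] result.
#' @param annotation the matching [generate_annotation()] result.
#' @param config the same [sim_config()].
#' @return list with `samples` (sample/group table), `counts` (named list of
#'   per-sample data.frames: contig, pos0, strand, a_count, g_count),
#'   `expression` (counts), `tpm`, `pdui`, and `lengths`.
#' @export
simulate_counts <- function(truth, annotation, config) {
  stopifnot(inherits(truth, "glorid_sim_truth"))
  model <- annotation$model
  nspg <- config$n_samples_per_group
  samples <- data.frame(
    sample_id = c(sprintf("A%d", seq_len(nspg)), sprintf("B%d", seq_len(nspg))),
    group = rep(c("A", "B"), each = nspg), stringsAsFactors = FALSE)

  ## site-level emission frame: every transcript A position + spike-in
  pos_list <- vector("list", nrow(model) + 1L)
  for (i in seq_len(nrow(model))) {
    row <- model[i, ]
    tp <- transcript_a_positions(annotation$reference, row)
    pos_list[[i]] <- data.frame(
      transcript_id = row$transcript_id, contig = row$contig,
      strand = row$strand, tpos = tp,
      pos0 = transcript_to_genomic(tp, row$strand, row$start0, row$end0),
      stringsAsFactors = FALSE)
  }
  pos_list[[nrow(model) + 1L]] <- data.frame(
    transcript_id = NA_character_, contig = annotation$spikein$contig,
    strand = "+", tpos = NA_integer_,
    pos0 = annotation$spikein$positions0, stringsAsFactors = FALSE)
  emit <- data.table::rbindlist(pos_list)

  ## true levels per group at each emitted position
  tr <- truth$sites
  key_emit <- site_key(emit$contig, emit$pos0, emit$strand)
  mA <- mB <- numeric(nrow(emit))
  if (nrow(tr) > 0) {
    m <- match(site_key(tr$contig, tr$pos0, tr$strand), key_emit)
    mA[m] <- tr$level_A
    mB[m] <- tr$level_B
  }

  tx <- truth$transcripts
  idx <- match(emit$transcript_id, tx$transcript_id)
  mu_A <- ifelse(is.na(idx), config$spikein_coverage_mean,
                 config$coverage_mean_per_tpm * tx$tpm_A[idx])
  mu_B <- ifelse(is.na(idx), config$spikein_coverage_mean,
                 config$coverage_mean_per_tpm * tx$tpm_B[idx])
  eps <- 1 - config$conversion_rate

  counts <- vector("list", nrow(samples))
  names(counts) <- samples$sample_id
  for (s in seq_len(nrow(samples))) {
    grB <- samples$group[s] == "B"
    mu <- if (grB) mu_B else mu_A
    m <- if (grB) mB else mA
    cov <- rnbinom(nrow(emit), mu = mu, size = config$coverage_dispersion)
    p_obs <- m + (1 - m) * eps
    a <- rbinom(nrow(emit), cov, p_obs)
    df <- data.frame(contig = emit$contig, pos0 = emit$pos0,
                     strand = emit$strand, a_count = a, g_count = cov - a,
                     stringsAsFactors = FALSE)
    counts[[s]] <- df[order(df$contig, df$pos0, df$strand), , drop = FALSE]
    rownames(counts[[s]]) <- NULL
  }

  ## expression counts: mean proportional to TPM x length
  nt <- nrow(tx)
  expr <- matrix(0L, nrow = nt, ncol = nrow(samples),
                 dimnames = list(tx$transcript_id, samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    tpm_g <- if (samples$group[s] == "B") tx$tpm_B else tx$tpm_A
    share <- tpm_g * tx$length
    mu <- if (sum(share) > 0) config$lib_size * share / sum(share) else share
    expr[, s] <- rnbinom(nt, mu = mu, size = config$expr_dispersion)
  }
  expression <- data.frame(transcript_id = tx$transcript_id, expr,
                           stringsAsFactors = FALSE, check.names = FALSE)
  lengths <- setNames(tx$length, tx$transcript_id)
  tpm <- if (nt > 0) {
    tpm_mat <- tpm_from_counts(expr + 0, lengths)
    data.frame(transcript_id = tx$transcript_id, tpm_mat,
               stringsAsFactors = FALSE, check.names = FALSE)
  } else expression

  pd <- matrix(0, nrow = nt, ncol = nrow(samples),
               dimnames = list(tx$transcript_id, samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    true_pd <- if (samples$group[s] == "B") tx$pdui_B else tx$pdui_A
    pd[, s] <- clip01(true_pd + rnorm(nt, 0, config$pdui_noise_sd))
  }
  pdui <- data.frame(transcript_id = tx$transcript_id, pd,
                     stringsAsFactors = FALSE, check.names = FALSE)

  list(samples = samples, counts = counts, expression = expression,
       tpm = tpm, pdui = pdui, lengths = lengths)
}

#' Generate a complete synthetic dataset and write it to disk
#'
#' Seeds the RNG once and runs [generate_annotation()], [plant_truth()] and
#' [simulate_counts()]; identical configuration and seed give byte-identical
#' files. Writes `reference.fa`, `annotation.gtf`, `annotation.bed12`,
#' `counts_<sample>.tsv`, `expression.tsv`, `tpm.tsv`, `pdui.tsv`,
#' `samples.tsv` and `truth.json` under `outdir`.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed); `NULL` keeps
#'   everything in memory.
#' @param seed integer seed (defaults to `config$rng_seed`).
#' @return invisibly, a list with `annotation`, `truth`, `data` and `paths`.
#' @export
simulate_dataset <- function(config = sim_config(), outdir = NULL,
                             seed = config$rng_seed) {
  set.seed(as.integer(seed))
  annotation <- generate_annotation(config)
  truth <- plant_truth(annotation, config)
  data <- simulate_counts(truth, annotation, config)

  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    Biostrings::writeXStringSet(annotation$reference, p("reference.fa"))
    write_annotation_gtf(annotation$model, p("annotation.gtf"))
    write_annotation_bed12(annotation$model, p("annotation.bed12"))
    for (s in names(data$counts))
      write_counts_tsv(data$counts[[s]], p(sprintf("counts_%s.tsv", s)))
    data.table::fwrite(data$expression, p("expression.tsv"), sep = "\t")
    data.table::fwrite(data$tpm, p("tpm.tsv"), sep = "\t")
    data.table::fwrite(data$pdui, p("pdui.tsv"), sep = "\t")
    data.table::fwrite(data$samples, p("samples.tsv"), sep = "\t")
    jsonlite::write_json(
      list(sites = truth$sites, transcripts = truth$transcripts,
           spikein_sites = truth$spikein_sites),
      p("truth.json"), auto_unbox = TRUE, digits = NA)
    paths <- setNames(file.path(outdir, list.files(outdir)), NULL)
  }
  invisible(list(annotation = annotation, truth = truth, data = data,
                 paths = paths))
}
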