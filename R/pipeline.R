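#' Pipeline run configuration
#'
#' Assembles all stage parameters with defaults mirroring the standard
#' analysis: calling thresholds 15/5/0.10, differential thresholds
#' |delta| >= 0.10 at p < 0.05 with a per-sample coverage floor of 15,
#' conversion QC threshold 0.99, transcript high-methylation boundary at
#' aggregate > 2, abundance scope top 500 transcripts, APA thresholds
#' |delta PDUI| > 0.1 at FDR < 0.05, metagene with 90 bins and a
#' +/-400 nt / 20 nt stop-codon profile. In simulation mode (`simulate =
#' TRUE`) the input data are generated by [simulate_dataset()] from
#' `sim`; otherwise `inputs` must point to existing files.
#'
#' @param simulate generate inputs with the synthetic module.
#' @param sim a [sim_config()] (simulation mode).
#' @param inputs named list of file paths (file mode): `counts` (named by
#'   sample), `reference`, `annotation`, `expression`, `tpm`, `pdui`
#'   (optional), `spikein_sites` (optional TSV: contig, pos0, strand).
#' @param groups named character vector sample -> "A"/"B" (file mode).
#' @param call,diff,apa,positional,integration stage parameter lists;
#'   given entries override the defaults.
#' @param qc_threshold conversion QC pass threshold.
#' @param seed integer seed for simulation mode.
#' @return a `glorid_run_config` list.
#' @export
run_config <- function(simulate = TRUE, sim = sim_config(), inputs = list(),
                       groups = NULL,
                       call = list(), diff = list(), apa = list(),
                       positional = list(), integration = list(),
                       qc_threshold = 0.99, seed = 1L) {
  cfg <- list(
    simulate = simulate, sim = sim, inputs = inputs, groups = groups,
    call = utils::modifyList(
      list(min_coverage = 15L, min_a_reads = 5L, min_level = 0.10), call),
    diff = utils::modifyList(
      list(min_delta = 0.10, alpha = 0.05, min_coverage_per_sample = 15L),
      diff),
    apa = utils::modifyList(list(min_delta = 0.1, alpha = 0.05), apa),
    positional = utils::modifyList(
      list(n_bins = 90L, window = 400L, bin_width = 20L), positional),
    integration = utils::modifyList(
      list(high_cutoff = 2, top_k = 500L), integration),
    qc_threshold = qc_threshold, seed = seed)
  class(cfg) <- "glorid_run_config"
  validate_run_config(cfg)
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `sim` entries override the
#' [sim_config()] defaults.
#'
#' @param path YAML file.
#' @return a `glorid_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, y$sim %||% list())
  groups <- if (!is.null(y$groups)) unlist(y$groups) else NULL
  run_config(simulate = y$simulate %||% TRUE, sim = sim,
             inputs = y$inputs %||% list(), groups = groups,
             call = y$call %||% list(), diff = y$diff %||% list(),
             apa = y$apa %||% list(),
             positional = y$positional %||% list(),
             integration = y$integration %||% list(),
             qc_threshold = y$qc_threshold %||% 0.99,
             seed = y$seed %||% 1L)
}

validate_run_config <- function(cfg) {
  if (!cfg$simulate) {
    req <- c("counts", "reference", "annotation", "expression")
    missing <- setdiff(req, names(cfg$inputs))
    if (length(missing) > 0)
      stop_glorid(sprintf("file mode needs inputs: %s",
                          paste(missing, collapse = ", ")),
                  "glorid_config_error")
    samples <- names(cfg$inputs$counts)
    if (is.null(cfg$groups) || !all(samples %in% names(cfg$groups)))
      stop_glorid("every sample needs a group assignment", "glorid_config_error")
    if (!all(cfg$groups %in% c("A", "B")))
      stop_glorid("groups must be 'A' or 'B'", "glorid_config_error")
  }
  with(cfg$call, {
    if (min_coverage < 0 || min_a_reads < 0 || min_level < 0 || min_level > 1)
      stop_glorid("invalid calling thresholds", "glorid_config_error")
  })
  if (cfg$diff$alpha <= 0 || cfg$diff$alpha >= 1)
    stop_glorid("diff alpha must lie in (0, 1)", "glorid_config_error")
  invisible(cfg)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full m6A comparison pipeline
#'
#' Executes simulate/ingest -> conversion QC -> site calling -> shared-site
#' intersection -> motif classification and DRAC restriction ->
#' beta-binomial differential methylation -> transcript aggregation, the
#' TPM-weighted global methylation statistic, abundance stratification and
#' PCA -> metagene and stop-codon profiles -> APA association, writing all
#' stage outputs plus a `report.json` summary under `outdir`. Identical
#' configuration and seed produce byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param outdir output directory.
#' @return invisibly, a list with all stage results and `report`.
#' @export
run_pipeline <- function(config = run_config(), outdir) {
  validate_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)

  ## ---- inputs ----
  if (config$simulate) {
    simdir <- p("sim")
    ds <- stage("simulate", simulate_dataset(config$sim, outdir = simdir,
                                             seed = config$seed))
    counts <- ds$data$counts
    samples <- ds$data$samples
    reference <- ds$annotation$reference
    model <- ds$annotation$model
    expression <- ds$data$expression
    tpm <- ds$data$tpm
    pdui <- ds$data$pdui
    lengths <- ds$data$lengths
    spikein_sites <- data.frame(contig = ds$annotation$spikein$contig,
                                pos0 = ds$annotation$spikein$positions0,
                                strand = "+", stringsAsFactors = FALSE)
  } else {
    ds <- NULL
    counts <- stage("ingest", lapply(config$inputs$counts, read_counts_tsv))
    samples <- data.frame(sample_id = names(counts),
                          group = unname(config$groups[names(counts)]),
                          stringsAsFactors = FALSE)
    reference <- stage("ingest", Biostrings::readDNAStringSet(config$inputs$reference))
    names(reference) <- sub("\\s.*$", "", names(reference))
    model <- stage("ingest", read_annotation(config$inputs$annotation))
    expression <- stage("ingest", read_matrix_tsv(config$inputs$expression))
    lengths <- setNames(model$tx_len, model$transcript_id)
    tpm <- if (!is.null(config$inputs$tpm))
      stage("ingest", read_matrix_tsv(config$inputs$tpm))
    else data.frame(transcript_id = expression$transcript_id,
                    tpm_from_counts(expression, lengths),
                    check.names = FALSE, stringsAsFactors = FALSE)
    pdui <- if (!is.null(config$inputs$pdui))
      stage("ingest", read_matrix_tsv(config$inputs$pdui)) else NULL
    spikein_sites <- if (!is.null(config$inputs$spikein_sites))
      as.data.frame(data.table::fread(config$inputs$spikein_sites)) else NULL
  }

  ## ---- conversion QC ----
  qc <- NULL
  if (!is.null(spikein_sites)) {
    qc <- stage("conversion_qc", lapply(samples$sample_id, function(s)
      conversion_qc(counts[[s]], spikein_sites,
                    threshold = config$qc_threshold, sample_id = s)))
    names(qc) <- samples$sample_id
    jsonlite::write_json(lapply(qc, unclass), p("qc.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  ## ---- site calling ----
  thr <- do.call(call_thresholds, config$call)
  calls <- stage("call_sites", lapply(counts, call_sites, thresholds = thr))
  for (s in names(calls))
    write_sites_tsv(calls[[s]], p(sprintf("sites_%s.tsv", s)))
  sh <- stage("shared_sites", shared_sites(calls))
  data.table::fwrite(sh$strata, p("shared_strata.tsv"), sep = "\t")

  ## consensus site table: union of per-sample calls, mean level/coverage
  ## over the samples detecting each site
  union_dt <- data.table::rbindlist(lapply(calls, function(df)
    data.table::data.table(contig = df$contig, pos0 = df$pos0,
                           strand = df$strand, coverage = df$coverage,
                           level = df$level)))
  consensus <- as.data.frame(union_dt[, .(
    n_detected = .N, coverage = mean(coverage), level = mean(level)),
    by = .(contig, pos0, strand)])
  consensus <- stage("annotate_sites",
                     annotate_sites(consensus, model, reference))
  write_sites_tsv(consensus, p("sites.tsv"))
  write_sites_bed(consensus, p("sites.bed"))
  write_sites_bedgraph(consensus, p("sites.bedGraph"))

  ## ---- motif ----
  msum <- stage("motif", motif_summary(consensus))
  data.table::fwrite(msum$frequencies, p("motif_summary.tsv"), sep = "\t")
  if (length(msum$pfm) > 0)
    data.table::fwrite(as.data.frame(msum$pfm), p("position_frequency_matrix.tsv"),
                       sep = "\t")
  class_counts <- table(factor(consensus$motif_class,
                               c("DRACH", "DRACN_1mm", "nonDRACN_1mm",
                                 "multi_mm")))
  jsonlite::write_json(as.list(class_counts), p("class_counts.json"),
                       auto_unbox = TRUE)
  drac <- restrict_to_drac(consensus)
  drac <- drac[drac$region != "intergenic", , drop = FALSE]

  ## ---- differential methylation ----
  universe <- stage("test_universe", build_test_universe(
    counts, model, reference,
    min_coverage_per_sample = config$diff$min_coverage_per_sample))
  sdrep <- stage("sd_report", sd_threshold_report(universe, samples))
  jsonlite::write_json(sdrep$summary, p("sd_report.json"),
                       auto_unbox = TRUE, digits = NA)
  dthr <- do.call(diff_thresholds, config$diff)
  diff <- stage("diff_methylation", diff_methylation(universe, samples))
  cls <- classify_differential(diff, dthr)
  write_sites_tsv(cls$sites, p("diff_sites.tsv"))
  txcls <- classify_transcripts(cls$sites)
  data.table::fwrite(txcls, p("transcript_classes.tsv"), sep = "\t")

  ## ---- integration ----
  tm <- stage("aggregate", aggregate_methylation(
    drac, transcript_ids = model$transcript_id,
    high_cutoff = config$integration$high_cutoff))
  data.table::fwrite(tm, p("transcript_methylation.tsv"), sep = "\t")
  W <- stage("weighted_methylation",
             weighted_global_methylation(tm, tpm, samples))
  data.table::fwrite(W$per_sample[, c("sample_id", "group", "W")],
                     p("weighted_methylation.tsv"), sep = "\t")
  tpm_mat <- as.matrix(tpm[, setdiff(names(tpm), "transcript_id"),
                           drop = FALSE])
  rownames(tpm_mat) <- tpm$transcript_id
  k50 <- stage("cumulative_abundance", list(
    A = cumulative_abundance(rowMeans(
      tpm_mat[, samples$sample_id[samples$group == "A"], drop = FALSE]))$k50,
    B = cumulative_abundance(rowMeans(
      tpm_mat[, samples$sample_id[samples$group == "B"], drop = FALSE]))$k50))
  strat <- stage("stratified_fc", stratified_expression_shift(
    tm, tpm, samples, top_k = config$integration$top_k))
  data.table::fwrite(strat, p("stratified_fc.tsv"), sep = "\t")

  ## PCA on differential sites (levels from the test universe counts)
  pca <- NULL
  dsites <- cls$sites[cls$sites$direction != "none", , drop = FALSE]
  if (nrow(dsites) >= 1L) {
    ucnt <- data.table::as.data.table(universe$counts)
    ucnt[, key := site_key(contig, pos0, strand)]
    dkeys <- site_key(dsites$contig, dsites$pos0, dsites$strand)
    sub <- ucnt[key %in% dkeys]
    lvl <- data.table::dcast(sub, key ~ sample_id,
                             value.var = c("a_count", "coverage"))
    amat <- as.matrix(lvl[, paste0("a_count_", samples$sample_id),
                          with = FALSE])
    nmat <- as.matrix(lvl[, paste0("coverage_", samples$sample_id),
                          with = FALSE])
    lmat <- amat / nmat
    colnames(lmat) <- samples$sample_id
    pca <- stage("pca", pca_separation(lmat, samples$group))
    pc <- data.frame(sample_id = rownames(pca$coords), pca$coords,
                     group = samples$group, stringsAsFactors = FALSE)
    data.table::fwrite(pc, p("pca.tsv"), sep = "\t")
  }

  ## ---- positional ----
  mg_sites <- drac[!is.na(drac$tpos), , drop = FALSE]
  metagene <- NULL
  if (nrow(mg_sites) > 0) {
    mg <- stage("metagene", metagene_coordinate(mg_sites, model))
    metagene <- metagene_density(mg, n_bins = config$positional$n_bins)
    data.table::fwrite(metagene, p("metagene.tsv"), sep = "\t")
  }
  stopprof <- NULL
  if (nrow(dsites) > 0) {
    stopprof <- stage("stop_profile", stop_codon_profile(
      dsites, model, window = config$positional$window,
      bin_width = config$positional$bin_width))
    data.table::fwrite(stopprof, p("stop_profile.tsv"), sep = "\t")
  }

  ## ---- APA ----
  apa <- NULL
  if (!is.null(pdui) && nrow(pdui) > 0) {
    m6a_status <- setNames(tm$n_sites > 0, tm$transcript_id)
    apa <- stage("apa", apa_association(
      pdui, samples, m6a_status,
      min_delta = config$apa$min_delta, alpha = config$apa$alpha))
    data.table::fwrite(apa$records, p("apa.tsv"), sep = "\t")
  }

  ## ---- report ----
  report <- list(
    n_samples = nrow(samples),
    qc = if (!is.null(qc)) lapply(qc, function(q)
      list(median_conversion = q$median_conversion, pass = q$pass)),
    n_called_per_sample = vapply(calls, nrow, integer(1)),
    n_shared = nrow(sh$shared),
    n_consensus = nrow(consensus),
    motif_class_counts = as.list(class_counts),
    n_drac = nrow(drac),
    n_universe = nrow(universe$sites),
    n_hyper = nrow(cls$hyper),
    n_hypo = nrow(cls$hypo),
    transcript_classes = as.list(table(factor(
      txcls$class, c("hyper", "hypo", "both", "unchanged")))),
    W = setNames(as.list(W$per_sample$W), W$per_sample$sample_id),
    W_group_means = as.list(W$group_means),
    W_t_test_p = if (!is.null(W$t_test)) W$t_test$p.value,
    k50 = k50,
    pca_silhouette = if (!is.null(pca)) pca$silhouette,
    apa_fisher_p = if (!is.null(apa) && !is.null(apa$fisher))
      apa$fisher$p_value,
    thresholds = list(call = config$call, diff = config$diff,
                      apa = config$apa,
                      high_cutoff = config$integration$high_cutoff,
                      qc_threshold = config$qc_threshold),
    seed = config$seed)
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")

  invisible(list(samples = samples, qc = qc, counts = counts, calls = calls,
                 shared = sh,
                 consensus = consensus, motif = msum, universe = universe,
                 sd_report = sdrep, diff = cls, transcript_classes = txcls,
                 transcript_meth = tm, weighted = W, k50 = k50,
                 stratified = strat, pca = pca, metagene = metagene,
                 stop_profile = stopprof, apa = apa, report = report,
                 truth = if (!is.null(ds)) ds$truth, model = model,
                 reference = reference))
}
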