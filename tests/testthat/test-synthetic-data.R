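test_that("generated transcripts have the configured architecture on both strands", {
  set.seed(1)
  cfg <- sim_config(n_transcripts = 10, utr5_len = 200, cds_len = 900,
                    utr3_len = 600, n_samples_per_group = 2)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann$model), 10)
  expect_true(all(ann$model$tx_len == 1700))
  expect_setequal(unique(ann$model$strand), c("+", "-"))
  # contigs include padding on both sides
  expect_true(all(Biostrings::width(ann$reference[ann$model$contig]) ==
                    1700 + 2 * cfg$pad))
})

test_that("every planted site carries a DRACH pentamer in transcript orientation", {
  set.seed(2)
  ann <- generate_annotation(tiny_config())
  drach <- oracle_drach_set()
  expect_gt(nrow(ann$sites), 0)
  expect_true(all(ann$sites$pentamer %in% drach))
  # check against the genomic sequence, strand-aware
  for (i in seq_len(nrow(ann$sites))) {
    s <- ann$sites[i, ]
    gseq <- substr(as.character(ann$reference[[s$contig]]),
                   s$pos0 - 1, s$pos0 + 3)
    expect_identical(if (s$strand == "+") gseq else revcomp(gseq),
                     s$pentamer)
  }
  # spacing: no two sites of a transcript have overlapping pentamers
  by_tx <- split(ann$sites$tpos, ann$sites$transcript_id)
  expect_true(all(vapply(by_tx, function(p)
    length(p) < 2 || all(diff(sort(p)) >= 5), logical(1))))
})

test_that("zero transcripts yield an empty annotation without error", {
  set.seed(3)
  ann <- generate_annotation(sim_config(n_transcripts = 0))
  expect_equal(nrow(ann$model), 0)
  expect_equal(nrow(ann$sites), 0)
  expect_true("spikein" %in% names(ann$reference))
})

test_that("invalid architecture is rejected at configuration time", {
  expect_error(sim_config(cds_len = 901), class = "glorid_config_error")
  expect_error(sim_config(conversion_rate = 0.5), class = "glorid_config_error")
  expect_error(sim_config(hyper_fraction_3utr = 1.5),
               class = "glorid_config_error")
})

test_that("without planted effects the two group truths are identical", {
  set.seed(4)
  cfg <- tiny_config(hyper_fraction_3utr = 0, hypo_fraction = 0)
  tr <- plant_truth(generate_annotation(cfg), cfg)
  expect_equal(tr$sites$level_A, tr$sites$level_B)
  expect_true(all(tr$sites$planted_class == "unchanged"))
})

test_that("planted levels are clipped to [0, 1] and effects have the planted sign", {
  set.seed(5)
  cfg <- tiny_config(hyper_fraction_3utr = 1, hypo_fraction = 0.3,
                     hyper_delta = 0.9)
  tr <- plant_truth(generate_annotation(cfg), cfg)
  s <- tr$sites
  expect_true(all(s$level_A >= 0 & s$level_A <= 1))
  expect_true(all(s$level_B >= 0 & s$level_B <= 1))
  hyper <- s[s$planted_class == "hyper", ]
  expect_gt(nrow(hyper), 0)
  # baseline 0.9 + delta 0.9 saturates at 1 (clipping)
  expect_true(all(hyper$level_B == pmin(1, hyper$base_level + 0.9)))
  expect_true(all(hyper$level_B >= hyper$level_A))
  hypo <- s[s$planted_class == "hypo", ]
  expect_true(all(hypo$level_B <= hypo$level_A))
})

test_that("hyper sites sit in the stop-proximal 3'-UTR window", {
  set.seed(6)
  cfg <- tiny_config(hyper_fraction_3utr = 1)
  tr <- plant_truth(generate_annotation(cfg), cfg)
  hyper <- tr$sites[tr$sites$planted_class == "hyper", ]
  expect_gt(nrow(hyper), 0)
  expect_true(all(hyper$region == "UTR3"))
  expect_true(all(hyper$offset_stop >= 0 & hyper$offset_stop < cfg$hyper_window))
})

test_that("baseline mixture: fraction of sites above 0.5 matches the high-component weight", {
  set.seed(7)
  # many short transcripts so the empirical frequency uses >= 1e4 draws
  cfg <- sim_config(n_transcripts = 3000, utr5_len = 50, cds_len = 300,
                    utr3_len = 150, unmethylated_fraction = 0,
                    hyper_fraction_3utr = 0, hypo_fraction = 0,
                    stop_window_cds = 30, stop_window_utr3 = 60)
  tr <- plant_truth(generate_annotation(cfg), cfg)
  expect_gt(nrow(tr$sites), 1e4)
  # oracle: empirical frequency of the same documented mixture
  mx <- cfg$meth_mixture
  hi <- runif(2e4) < mx$weight_high
  draws <- rbeta(2e4, ifelse(hi, mx$mean_high, mx$mean_low) *
                   ifelse(hi, mx$conc_high, mx$conc_low),
                 (1 - ifelse(hi, mx$mean_high, mx$mean_low)) *
                   ifelse(hi, mx$conc_high, mx$conc_low))
  expect_lt(abs(mean(tr$sites$base_level > 0.5) - mean(draws > 0.5)), 0.03)
  expect_lt(abs(mean(tr$sites$base_level > 0.5) - mx$weight_high), 0.03)
})

test_that("count model: conversion failures drive the unmethylated A rate", {
  set.seed(8)
  cfg <- tiny_config(n_transcripts = 5, spikein_len = 2000,
                     spikein_coverage_mean = 2000)
  ann <- generate_annotation(cfg)
  tr <- plant_truth(ann, cfg)
  d <- simulate_counts(tr, ann, cfg)
  # pooled spike-in reads across samples: >= 1e5 Bernoulli draws at p = 0.01
  spk <- do.call(rbind, lapply(d$counts, function(x)
    x[x$contig == "spikein", ]))
  tot <- sum(spk$a_count + spk$g_count)
  expect_gt(tot, 1e5)
  expect_lt(abs(sum(spk$a_count) / tot - 0.01), 0.002)
})

test_that("degenerate methylation levels force the A count", {
  set.seed(9)
  cfg <- tiny_config(conversion_rate = 1.0)
  ann <- generate_annotation(cfg)
  tr <- plant_truth(ann, cfg)
  # m = 1 at every planted site -> a_count equals coverage there;
  # m = 0 elsewhere with perfect conversion -> a_count 0
  tr$sites$level_A <- 1
  tr$sites$level_B <- 1
  d <- simulate_counts(tr, ann, cfg)
  keys <- paste(tr$sites$contig, tr$sites$pos0, tr$sites$strand)
  for (s in d$counts[1:2]) {
    k <- paste(s$contig, s$pos0, s$strand)
    planted <- s[k %in% keys, ]
    expect_true(all(planted$g_count == 0))  # a_count equals coverage
    expect_true(all(s$a_count[!k %in% keys] == 0))
  }
})

test_that("every planted site is emitted and lies on its annotated transcript", {
  set.seed(10)
  cfg <- tiny_config()
  ann <- generate_annotation(cfg)
  tr <- plant_truth(ann, cfg)
  d <- simulate_counts(tr, ann, cfg)
  emitted <- paste(d$counts[[1]]$contig, d$counts[[1]]$pos0,
                   d$counts[[1]]$strand)
  expect_true(all(paste(tr$sites$contig, tr$sites$pos0, tr$sites$strand) %in%
                    emitted))
  m <- match(tr$sites$transcript_id, ann$model$transcript_id)
  expect_false(anyNA(m))
  expect_true(all(tr$sites$pos0 >= ann$model$start0[m] &
                    tr$sites$pos0 < ann$model$end0[m]))
})

test_that("observed per-site A rate converges to p_obs at high coverage", {
  set.seed(11)
  cfg <- tiny_config(coverage_mean_per_tpm = 10, coverage_dispersion = 1e6)
  ann <- generate_annotation(cfg)
  tr <- plant_truth(ann, cfg)
  d <- simulate_counts(tr, ann, cfg)
  s1 <- d$counts[[1]]
  k <- paste(s1$contig, s1$pos0, s1$strand)
  m <- match(paste(tr$sites$contig, tr$sites$pos0, tr$sites$strand), k)
  cov <- s1$a_count[m] + s1$g_count[m]
  high <- which(cov >= 5e4)
  expect_gt(length(high), 5)
  p_obs <- tr$sites$level_A + (1 - tr$sites$level_A) * (1 - cfg$conversion_rate)
  rate <- s1$a_count[m] / cov
  expect_true(all(abs(rate[high] - p_obs[high]) < 0.01))
})

test_that("identical configuration and seed reproduce byte-identical files", {
  d1 <- file.path(tempdir(), "simdet1")
  d2 <- file.path(tempdir(), "simdet2")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_dataset(tiny_config(), outdir = d1, seed = 99)
  simulate_dataset(tiny_config(), outdir = d2, seed = 99)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_identical(unname(h1), unname(h2))
})
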