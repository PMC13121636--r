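test_that("TPM normalization matches hand computation and re-sums to 1e6", {
  counts <- matrix(c(10, 10), ncol = 1, dimnames = list(c("t1", "t2"), "s1"))
  tpm <- tpm_from_counts(counts, c(t1 = 1000, t2 = 2000))
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  one <- tpm_from_counts(matrix(5, 1, 1, dimnames = list("t", "s")),
                         c(t = 500))
  expect_equal(unname(one[1, 1]), 1e6)
  unif <- tpm_from_counts(matrix(7, 4, 2, dimnames = list(letters[1:4], NULL)),
                          setNames(rep(100, 4), letters[1:4]))
  expect_true(all(unif == 2.5e5))
  set.seed(50)
  big <- matrix(rpois(300, 50), 100, 3,
                dimnames = list(sprintf("t%d", 1:100), NULL))
  t2 <- tpm_from_counts(big, setNames(runif(100, 200, 2000),
                                      rownames(big)))
  expect_equal(unname(colSums(t2)), rep(1e6, 3), tolerance = 1e-3)
  expect_error(tpm_from_counts(matrix(0, 2, 1,
                                      dimnames = list(c("a", "b"), NULL)),
                               c(a = 1, b = 1)),
               class = "glorid_input_error")
})

test_that("the count filter flags transcripts at or below 10 in any sample", {
  cm <- matrix(c(11, 12, 10, 50, 11, 0), nrow = 3, byrow = TRUE,
               dimnames = list(c("t1", "t2", "t3"), NULL))
  expect_equal(unname(expression_filter(cm)), c(TRUE, FALSE, FALSE))
})

test_that("transcript aggregation sums site levels and classes by the >2 boundary", {
  sites <- data.frame(
    transcript_id = c("T1", "T1", "T1", "T2"),
    level = c(0.5, 0.9, 0.8, 0.3))
  agg <- aggregate_methylation(sites, transcript_ids = c("T1", "T2", "T3"))
  expect_equal(agg$aggregate_methylation, c(2.2, 0.3, 0))
  expect_equal(agg$meth_class, c("high", "low", "unmethylated"))
  # the boundary is exclusive: aggregate exactly 2 stays low
  two <- aggregate_methylation(data.frame(transcript_id = "T",
                                          level = c(1, 1)))
  expect_equal(two$meth_class, "low")
})

test_that("W is the TPM-weighted mean aggregate methylation", {
  tm <- data.frame(transcript_id = c("T1", "T2"), n_sites = c(1L, 0L),
                   aggregate_methylation = c(1.0, 0.0),
                   meth_class = c("low", "unmethylated"))
  tpm <- matrix(c(5e5, 5e5), 2, 1, dimnames = list(c("T1", "T2"), "s1"))
  samples <- data.frame(sample_id = "s1", group = "A")
  W <- weighted_global_methylation(tm, tpm, samples)
  expect_equal(W$per_sample$W, 0.5)
  tm0 <- transform(tm, aggregate_methylation = 0)
  expect_equal(weighted_global_methylation(tm0, tpm, samples)$per_sample$W, 0)
  bad <- transform(tm, transcript_id = c("X1", "X2"))
  expect_error(weighted_global_methylation(bad, tpm, samples),
               class = "glorid_input_error")
})

test_that("W is order-invariant, scales linearly, and is diluted by unmethylated mass", {
  tm <- data.frame(transcript_id = c("T1", "T2", "T3"),
                   n_sites = c(2L, 1L, 0L),
                   aggregate_methylation = c(1.5, 0.5, 0),
                   meth_class = c("low", "low", "unmethylated"))
  tpm <- matrix(c(2e5, 3e5, 5e5), 3, 1, dimnames = list(tm$transcript_id, "s"))
  samples <- data.frame(sample_id = "s", group = "A")
  w0 <- weighted_global_methylation(tm, tpm, samples)$per_sample$W
  # reorder
  perm <- c(3, 1, 2)
  w1 <- weighted_global_methylation(tm[perm, ],
                                    tpm[perm, , drop = FALSE],
                                    samples)$per_sample$W
  expect_equal(w0, w1)
  # scale aggregates by c
  tm3 <- transform(tm, aggregate_methylation = 3 * aggregate_methylation)
  expect_equal(weighted_global_methylation(tm3, tpm, samples)$per_sample$W,
               3 * w0)
  # add expression mass to the unmethylated transcript (renormalized):
  # W strictly decreases
  tpm2 <- tpm; tpm2["T3", 1] <- 2 * tpm2["T3", 1]
  tpm2 <- tpm2 / sum(tpm2) * 1e6
  w2 <- weighted_global_methylation(tm, tpm2, samples)$per_sample$W
  expect_lt(w2, w0)
})

test_that("k50 is the minimal transcript count reaching half the transcriptome", {
  expect_equal(cumulative_abundance(c(5e5, 3e5, 2e5))$k50, 1)  # top share = 0.5
  expect_equal(cumulative_abundance(rep(1, 10))$k50, 5)
  expect_error(cumulative_abundance(c(0, 0)), class = "glorid_input_error")
  set.seed(51)
  skewed <- rlnorm(500, 0, 2)
  expect_lt(cumulative_abundance(skewed)$k50, 125)
})

test_that("stratified expression shifts recover planted class fold changes", {
  tm <- data.frame(transcript_id = sprintf("T%d", 1:6),
                   n_sites = c(0L, 0L, 3L, 3L, 1L, 1L),
                   aggregate_methylation = c(0, 0, 2.5, 2.6, 0.4, 0.5),
                   meth_class = c("unmethylated", "unmethylated",
                                  "high", "high", "low", "low"))
  tpm <- matrix(1000, 6, 4,
                dimnames = list(tm$transcript_id, paste0("s", 1:4)))
  samples <- data.frame(sample_id = paste0("s", 1:4),
                        group = c("A", "A", "B", "B"))
  fc <- setNames(c(1, 1, -1, -1, 0, 0), tm$transcript_id)
  out <- stratified_expression_shift(tm, tpm, samples, top_k = 4, log2fc = fc)
  all_sc <- out[out$scope == "all", ]
  expect_equal(all_sc$median_log2fc[all_sc$class == "unmethylated"], 1)
  expect_equal(all_sc$median_log2fc[all_sc$class == "high"], -1)
  # top_k scope only covers 4 transcripts (rank ties broken deterministically)
  expect_equal(sum(out$n[out$scope == "top_k"]), 4)
  # an empty class is simply absent
  tm_nohigh <- tm[tm$meth_class != "high", ]
  out2 <- stratified_expression_shift(
    tm_nohigh, tpm[tm_nohigh$transcript_id, ], samples, top_k = 4,
    log2fc = fc[tm_nohigh$transcript_id])
  expect_false("high" %in% out2$class[out2$scope == "all"])
})

test_that("PCA separates groups that differ at one site", {
  lv <- rbind(site1 = c(0.2, 0.2, 0.8, 0.8),
              site2 = c(0.5, 0.5, 0.5, 0.5))
  colnames(lv) <- paste0("s", 1:4)
  res <- pca_separation(lv, c("A", "A", "B", "B"))
  expect_equal(res$silhouette, 1)
  expect_gt(abs(res$coords$PC1[1] - res$coords$PC1[3]), 0.5)
  # all-identical samples: defined output with zero coordinates
  flat <- pca_separation(matrix(0.4, 5, 4,
                                dimnames = list(NULL, paste0("s", 1:4))),
                         c("A", "A", "B", "B"))
  expect_true(all(flat$coords == 0))
  expect_true(is.na(flat$silhouette))
  expect_error(pca_separation(lv[, 1:2], c("A", "B")),
               class = "glorid_input_error")
})

test_that("Fisher exact p equals the hypergeometric enumeration oracle", {
  tab <- matrix(c(10, 30, 20, 5), 2)
  expect_lt(abs(fisher.test(tab)$p.value - fisher_enum_p(tab)), 1e-10)
  set.seed(52)
  for (i in 1:50) {
    t2 <- matrix(rpois(4, 15) + 1, 2)
    expect_lt(abs(fisher.test(t2)$p.value - fisher_enum_p(t2)), 1e-10)
  }
})

test_that("BH adjustment matches the reference step-up procedure", {
  set.seed(53)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(p.adjust(p, "BH"), bh_stepup(p), tolerance = 1e-12)
  }
})

test_that("APA classes follow the delta-PDUI and FDR thresholds", {
  set.seed(54)
  samples <- data.frame(sample_id = paste0("s", 1:8),
                        group = rep(c("A", "B"), each = 4))
  jitter <- function(x) x + rnorm(4, 0, 0.005)
  pdui <- rbind(
    short = c(jitter(0.80), jitter(0.65)),   # delta -0.15
    small = c(jitter(0.80), jitter(0.75)),   # delta -0.05: below cutoff
    long  = c(jitter(0.60), jitter(0.80)),   # delta +0.20
    none  = c(jitter(0.70), jitter(0.70)))
  colnames(pdui) <- samples$sample_id
  status <- c(short = TRUE, small = TRUE, long = FALSE, none = FALSE)
  res <- apa_association(pdui, samples, status)
  rec <- res$records
  expect_equal(rec$class[rec$transcript_id == "short"], "shortened")
  expect_equal(rec$class[rec$transcript_id == "small"], "none")
  expect_equal(rec$class[rec$transcript_id == "long"], "lengthened")
  expect_equal(res$fisher$table["shortened", "m6A"], 1)
  expect_error(apa_association(pdui, samples[c(1, 5), ], status),
               class = "glorid_input_error")
})
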