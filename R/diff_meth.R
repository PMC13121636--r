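#' Differential-methylation thresholds
#'
#' Defaults mirror the standard practice for per-site comparisons of
#' deamination data: an absolute methylation difference of at least 10%
#' (a cutoff that clearly exceeds the within-group site-level variability)
#' and a raw p-value below 0.05; no multiple-testing correction by default.
#'
#' @param min_delta minimum |methylation difference| (inclusive).
#' @param alpha p-value cutoff (strict).
#' @param min_coverage_per_sample coverage a site needs in every sample to
#'   enter the test universe.
#' @return a `glorid_diff_thresholds` list.
#' @export
diff_thresholds <- function(min_delta = 0.10, alpha = 0.05,
                            min_coverage_per_sample = 15L) {
  if (alpha <= 0 || alpha >= 1)
    stop_glorid("alpha must lie in (0, 1)", "glorid_config_error")
  structure(list(min_delta = min_delta, alpha = alpha,
                 min_coverage_per_sample = min_coverage_per_sample),
            class = "glorid_diff_thresholds")
}

#' Build the two-group test universe of DRAC positions
#'
#' The universe contains every annotated center-A position whose pentamer is
#' DRAC-conform (classes `DRACH`/`DRACN_1mm`) and whose A+G coverage reaches
#' `min_coverage_per_sample` in every sample of both groups. Unmethylated
#' positions (level 0) are retained: the test is over all candidate DRAC
#' positions, not only called sites.
#'
#' @param count_tables named list of per-sample count data.frames covering
#'   both groups.
#' @param model a [transcript_model()].
#' @param reference reference sequences ([Biostrings::DNAStringSet]).
#' @param min_coverage_per_sample per-sample coverage floor.
#' @return list with `sites` (site metadata: key, pentamer, transcript,
#'   region) and `counts` (long data.table: key, sample_id, a_count,
#'   coverage).
#' @export
build_test_universe <- function(count_tables, model, reference,
                                min_coverage_per_sample = 15L) {
  stopifnot(length(count_tables) >= 2L)
  long <- data.table::rbindlist(lapply(names(count_tables), function(s) {
    df <- count_tables[[s]]
    data.table::data.table(contig = df$contig, pos0 = df$pos0,
                           strand = df$strand, sample_id = s,
                           a_count = df$a_count,
                           coverage = df$a_count + df$g_count)
  }))
  n_samples <- length(count_tables)
  ok <- long[, .(n_ok = sum(coverage >= min_coverage_per_sample)),
             by = .(contig, pos0, strand)][n_ok == n_samples]
  if (nrow(ok) == 0L)
    stop_glorid("test universe is empty: no position reaches the coverage floor in every sample",
                "glorid_pipeline_error")
  meta <- as.data.frame(ok[, .(contig, pos0, strand)])
  meta <- suppressWarnings(annotate_sites(meta, model, reference))
  meta <- restrict_to_drac(meta)
  meta <- meta[meta$region != "intergenic", , drop = FALSE]
  if (nrow(meta) == 0L)
    stop_glorid("test universe is empty after DRAC/transcript restriction",
                "glorid_pipeline_error")
  meta <- meta[order(meta$contig, meta$pos0, meta$strand), , drop = FALSE]
  rownames(meta) <- NULL
  keys <- site_key(meta$contig, meta$pos0, meta$strand)
  counts <- long[site_key(contig, pos0, strand) %in% keys]
  list(sites = meta, counts = counts)
}

#' Within-group standard deviations of site methylation levels
#'
#' Computes, per site and group, the sample standard deviation (n-1
#' denominator) of the observed levels `a / coverage`, and summarizes each
#' group by the mean SD, the 90th percentile, and the fraction of sites
#' with SD below 10%. This is the empirical justification for the 10%
#' differential-methylation cutoff.
#'
#' @param universe a [build_test_universe()] result.
#' @param samples data.frame with `sample_id` and `group` (two groups).
#' @return list with `per_site` (site x group SD table) and `summary`.
#' @export
sd_threshold_report <- function(universe, samples) {
  cnt <- data.table::as.data.table(universe$counts)
  cnt <- merge(cnt, data.table::as.data.table(samples), by = "sample_id")
  if (any(table(samples$group) < 2L))
    stop_glorid("SD undefined: need >= 2 samples per group",
                "glorid_input_error")
  cnt[, level := a_count / coverage]
  per <- cnt[, .(sd_level = sd(level)), by = .(contig, pos0, strand, group)]
  summary <- per[, .(n_sites = .N, mean_sd = mean(sd_level),
                     p90_sd = unname(quantile(sd_level, 0.90)),
                     frac_below_0.10 = mean(sd_level < 0.10)),
                 by = group][order(group)]
  list(per_site = as.data.frame(per), summary = as.data.frame(summary))
}

## deterministic canonical ordering of the two groups so that swapping the
## group labels mirrors the fit exactly (delta negated, p identical)
group_sort_key <- function(a, n) {
  paste(c(sum(n), sum(a), n, a), collapse = ",")
}

bb_nll <- function(a, n, pi, theta) {
  -sum(dbetabinom_log(a, n, pi, theta))
}

#' Per-site two-group beta-binomial likelihood-ratio test
#'
#' Models the unconverted-A counts of each sample as
#' `a_i ~ BetaBinomial(n_i, pi_g, phi)` with a group-specific mean level
#' `pi_g` and one per-site dispersion `phi = 1 / (alpha + beta + 1)` shared
#' by both groups. Means and dispersion are fitted by maximum likelihood
#' (on logit/log scales); the null constrains `pi_A = pi_B` and the
#' p-value comes from the likelihood-ratio statistic against chi-squared
#' with one degree of freedom, floored at machine epsilon. The reported
#' `delta` is `pi_B - pi_A` from the alternative fit. With `phi_fixed = 0`
#' the model reduces to a pure binomial likelihood-ratio test on the
#' pooled group counts (closed form).
#'
#' @param a_A,n_A unconverted-A and coverage vectors for group A samples.
#' @param a_B,n_B the same for group B.
#' @param phi_fixed optionally fix the dispersion instead of estimating it.
#' @return list with `pi_A`, `pi_B`, `delta`, `dispersion`, `lr_stat`,
#'   `p_value`.
#' @export
beta_binomial_test <- function(a_A, n_A, a_B, n_B, phi_fixed = NULL) {
  keepA <- n_A > 0; keepB <- n_B > 0
  a_A <- a_A[keepA]; n_A <- n_A[keepA]
  a_B <- a_B[keepB]; n_B <- n_B[keepB]
  if (length(n_A) == 0L || length(n_B) == 0L)
    stop_glorid("degenerate site: a group has no coverage",
                "glorid_degenerate_site")

  ## binomial limit: closed-form MLEs and LRT
  if (!is.null(phi_fixed) && phi_fixed == 0) {
    pA <- sum(a_A) / sum(n_A); pB <- sum(a_B) / sum(n_B)
    p0 <- (sum(a_A) + sum(a_B)) / (sum(n_A) + sum(n_B))
    llb <- function(a, n, p) {
      p <- min(max(p, 1e-12), 1 - 1e-12)
      sum(lchoose(n, a) + a * log(p) + (n - a) * log(1 - p))
    }
    lr <- 2 * (llb(a_A, n_A, pA) + llb(a_B, n_B, pB) -
                 llb(c(a_A, a_B), c(n_A, n_B), p0))
    lr <- max(lr, 0)
    return(list(pi_A = pA, pi_B = pB, delta = pB - pA, dispersion = 0,
                lr_stat = lr,
                p_value = max(pchisq(lr, 1, lower.tail = FALSE),
                              .Machine$double.eps)))
  }

  swapped <- group_sort_key(a_B, n_B) < group_sort_key(a_A, n_A)
  if (swapped) {
    tmp <- list(a_A, n_A); a_A <- a_B; n_A <- n_B
    a_B <- tmp[[1]]; n_B <- tmp[[2]]
  }

  lo_l <- -12; hi_l <- 12; lo_t <- -7; hi_t <- 20
  start_p <- function(a, n) qlogis((sum(a) + 0.5) / (sum(n) + 1))
  sA <- min(max(start_p(a_A, n_A), lo_l), hi_l)
  sB <- min(max(start_p(a_B, n_B), lo_l), hi_l)
  s0 <- min(max(start_p(c(a_A, a_B), c(n_A, n_B)), lo_l), hi_l)
  lt_fix <- if (!is.null(phi_fixed)) log((1 - phi_fixed) / phi_fixed) else NULL

  nll_alt <- function(par) {
    lt <- if (is.null(lt_fix)) par[3] else lt_fix
    bb_nll(a_A, n_A, plogis(par[1]), exp(lt)) +
      bb_nll(a_B, n_B, plogis(par[2]), exp(lt))
  }
  nll_null <- function(par) {
    lt <- if (is.null(lt_fix)) par[2] else lt_fix
    bb_nll(c(a_A, a_B), c(n_A, n_B), plogis(par[1]), exp(lt))
  }
  if (is.null(lt_fix)) {
    f1 <- nlminb(c(sA, sB, 5), nll_alt, lower = c(lo_l, lo_l, lo_t),
                 upper = c(hi_l, hi_l, hi_t))
    f0 <- nlminb(c(s0, 5), nll_null, lower = c(lo_l, lo_t),
                 upper = c(hi_l, hi_t))
    theta <- exp(f1$par[3])
  } else {
    f1 <- nlminb(c(sA, sB), nll_alt, lower = c(lo_l, lo_l),
                 upper = c(hi_l, hi_l))
    f0 <- nlminb(s0, nll_null, lower = lo_l, upper = hi_l)
    theta <- exp(lt_fix)
  }
  pA <- plogis(f1$par[1]); pB <- plogis(f1$par[2])
  if (swapped) { tmp <- pA; pA <- pB; pB <- tmp }
  lr <- max(2 * (f0$objective - f1$objective), 0)
  list(pi_A = pA, pi_B = pB, delta = pB - pA,
       dispersion = max(1 / (1 + theta), 0),
       lr_stat = lr,
       p_value = max(pchisq(lr, 1, lower.tail = FALSE), .Machine$double.eps))
}

#' Run the beta-binomial test over a test universe
#'
#' @param universe a [build_test_universe()] result.
#' @param samples data.frame with `sample_id` and `group` (values "A"/"B").
#' @param verbose log skipped (degenerate) sites.
#' @return data.frame of per-site results (one row per testable site) with
#'   group level estimates, `delta`, `dispersion`, `p_value`.
#' @export
diff_methylation <- function(universe, samples, verbose = FALSE) {
  meta <- universe$sites
  cnt <- data.table::as.data.table(universe$counts)
  grp <- setNames(samples$group, samples$sample_id)
  cnt[, `:=`(key = site_key(contig, pos0, strand),
             group = unname(grp[sample_id]))]
  data.table::setkey(cnt, key)
  keys <- site_key(meta$contig, meta$pos0, meta$strand)

  res <- vector("list", nrow(meta))
  for (i in seq_along(keys)) {
    x <- cnt[.(keys[i])]
    iA <- x$group == "A"
    fit <- tryCatch(
      beta_binomial_test(x$a_count[iA], x$coverage[iA],
                         x$a_count[!iA], x$coverage[!iA]),
      glorid_degenerate_site = function(e) {
        if (verbose) message("site ", keys[i], " skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(fit))
      res[[i]] <- data.frame(meta[i, , drop = FALSE],
                             pi_A = fit$pi_A, pi_B = fit$pi_B,
                             delta = fit$delta, dispersion = fit$dispersion,
                             p_value = fit$p_value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Classify tested sites as hyper-/hypomethylated
#'
#' A site is `hyper` if `delta >= min_delta` and `p < alpha`, `hypo` if
#' `delta <= -min_delta` and `p < alpha`, otherwise `none`. Raw p-values
#' are used (no multiple-testing correction); pass `adjust = "BH"` to
#' classify on Benjamini-Hochberg adjusted values instead.
#'
#' @param diff data.frame from [diff_methylation()].
#' @param thresholds a [diff_thresholds()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return the input with a `direction` column plus `hyper`/`hypo` subsets.
#' @export
classify_differential <- function(diff, thresholds = diff_thresholds(),
                                  adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  p <- if (adjust == "BH") p.adjust(diff$p_value, "BH") else diff$p_value
  sig <- p < thresholds$alpha
  diff$direction <- ifelse(sig & diff$delta >= thresholds$min_delta, "hyper",
                           ifelse(sig & diff$delta <= -thresholds$min_delta,
                                  "hypo", "none"))
  list(sites = diff,
       hyper = diff[diff$direction == "hyper", , drop = FALSE],
       hypo = diff[diff$direction == "hypo", , drop = FALSE])
}

#' Transcript-level differential-methylation classes
#'
#' A transcript is `hyper` (`hypo`) if at least one of its sites is hyper-
#' (hypo-)methylated, `both` if it has at least one of each, and
#' `unchanged` otherwise.
#'
#' @param diff classified site data.frame (needs `transcript_id`,
#'   `direction`).
#' @return data.frame with per-transcript site counts and class.
#' @export
classify_transcripts <- function(diff) {
  assert_columns(diff, c("transcript_id", "direction"), "differential sites")
  dt <- data.table::as.data.table(diff)[!is.na(transcript_id)]
  out <- dt[, .(n_hyper_sites = sum(direction == "hyper"),
                n_hypo_sites = sum(direction == "hypo")),
            by = transcript_id]
  out[, class := ifelse(n_hyper_sites > 0 & n_hypo_sites > 0, "both",
                        ifelse(n_hyper_sites > 0, "hyper",
                               ifelse(n_hypo_sites > 0, "hypo", "unchanged")))]
  as.data.frame(out[order(transcript_id)])
}
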