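#' Configuration for the synthetic GLORI dataset generator
#'
#' Bundles every knob of the generator: transcript architecture, the
#' bimodal methylation mixture, deamination conversion efficiency,
#' coverage and expression models, the planted two-group effects
#' (3'-UTR hypermethylation near the stop codon, scattered
#' hypomethylation, abundance shifts that dilute global methylation,
#' and a PDUI shift for methylated transcripts), and the RNG seed.
#'
#' Defaults emulate the study conditions the pipeline targets: nine
#' samples per group, a site-per-transcript Poisson rate of 4, a
#' methylation mixture peaking near 20% and 95%, a 99% deamination
#' conversion rate, and a +0.20 hypermethylation effect planted in the
#' first `hyper_window` nucleotides of the 3'-UTR of group B.
#'
#' @param n_transcripts number of (single-exon) transcripts.
#' @param utr5_len,cds_len,utr3_len region lengths in nt; `cds_len` must be
#'   divisible by 3 (the CDS includes the stop codon).
#' @param sites_per_transcript_mean Poisson mean of m6A sites per methylated
#'   transcript.
#' @param unmethylated_fraction fraction of transcripts carrying no m6A site
#'   at all (the "unmethylated" abundance class).
#' @param meth_mixture two-component Beta mixture for baseline site levels:
#'   list with `weight_high`, `mean_low`, `mean_high`, `conc_low`,
#'   `conc_high` (concentration = alpha + beta).
#' @param conversion_rate A-to-G deamination conversion efficiency for
#'   unmethylated adenosines; must lie in (0.9, 1].
#' @param coverage_mean_per_tpm negative-binomial mean coverage per TPM unit
#'   at a site.
#' @param coverage_dispersion negative-binomial `size` for site coverage.
#' @param n_samples_per_group samples per group (groups "A" = control,
#'   "B" = affected).
#' @param hyper_fraction_3utr fraction of stop-proximal 3'-UTR sites planted
#'   hypermethylated in group B.
#' @param hyper_delta planted methylation difference (applied +/- before
#'   clipping to `[0, 1]`).
#' @param hyper_window width (nt) of the 3'-UTR window after the stop codon
#'   eligible for planted hypermethylation.
#' @param hypo_fraction fraction of sites outside that window planted
#'   hypomethylated in group B.
#' @param stop_proximal_fraction fraction of baseline sites placed inside the
#'   stop-codon window (last `stop_window_cds` nt of CDS plus first
#'   `stop_window_utr3` nt of 3'-UTR); the remainder is uniform over the
#'   transcript.
#' @param stop_window_cds,stop_window_utr3 stop-codon window extents in nt.
#' @param dilution_scheme named fold-changes of group-B expression by
#'   transcript methylation class (`unmethylated`, `low`, `high`); the
#'   defaults move abundance from highly methylated to unmethylated
#'   transcripts, diluting global methylation in group B.
#' @param tpm_lnorm_sigma log-normal sigma of baseline transcript abundance.
#' @param lib_size expected total RNA-seq counts per sample.
#' @param expr_dispersion negative-binomial `size` for expression counts.
#' @param pdui_effect PDUI decrease in group B for methylated transcripts
#'   (3'-UTR shortening).
#' @param apa_background_fraction fraction of transcripts with an
#'   m6A-independent PDUI shift of `+/- pdui_effect` (random sign) in
#'   group B, so that both shortened and lengthened classes occur.
#' @param pdui_noise_sd Gaussian sd of per-sample PDUI noise (values clipped
#'   to `[0, 1]`).
#' @param spikein_len length (nt) of the unmethylated spike-in contig.
#' @param spikein_coverage_mean mean coverage at spike-in adenosines.
#' @param pad nt of random padding sequence on each side of a transcript on
#'   its contig.
#' @param rng_seed integer seed; identical configurations and seeds yield
#'   byte-identical outputs.
#'
#' @return an object of class `glorid_sim_config` (a validated list).
#' @export
sim_config <- function(n_transcripts = 150,
                       utr5_len = 200, cds_len = 900, utr3_len = 600,
                       sites_per_transcript_mean = 4,
                       unmethylated_fraction = 0.3,
                       meth_mixture = list(weight_high = 0.5,
                                           mean_low = 0.20, mean_high = 0.95,
                                           conc_low = 20, conc_high = 40),
                       conversion_rate = 0.99,
                       coverage_mean_per_tpm = 0.05,
                       coverage_dispersion = 10,
                       n_samples_per_group = 9,
                       hyper_fraction_3utr = 0.5,
                       hyper_delta = 0.20,
                       hyper_window = 200,
                       hypo_fraction = 0.05,
                       stop_proximal_fraction = 0.5,
                       stop_window_cds = 100,
                       stop_window_utr3 = 200,
                       dilution_scheme = c(unmethylated = 2, low = 1, high = 0.5),
                       tpm_lnorm_sigma = 1.5,
                       lib_size = 2e6,
                       expr_dispersion = 20,
                       pdui_effect = 0.2,
                       apa_background_fraction = 0.15,
                       pdui_noise_sd = 0.05,
                       spikein_len = 400,
                       spikein_coverage_mean = 1000,
                       pad = 50,
                       rng_seed = 1L) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "glorid_sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_transcripts < 0)
      stop_glorid("n_transcripts must be >= 0", "glorid_config_error")
    if (utr5_len <= 0 || cds_len <= 0 || utr3_len <= 0)
      stop_glorid("region lengths must be positive", "glorid_config_error")
    if (cds_len %% 3 != 0)
      stop_glorid("cds_len must be divisible by 3", "glorid_config_error")
    fracs <- c(unmethylated_fraction, hyper_fraction_3utr, hypo_fraction,
               stop_proximal_fraction, meth_mixture$weight_high,
               meth_mixture$mean_low, meth_mixture$mean_high)
    if (any(fracs < 0 | fracs > 1))
      stop_glorid("all fractions must lie in [0, 1]", "glorid_config_error")
    if (conversion_rate <= 0.9 || conversion_rate > 1)
      stop_glorid("conversion_rate must lie in (0.9, 1]", "glorid_config_error")
    if (n_samples_per_group < 1)
      stop_glorid("n_samples_per_group must be >= 1", "glorid_config_error")
    if (!all(c("unmethylated", "low", "high") %in% names(dilution_scheme)))
      stop_glorid("dilution_scheme needs fold-changes named unmethylated, low, high",
                  "glorid_config_error")
  })
  invisible(cfg)
}
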