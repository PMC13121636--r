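---
title: "Methods: comparative m6A epitranscriptomics from deamination counts"
author: "glorid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative m6A epitranscriptomics from deamination counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glorid)
```

## The measurement model

Chemical-deamination sequencing (GLORI-style assays) converts unmethylated
adenosines to inosine, read as G; N6-methyladenosine (m6A) resists
conversion and is read as A. After alignment and pileup, each candidate
adenosine position carries two counts per sample: `a_count` (unconverted A
reads) and `g_count` (converted reads). The *non-conversion rate*
`a / (a + g)` directly estimates the site's methylation level, so the whole
analysis operates on per-site count tables rather than reads. Alignment of
deaminated reads is upstream of this package; its contract starts at the
pileup table.

Observed A reads at a site with true methylation level $m$ follow

$$a \sim \mathrm{Binomial}\!\left(n,\; m + (1 - m)(1 - c)\right),$$

where $c$ is the deamination conversion rate. Conversion failure and
sequencing error are deliberately folded into the single $(1 - c)$ term:
the assay's quality metric is the aggregate conversion ratio measured on an
unmethylated spike-in, and the two error sources are not separable at the
count level. `conversion_qc()` reports the median spike-in conversion per
sample against a 0.99 pass threshold, the efficiency expected of a
successful reaction.

## Site calling and motif confidence

`call_sites()` applies three joint criteria, all inclusive boundaries:
coverage $\ge$ 15 reads, unconverted-A reads $\ge$ 5, and level $\ge$ 0.10.
The level boundary is read as inclusive: where tool parameter lists
("$\ge 0.1$ A rate") and informal descriptions ("level $> 10\%$")
disagree, the operational parameter is treated as authoritative. "Variant nucleotides" are the unconverted A reads: in
a deaminated library the A base is the variant relative to the converted
background.

Called sites are classified against the DRACH consensus
(D = A/G/T, R = A/G, central A, C, H = A/C/T; RNA U maps to T because the
analysis lives in reference space). Mismatches are counted at positions
1, 2, 4 and 5, partitioning the 256 center-A pentamers into 18 DRACH,
6 DRACN (one mismatch, at position 5), 78 non-DRACN (one mismatch in the
first four bases) and 154 multi-mismatch pentamers. Because sites in
motifs unrelated to DRACH behave like deamination artefacts (low, noisy
levels), every downstream stage is restricted to the 24 DRAC-conform
pentamers (DRACH plus DRACN). The "15 most detected motifs" table breaks
count ties lexicographically; whether tie-breaking ever matters in practice
is data-dependent, so the rule is simply fixed as a repository convention.

Coordinates are 0-based half-open internally; GTF is converted on ingest
and BED output stays 0-based. One boundary convention is applied
everywhere: the CDS includes the stop codon, and the first base after the
CDS belongs to the 3'-UTR.

## Differential methylation

For each DRAC position covered by $\ge$ 15 reads in *every* sample
(unmethylated positions included — the test universe is all candidate
positions, not just called sites), the two groups are compared with a
per-site beta-binomial model:

$$a_i \sim \mathrm{BetaBinomial}(n_i, \pi_{g(i)}, \phi),$$

with group means $\pi_A, \pi_B$ and a single per-site dispersion
$\phi = 1/(\alpha + \beta + 1)$ shared by both groups. All three
parameters are fitted by maximum likelihood on logit/log scales
(box-constrained quasi-Newton, logits in $[-12, 12]$, $\log\theta$ in
$[-7, 20]$ so the binomial limit is reachable without overflow); the null
constrains $\pi_A = \pi_B$, and the p-value is the likelihood-ratio
statistic against $\chi^2_1$, floored at machine epsilon. This per-site
MLE with a common dispersion and no windowing or shrinkage across sites is
the closest published description of beta-binomial site testing for this
assay class; dispersion shrinkage variants exist, so the calibration is
asserted by simulation (type-I error within [0.03, 0.07] at the study's
sample size) rather than by matching any particular implementation.

The reported effect `delta` is $\hat\pi_B - \hat\pi_A$ from the model fit
rather than the unweighted mean of sample levels, keeping the effect
estimate coverage-weighted consistently with the likelihood. Sites are
hypermethylated at `delta >= 0.10` and `p < 0.05` (raw p-values, matching
the stated practice; a Benjamini-Hochberg option exists but is off by
default). The 10% cutoff is justified empirically by
`sd_threshold_report()`: at the default study conditions the within-group
SD of observed levels has a mean near 1% and a 90th percentile well below
6%, so a 10% difference clearly exceeds stochastic variability. Exact
label-swap symmetry of the test (delta negated, p identical) is guaranteed
by fitting in a canonical group order derived from the data.

Transcripts are classed hyper/hypo if at least one site changes in that
direction, `both` if both directions occur.

## Transcript aggregation and the dilution statistic

The aggregate methylation of a transcript is the **sum** of its called
sites' levels. A sum (not a mean) is forced by the `aggregate > 2`
boundary of the "highly methylated" class, which a mean of fractions could
never reach. The TPM-weighted global methylation of a sample is

$$W = \sum_t \mathrm{aggregate}(t) \cdot \frac{\mathrm{TPM}(t)}{10^6},$$

i.e. an expression-weighted mean aggregate. Dividing by $10^6$ differs
from an unnormalized weighted sum only by that constant and does not
affect group comparisons; it makes $W$ interpretable as the methylation of
an average expressed transcript-copy. Because TPM is relative, moving
expression mass toward unmethylated transcripts *must* lower $W$ — the
"dilution" mechanism — and the package tests this as an algebraic
invariant. Group $W$ values are compared with a two-sided t-test (the
sidedness of the original comparison is not stated; two-sided is the
conservative choice).

Expression handling is intentionally naive inside the pipeline: TPM from
counts and lengths, a count filter (> 10 in every sample), and log2 fold
changes of mean group TPM with a 1-TPM pseudocount. A full
negative-binomial DE model is out of scope; an external DE table can be
substituted. The "highly abundant" scope of the stratified fold-change
analysis is a rank cutoff (top 500 by mean TPM) rather than a TPM
threshold, because a rank is scale-free; this choice is configurable.

Group separation uses the singular-value decomposition of the site-by-sample
level matrix (centered per site) and reports the mean silhouette width of
the group labels on the first two components.

Alternative polyadenylation enters as per-transcript PDUI values computed
upstream (the two-site regression that produces them is out of scope).
Per transcript, delta PDUI is the group-B minus group-A mean, tested with
a two-sided Welch t-test and BH-FDR across transcripts; transcripts pass
at |delta| > 0.1 and FDR < 0.05, and the shortened/lengthened by
methylated/unmethylated association is a two-sided Fisher exact test.

## Positional analyses

Metagene coordinates stretch each region to unit length (5'-UTR to
[0, 1), CDS to [1, 2), 3'-UTR to [2, 3)), matching the three-panel
metagene convention; 90 bins (30 per region) is the default. Sites are
counted equally; weighting by methylation level is available as an option
since the convention is ambiguous on this point. The stop-codon profile
offsets sites from the CDS/3'-UTR junction (offset 0 = first 3'-UTR base)
and averages delta within bins; the window and bin width are not
prescribed anywhere, so ±400 nt and 20 nt are package defaults.

## The synthetic-data generator

The generator exists because the analyses above need data with known
truth. It emulates, at count level:

- single-exon transcripts (200 nt 5'-UTR, 900 nt CDS, 600 nt 3'-UTR) on
  individual contigs, both strands; splicing adds nothing to these
  computations and would only complicate coordinate tests;
- a Poisson number of m6A sites per methylated transcript (mean 4, the
  typical per-transcript site count), with 30% of transcripts fully
  unmethylated so that an unmethylated abundance class exists;
- DRACH pentamers written into the sequence at every planted site, at
  least 5 nt apart so pentamers never overlap;
- baseline levels from a two-component Beta mixture with means 0.20 and
  0.95 (equal weights, concentrations 20 and 40), reproducing the
  characteristic bimodal level distribution;
- half of all sites placed in a stop-codon window (last 100 nt of CDS,
  first 200 nt of 3'-UTR), giving the metagene its stop-proximal peak;
- group-B hypermethylation (+0.20) planted on half of the stop-proximal
  3'-UTR sites, and hypomethylation (-0.20) on 5% of the remaining sites.
  Planted effects are applied to baselines drawn from the matching mixture
  component (low for hyper, high for hypo) so the full effect size is
  observable before clipping to [0, 1];
- negative-binomial coverage proportional to the transcript's group TPM
  (0.05x per TPM, dispersion 10), log-normal baseline abundance
  (sigma 1.5), and binomial A counts at
  $p_\mathrm{obs} = m + (1-m)(1-c)$ with $c = 0.99$;
- an expression shift in group B (unmethylated transcripts x2, highly
  methylated x0.5, then renormalized) that produces global dilution;
- PDUI shortening (-0.2) for methylated transcripts in group B on top of
  a background of m6A-independent ±0.2 shifts affecting 15% of
  transcripts (without a background class the shortened/lengthened table
  would be degenerate), plus Gaussian observation noise (sd 0.05) clipped
  to [0, 1];
- an unmethylated spike-in contig at fixed coverage for conversion QC.

Nine samples per group is the default, matching the tissue comparison the
pipeline targets. What the generator does **not** emulate: read-level
artefacts (mapping bias, PCR duplicates), splice isoforms, batch effects,
contamination, biological within-group level variability beyond counting
noise, and transcript-length or GC effects on coverage. Passing recovery
tests therefore demonstrates correctness of the statistical machinery
under the stated generative model, not robustness to every real-data
pathology.

Default problem sizes are chosen for fast, fully reproducible desk-scale
analysis: 150 transcripts x 18 samples yields roughly 65,000 candidate
adenosines per sample and a test universe of ~5,000 DRAC positions, large
enough for stable calibration estimates while a full pipeline run stays
near a minute. All randomness flows from a single integer seed; identical
configuration and seed give byte-identical output files.

## Numerical and degenerate-input conventions

- Optimization on logit/log scales with box constraints; starting values
  from shrunk pooled proportions ((a + 0.5) / (n + 1)).
- Likelihood-ratio statistics are floored at 0 and p-values at machine
  epsilon.
- Sites with zero coverage throughout a group are skipped (logged), not
  imputed.
- Pentamers are undefined within 2 nt of a contig edge; such sites are
  dropped with a warning.
- The silhouette is `NA` for a zero-variance level matrix (coordinates are
  all zero); Fisher's test is omitted when no transcript is classified
  shortened or lengthened.
- `k50` uses an inclusive boundary (cumulative share >= 0.5), so a
  transcript holding exactly half the transcriptome gives k50 = 1.

## Known limitations

The beta-binomial test treats sites independently; borrowing dispersion
strength across sites would improve power at low coverage. The pipeline
assumes one transcript model per site (ties between overlapping
transcripts are broken by identifier order). PDUI inference uses a t-test
on provided indices rather than the regression that generated them.
Finally, all acceptance-style checks run on synthetic data; headline site
counts from real tissue cohorts depend on sequencing depth and cannot be
reproduced at this scale.
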