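---
title: "Methods: regional rare-variant burden scanning and biomarker statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional rare-variant burden scanning and biomarker statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regionburden)
```

# Overview

`regionburden` implements the computational spine of a tumor-evolution
study design: deep sequencing of many laser-capture microdissected tumor
islets from one patient identifies *ancestor* mutations (present in
essentially all islets, absent from the matched normal), targeted
sequencing of a candidate region across a patient cohort is scanned for
windows enriched in rare variants, candidate non-coding variants are
assigned to genes through GREAT-style regulatory domains and tested for
gene-ontology enrichment, and an immunohistochemistry (IHC) readout is
evaluated as a biomarker. Because the original inputs are
controlled-access patient genomes, every input has a synthetic generator
whose defaults encode the study's design parameters, and all statistical
machinery is validated against closed forms, exhaustive enumeration or
brute-force oracles on those synthetic inputs.

# Ancestor-variant discovery

A variant (identified by chromosome, position, reference and alternate
base; zygosity is ignored because islet calls are sparse) is an ancestor
candidate when its islet-presence fraction — carriers divided by the total
number of islets, computed exactly — is at least the threshold
(default 0.90, compared inclusively, so 27 of 30 islets qualifies) and it
was not called in the matched normal. The fraction is computed over *all*
islets rather than islets with adequate coverage at the site; the
generator does not model coverage dropout, so on synthetic data the two
readings coincide.

The islet generator (`simulate_islet_callsets()`) draws a founding clone
of `root_variants` loci carried by each islet independently with
probability `root_presence` (default 0.95, chosen so that presence
fluctuates realistically around the 90% calling threshold rather than
sitting degenerately at 1), plus islet-private variants (Poisson per
islet) and germline variants shared with the normal.

# The window scan

The target is a 2 Mb region tiled with 40 kb windows advanced by 100 bp
(19,601 windows; the first window starts at the region start and the
count is `floor((L - w)/step) + 1`). Three statistics are attached to
each window.

**Ratio statistic.** Observed number of *distinct* rare variants in the
cancer cohort divided by the expected number of common-SNP carrier calls.
Rare variants are single-nucleotide substitutions seen in fewer than five
distinct samples (strict comparison), absent from the reference
allele-frequency panel, and flagged `pass` or `allele_bias` by the
caller. The expectation is obtained by simulation: at every panel site
with minor allele frequency above 5% inside the region, genotypes for a
33-sample cohort are drawn under Hardy–Weinberg equilibrium with no
linkage (per-site carrier counts are Binomial(33, 2p(1−p) + p²), which is
distributionally identical to drawing the full genotype matrix and
counting non-reference calls, and much cheaper), and the per-window sum
of carriers is averaged over 1000 simulations. Counting *carrier
genotype calls* rather than *segregating sites* is the default because
the average profile is defined over individuals' non-reference calls; a
`density_mode = "sites"` switch provides the segregating-sites variant,
and the across-simulation variance is recorded for diagnostics. Windows
with zero expectation but positive observation get an `Inf` sentinel,
are excluded from ranking, and are reported with a warning; division of
zero by zero reports 0.

**Order-statistic p-value.** 100 subsets of 33 individuals are sampled
without replacement (independently across subsets) from a control
population; the rare-variant filter and the ratio statistic are
recomputed within each subset, and the p-value is the fraction of control
statistics at least as large as the observed one. Ties count against
significance, and zero exceedances are reported censored at 1/N
(printed "< 0.01" for N = 100) rather than as zero, so the p-value is
never anti-conservatively exact. Under the null (cases drawn from the
control model) these p-values are stochastically at least uniform, which
the test suite asserts with a one-sided Kolmogorov–Smirnov check.

**Poisson hotspot p-value.** Under a uniform-occurrence null, the count
in a window of width *w* is Poisson with rate (total variants in region /
region length) × *w*; the p-value is the upper tail P(X ≥ observed).
The global rate is estimated from the same data, which is negligible at
thousands of windows.

No multiple-testing correction is applied across the overlapping
windows: the scan is a localization device, adjacent windows share
399 of 400 steps of their span, and the confirmatory inference is the
order-statistic p-value.

## Calibration and localization: what the synthetic checks show

Two property checks pin down what the scan can and cannot do.

*Type-I error.* Calibration of the Poisson model is assessed on null
synthetic data over ≥ 1000 *non-overlapping* windows. The 2 Mb region
holds only 50 non-overlapping 40 kb windows, so the calibration design
uses 500 bp windows with a null rate giving about 13 expected variants
per window. That rate was chosen analytically before any test was run:
the Poisson test is discrete, and its achievable size at the nominal 5%
level oscillates with the window rate; around 13 per window the rejection
threshold is stable to the jitter of the estimated global rate and the
achieved size is ≈ 0.043.

*Localization.* With a single 40 kb window whose rare-variant rate is
five-fold the background, at the study-scale rate of roughly 0.43
variants per kb cohort-wide, the top-ranked window by the ratio
statistic always overlaps the enriched window, and no window disjoint
from it attains the maximum — but the argmax is *not* localized to the
100 bp step grid, for two reasons. First, shifting a window by one step
trades an expected ≈ 0.2 enriched variants against ≈ 0.04 background
variants, so windows many steps away tie with or beat the aligned window
by one variant, and Monte-Carlo noise in the expected-density
denominator breaks exact ties arbitrarily. Second, and larger, the
denominator itself varies several-fold across windows with the local
common-SNP density (that is what the statistic is *for*: it normalizes
rare burden by common-variant opportunity), so when the density profile
slopes across the enriched neighborhood the ratio argmax is pulled up to
half a window toward the low-density side. Ranking by the raw count
(equivalently by Poisson p-value, since every window shares one rate)
localizes to within a few kb. The test suite asserts exactly these two
supportable resolutions — overlap for the ratio ranking, ±10 kb for the
count ranking — and the acceptance script additionally reports the
strict one-step recovery rate of the ratio ranking, which is low for
the reasons just given.

# Regulatory domains and ontology enrichment

Each gene's basal domain spans 5 kb upstream to 1 kb downstream of its
TSS, strand-aware. The extension per side is the distance to the nearest
neighboring basal domain boundary, capped at 1 Mb, clipped at position 1
and the chromosome end; a basal domain overlapping the gene's own
clamps the extension to zero on that side. A variant maps to *every*
gene whose extended domain contains it. The alternative reading —
assignment to the single nearest TSS — is available as
`mode = "nearest_tss"` (ties broken toward the first gene in annotation
order); which assignment a given historical gene count corresponds to is
not always documented, so both are provided and neither is privileged.

Enrichment of a gene set is the fraction of foreground variants mapping
to a set member divided by the same fraction among background variants
(background choice — progeny variants, whole genome, germline — is a
configuration input, not a package decision). The permutation null draws
10,000 foreground-sized samples from the background *variants* (the
variant, not the gene, is the exchangeable unit) without replacement
within a sample; the p-value is the fraction of samples whose enrichment
is *strictly* higher than observed (ties favor the null), censored at
1/n_perm at zero exceedances. In `ontology_enrichment()` one set of
permutation draws is shared across gene sets, which preserves each
marginal p-value and makes the q-values (Benjamini–Hochberg across sets;
the conventional choice where only an unspecified "FDR Q value" is
given) mutually consistent. A set is a *hit* when q < 0.01 and more than
ten distinct set genes are supported by foreground variants.

# Biomarker statistics

Nuclei are scored 0/1+/2+/3+ and aggregated to per-case percentages;
the biomarker readout is the percent of 3+ (strong) nuclei. Group
comparisons use one-way ANOVA followed by Tukey's HSD (studentized-range
distribution, via R's `TukeyHSD`); with two groups F equals the squared
pooled t statistic, which the suite checks to 1e-9. Case/control
discrimination fits a maximum-likelihood binomial GLM of the label on
percent-3+ (other bins can be added behind the formula by the user; the
single-predictor design is the default because the strong-staining bin
is the stated readout) and reports the ROC by threshold sweep with
trapezoidal AUC — identical to the Mann–Whitney rank statistic with
midrank ties, asserted to 1e-12. Complete separation is flagged but the
AUC remains defined.

The validation-cohort sizing uses the normal-approximation formula with
unpooled variances, `n = (z_{1-α/2} + z_{power})² (sd₁² + sd₂²) / Δ²`,
rounded to the *nearest* integer: with the discovery-set estimates
(means 3 and 14, sds 4 and 10, 90% power, two-sided 5% level) this gives
10.07 → 10 cases per group, whereas a ceiling convention would give 11.

Droplet-digital-PCR wells with fewer than 7,000 total droplets fail QC
and are excluded; the mutant fraction is mutant-positive droplets over
all allele-positive droplets pooled across passing wells, with an `NA`
sentinel when no well passes.

## IHC generator: censored, not truncated

Per-case percent-3+ is drawn from the group's normal distribution
**censored** to [0, 100] (mass outside the bounds collapses onto them),
not truncated. Censoring is deliberate on two grounds. First, realism: a
benign fallopian tube commonly has *no* strongly stained nuclei, so a
point mass at exactly 0% is a feature of real data, not an artifact.
Second, ROC behavior: censoring is a monotone many-to-one transform, and
with midrank tie handling the rank AUC stays at the binormal closed form
Φ(Δ/√(sd₁² + sd₂²)) ≈ Φ(11/√116) ≈ 0.846 up to a small tie correction,
whereas truncation (renormalizing the density inside the bounds)
reshapes the benign distribution enough to shift the AUC upward by
≈ 0.04 at these parameters. The remaining mass per case is split among
the 0/1+/2+ bins with symmetric Dirichlet(1,1,1) weights, the last bin
computed by subtraction so the four percentages sum to 100 exactly.

Default group parameters are the discovery-set estimates (benign 3 ± 4,
tumor-patient FTE 14 ± 10 percent) with validation-set cohort sizes
(46 and 42).

# What the generators do and do not emulate

The generators reproduce: Hardy–Weinberg genotypes at independent common
SNPs; rare variants as independent per-individual singletons at a
homogeneous rate with optional fold-enriched windows (defaults sized so
a 33-sample cohort carries on the order of 850–900 distinct rare
variants over 2 Mb, matching the scale of the study's targeted-sequencing
yield); islet call sets with root/private/germline strata; gene layouts
with uniform TSS positions; and censored-normal IHC scores. They do
*not* model linkage disequilibrium, indels or structural variants,
sequencing error or coverage variation, haplotype phase, clonal
phylogenies beyond a single root clone, or spatial correlation of gene
positions and ontology membership. Passing tests therefore demonstrate
that the statistical machinery is correct and calibrated under its own
stated assumptions — not that those assumptions hold in any particular
real cohort; in real data, LD between panel sites inflates the variance
(though not the mean) of the expected-density profile, and callability
differences between cases and controls are confounded with the ratio
statistic.

# Numerical and reproducibility choices

Coordinates are 1-based inclusive internally; BED's 0-based half-open
convention is converted only at the file boundary, and the conversion is
involutive. All simulators take explicit seeds, evaluated under a
save/restore of the caller's RNG state (`with_seed()`), and a fixed seed
gives bit-identical output. The pipeline derives per-stage seeds from a
single global seed by a fixed affine map modulo 2³¹ − 1, so stages are
independently reproducible and the whole run is byte-identical under a
fixed configuration. Problem sizes in the test suite (e.g. 2,000
simulations for Monte-Carlo closed-form checks, 100 seeded scan
replicates, 1,000 random gene layouts against the brute-force domain
oracle, 20,000 cases per group for the AUC check) were chosen so that
three-standard-error tolerances are decisive for the properties under
test.

# Known limitations

- The ratio statistic inherits the variance of its simulated
  denominator; with few common sites per window the Monte-Carlo noise is
  material, and windows with *no* common site are excluded from ranking
  rather than rescued.
- The order-statistic p-value has resolution 1/N (0.01 at the default
  100 subsets) and is censored below that; it cannot distinguish strong
  from very strong enrichment.
- The Poisson hotspot model assumes a homogeneous rate; real mutation
  rates vary with sequence context, which the generator does not emulate.
- Gene-set membership is taken as given (curated-evidence filtering is a
  preprocessing concern of the gene-set file); the package does not fetch
  or version ontologies.
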