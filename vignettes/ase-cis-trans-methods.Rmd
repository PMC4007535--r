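---
title: "Dissecting cis and trans regulatory variation from allele-specific signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting cis and trans regulatory variation from allele-specific signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asecis)
library(dplyr)
```

## The measurement problem

Expression differences between two genotypes can be caused by variants in
the gene's own regulatory sequence (*cis*) or by variants in diffusible
factors acting on it (*trans*). Inside an F1 heterozygote both alleles share
one cellular environment, so unequal expression of the two alleles
(*allelic imbalance*, AI) is evidence of cis variation. Following one allele
from the reference background into a foreign background exposes trans
variation, and comparing AI between two genotypes that carry the *same*
alleles in *different* backgrounds exposes cis-by-trans interaction.

Arrays measure alleles with SNP probe sets: perfect-match probes for each
allele (PM1/PM2) and mismatch (MM) probes, replicated at offsets -4/0/+4
around the SNP. Each probe has its own affinity, so a raw PM1/PM2 ratio
confounds allelic expression with probe chemistry. The design solves this
with genomic DNA hybridizations of the same genotypes: DNA carries known
allele dosage (0/1/2 copies), so the DNA allele ratio measures pure probe
affinity plus dosage, and every test below is a *difference of RNA and DNA
allele contrasts* in which affinities cancel.

The X-substitution design crosses five donor lines to a common reference
(`st e`): F1s (heterozygous everywhere), X-heterozygotes (heterozygous X in
a reference autosomal background), the substitution homozygotes (females
only; substitution males are genetically identical to X-heterozygote males)
and the reference homozygote. RNA is hybridized in 3 replicates x 2 sexes x
11 genotypes plus the 5 substitution-homozygote female genotypes (81
arrays); one female DNA control per homozygous and F1 genotype adds 11
arrays.

## The generative simulator

`sim_config()` / `simulate_experiment()` generate a complete synthetic
experiment with exactly this structure. Probe intensity is multiplicative:

    I(p, s) = exp(alpha_p) * (q_match + kappa * q_other + b) * exp(eps)

with fixed probe affinities `alpha_p ~ N(0, affinity_sd^2)`,
cross-hybridization fraction `kappa`, optical background `b` (1% of the base
signal) and log-normal noise whose SD depends on nucleic acid (RNA 0.15,
DNA 0.10 by default -- DNA hybridizations are cleaner). For DNA, `q` is
allele copy number; for RNA, per-copy expression composes the gene baseline
(`ln` intensity ~ N(log 300, 0.8^2)) with the truth table's effects. Because
the model is multiplicative, affinities are additive on the log scale and
cancel exactly in DNA-controlled contrasts -- the property the analysis
relies on, and the property the tests verify symbolically at
`kappa -> 0, noise -> 0`.

Choices a reader should know about:

* **Trans dosage.** A trans effect is defined as the effect of one
  heterozygous dose of the donor background (the F1 background). The
  X-heterozygote carries only the donor X, so it receives `x_trans_frac`
  (default 0.2, roughly the X's genome share) of the effect, and the
  substitution homozygote twice that. The cis-by-trans interaction is
  realized in the F1 background only, which makes the interaction contrast
  (C6 below) estimate it exactly.
* **Orientations.** Cis and interaction truths are recorded as the
  st e-minus-allele2 log difference, the same orientation the contrasts
  report; `effect_mean_cis < 0` emulates a systematic deficit of the
  reference allele. Trans truth is in the C3 orientation; the sex effect is
  female minus male.
* **Dosage compensation.** Hemizygous male X expression is fully
  compensated (the single copy is expressed at twice the per-copy rate), as
  in Drosophila; without this every X-linked gene would be artifactually
  female-biased by `ln 2`.
* **Sex-limited effects** are realized by zeroing one sex's effect for a
  fraction `frac_sex_limited` of drawn effects, emulating sex-limited
  expression of the underlying trans factors.
* **Missing sequence data** (`frac_missing_seq`) and monomorphic crosses
  (`frac_monomorphic`) are assigned per line-by-probe-set pair at random to
  exercise the discriminant fallback and the drop rules.
* **Slide factors** default to zero: the independent-error cell-means model
  deliberately ignores within-slide correlation, so nonzero `slide_sd` is a
  robustness knob (it makes within-slide contrasts conservative), not a
  default condition.

What the generator does *not* emulate: spatial artifacts, GC-dependent
background beyond the binned controls, saturation, batch structure, or any
mean-variance relationship (noise is log-additive at every intensity).
Passing tests on this generator therefore show the *statistical machinery*
is correct under its own assumptions; they do not certify behavior under
real-array pathologies.

## Normalization

**3' expression module.** For each perfect-match probe, the 5th percentile
(type-7, linear interpolation -- pinned for reproducibility) of the
mismatch/background probes with the same GC count on the same array is
subtracted; probe-set values are `ln(mean corrected PM + 100)`. The `+100`
guard tolerates negative corrected probes; a probe-set mean at or below
-100 is an error. The percentile is computed per array; computing it across
arrays is a documented alternative the implementation does not take. Note
the `+100` compresses log-ratios of weakly expressed genes (a gene at
intensity 300 sees roughly a 0.75 attenuation of its log fold change) --
this is inherent to the published estimator, and the overall-expression
contrasts inherit it.

**SNP module.** Per probe set and array, the mean intensity of each allele
class is log-transformed and centered by the array's median. The median is
taken over *probe-set-level* mean signals (one value per probe set), not
over the pooled class values: total target per probe set is conserved
regardless of zygosity, so the probe-set-level median is invariant to which
genotype sits on the slide, while a pooled-class median tracks how many
classes carry signal (homozygote arrays have two background classes of
three) and would shift every cross-slide contrast by roughly `ln 2`-scale
genotype offsets. The pooled-class variant remains available
(`slide_median = "classes"`) for comparison.

## Allele assignment

Where both parental bases are known, assignment is by sequence: identical
bases drop the cross (`NO_POLYMORPHISM`); a reference base matching neither
PM target drops it (`STE_MATCHES_NEITHER`); otherwise the reference-matching
PM probe is recorded. Where sequence is missing, a two-class linear
discriminant (equal priors, pooled covariance; engine `MASS::lda`) is
trained on the per-sample `(PM1, PM2)` log class means of the two parental
homozygotes, and the probe set is retained when leave-one-out parental
accuracy is 100% and either the F1 females project into the central band
between the centroids (half-width `0.5 * band_factor *` centroid distance,
`band_factor = 0.6`) or the parental projections are disjoint. The feature
space, priors and band are not dictated by the published description; they
are exposed as configuration with these defaults. Two points deserve
emphasis:

* The only allele2 homozygote in the design is the X-substitution
  homozygote, so the fallback is trainable for X-linked probe sets only;
  autosomal missing-sequence pairs drop as `MISSING_DATA_UNRESOLVED`. (A
  discriminant trained on two genotypes that are identical at the probe set
  can only separate them by noise; admitting such sets pollutes the
  reference-genotype cells with arbitrarily mapped signal.)
* Assignments are harmonized to one consensus reference probe per probe set
  (sequence beats discriminant, majority otherwise), because the reference
  base is a fixed property of the reference line; lines whose discriminant
  assignment conflicts with the consensus are dropped for that probe set.

## The heteroscedastic cell-means model

Per gene, normalized allele signals are modelled with one free mean per
cell -- allele x genotype x nucleic acid x sex -- and *separate pooled
residual variances* for RNA and DNA, each with `df = sum(n_cell - 1)`.
X-linked genes use female RNA only (males are hemizygous; no within-male
allelic contrast exists) and carry no sex index; DNA cells are never
sex-indexed (all DNA came from females) and are shared by both sexes'
contrasts. The X-heterozygote genotypes have no DNA of their own; the F1
DNA, with identical expected allele dosage, is their control.

Genes with several informative probe sets are considered jointly: each
probe set and allele class is centered by its mean over the samples shared
by *all* of the gene's probe sets, then pooled as replicates within cells.
Centering at class granularity matters: the two PM classes carry different
fixed affinity sums which cancel in every contrast but would otherwise sit
in the pooled residual and roughly double it, halving every F statistic.
Computing the centering means on the shared sample subset matters too:
probe sets informative for different line subsets otherwise see different
genotype mixtures, and genotype structure leaks into the offsets. Both
refinements were adopted after the package's own null calibration exposed
the miscalibration; `center = "probeset"` and `"none"` remain available.

The six contrast families (coefficients in `build_contrasts()`):

| family | estimand | scope |
|---|---|---|
| C1 | AI in F1 minus DNA dosage ratio (composite cis) | X females; autosomes both sexes |
| C2 | AI in X-het minus F1 DNA ratio (cis) | X females |
| C3 | st e allele, F1 vs reference background (trans) | X females; autosomes both sexes |
| C4 | st e allele, X-het vs reference background | X females |
| C5 | substituted allele, X-het vs substitution homozygote | X females |
| C6 | AI difference, F1 vs X-het (cis-by-trans) | X females |

Each test is `F = (estimate/se)^2` with
`se^2 = var_RNA * sum_RNA(c^2/n) + var_DNA * sum_DNA(c^2/n)` and
denominator df by Satterthwaite combination of the two variance groups; the
standardized effect is `estimate / sqrt(var_RNA)` (RNA noise is the
relevant sampling scale; a configuration switch could use another scale).
The reference-allele cell takes the positive coefficient, so genes whose
st e allele is lower yield negative estimates. P-values are
Benjamini-Hochberg adjusted *within contrast family*, pooled across lines,
sexes and chromosomes, at an FDR of 0.20 (chosen to balance type I and II
error in this design; the level is a parameter everywhere).

Known approximations: the centering constants are estimated but not
subtracted from the pooled df (a ~2% liberality of F at default sizes), and
the per-slide median couples observations on one slide (a same-order
effect, conservative for within-slide contrasts). Null simulation at 2,000
genes shows per-family p-value uniformity passing a Kolmogorov-Smirnov test
at the 0.01 level for all six families.

A gene's classification: cis if any C1/C2 is significant in any line (per
sex where testable), trans if any C3/C4/C5, and cis-by-trans only when a
significant C6 coincides with a significant C1/C2 *in the same line* -- an
interaction without a detectable composite cis effect is not counted.
Sex-limited classes (autosomes only) come from the per-sex flags.

## Overall expression

The 3' module is analyzed per probe set with a genotype-by-sex cell-means
model on RNA only (males and females are separate genotypes): substitution
contrasts (substitution homozygote vs reference; these read as cis tests
for X-linked genes and trans tests for autosomal ones), dominance
(X-heterozygote vs the midparent of the substitution and reference
homozygotes -- the only parent/progeny triple hybridized; females, since
substitution males have no heterozygous counterpart), a joint F-test of
equality of all genotype means (sex-averaged), and the average
female-minus-male difference over the two-sex genotypes. All
overall-expression contrasts share one pooled BH family. Gene-level sex
bias is called from the probe set with the smallest sex-effect q (ties to
the larger absolute estimate): female-biased if the female-minus-male
estimate is significantly positive, male-biased if negative.

## Association layer

`build_summary_tables()` assembles the three published table shapes
(per-contrast counts with half-up two-decimal percentages; sex-bias by
chromosome; sex-limited variation by sex-bias class, autosomes only, with
independence-expected counts always derived from the cells). The tests:
Pearson chi-square with expected counts; two-sided Fisher exact (p from the
hypergeometric via `stats::fisher.test`, odds ratio reported as the sample
`ad/bc`); McNemar on the male-only/female-only discordant counts without
continuity correction (the counts in play are large; the correction is a
switch); and Breslow-Day homogeneity of odds ratios across bias-class
strata oriented `[[both, female-only],[male-only, none]]`, with Tarone's
adjustment on by default. Chi-square, McNemar and Breslow-Day are
implemented from their textbook formulas (no base-R Breslow-Day exists) and
cross-checked in the tests against `chisq.test`, `mcnemar.test` and a
margin-preserving enumeration oracle.

One reproduction note: feeding the published sex-limited trans table
through this Breslow-Day gives p = 0.00615, which matches the published
bound "<0.006" only at its printed one-significant-digit precision; no
re-orientation of the same cells changes this (all 2x2 arrangements of four
cells give the same homogeneity test). The cis version gives p = 2e-15.
Also, the published cis table's cells sum to 8,913 although its caption
says 8,915; marginals here are always derived from cells.

## Problem sizes used in the checks

The packaged checks run the null calibration at 2,000 genes (300 X-linked,
1,700 autosomal -- the study's X share), effect recovery at 300 genes with
`frac_cis = 0.3`, `effect_sd_cis = 0.5` and cross-hybridization off (the
known attenuation `ln((e^d + k)/(1 + k e^d))/d ~ 0.90` at `k = 0.05`,
`d = 0.5` is a property of the array physics, not of the estimator), power
curves at 60 genes per condition, and qualitative-pattern runs at 200
genes. Unit fixtures are smaller. These sizes were chosen to estimate each
quantity within useful Monte-Carlo error while keeping a full run in
minutes on one core.

## A worked example

```{r example, eval = FALSE}
run <- run_ase_pipeline(
  sim_config(n_genes_x = 30, n_genes_auto = 170, seed = 1),
  out_dir = "ase_run"
)
glance(run)
run$tables$table1
autoplot(run$contrasts)
```

## Limitations

No shrinkage or empirical-Bayes moderation of the per-gene variances; no
mixed-effects modelling of probe sets; no array-image or CEL-level
processing; the interaction test uses the F1-vs-X-heterozygote allelic
difference form (a homozygote-vs-heterozygote alternative exists in the
literature of such designs but is not implemented); genome-wide counts from
the real deposited data are not reproduced -- only the arithmetic on the
published tables and the statistical properties of the method on synthetic
data are.
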