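---
title: "Methods: integrated miRNA expression and copy-number analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated miRNA expression and copy-number analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircnv)
```

## The analysis problem

Serially passaged tumor xenografts — here, Ewing's sarcoma series grown in
nude mice — are profiled on two platforms: miRNA microarrays (Agilent-style
feature tables carrying a *total gene signal* and *total gene error* per
probe and array) and array-CGH, whose segmentation output is reported as
signed cytoband intervals such as `+1q21.1-qter` or `-9p21.3`. The package
answers the joint question: which miRNAs are differentially expressed
between xenografts and non-tumor control cells, and how often does a
miRNA's genomic locus sit inside a gained or lost region in the same
samples?

The packaged study tables describe six xenograft series from five patients
(34 passages, of which 14 were also miRNA-profiled) plus two mesenchymal
stem cell controls, the conventional expression baseline for this tumor
type. Copy-number calls come in two layers: calls present in every passage
of a series, and calls restricted to specific passages; a sample's call
set is the union of both layers applicable to it.

## Detection, normalization, filtering

A probe is **detected** on an array when `signal / error >= 3`; a ratio of
exactly 3 is detected (the rule excludes only ratios *under* three). The
detection call is made on raw signals, before any transformation, because
the signal-to-error ratio is a property of the measurement, not of the
normalized scale.

Expression values are `log2(signal + offset)` followed by quantile
normalization between all arrays (each array's sorted values are replaced
by the across-array mean of sorted values; ties receive the mean of the
reference values at their ranks, which keeps the result invariant to
permutations of tied entries). The offset is not fixed by the upstream
protocol; the default of 1.0 stabilizes zero signals while perturbing
bright probes negligibly, and it is configurable.

Probes are then filtered: control probes are dropped; miRNAs detected in
no sample are dropped; and each remaining miRNA must exceed, on at least
one array, that array's negative-control floor, defined as
`mean + 1.5 * sd` of the negative-control probes' normalized expression.
The summary statistic for "negative-control expression" is not fully
pinned down by convention — we use the per-array arithmetic mean (standard
for this platform's QC and symmetric), with the median available as an
option. Filters run after normalization so that the floor and the probe
values live on the same scale.

## Moderated t-tests

With only two control arrays, per-miRNA variance estimates are unstable;
the package uses the empirical-Bayes moderated t-statistic. Each miRNA's
pooled two-sample variance $s_g^2$ (with $d_g = n_1 + n_2 - 2$ degrees of
freedom) is assumed drawn from a scaled inverse chi-square prior with
hyperparameters $d_0$ (prior degrees of freedom) and $s_0^2$ (prior
variance). The posterior variance
$\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ replaces $s_g^2$ in
the t-statistic, which then has $d_0 + d_g$ degrees of freedom.

The hyperparameters are estimated by moment-matching the log sample
variances: under the model, $\log s_g^2$ has a known mean and variance
built from digamma and trigamma functions, so the excess dispersion of the
observed log variances determines $d_0$ through a trigamma inverse (solved
by Newton iteration to relative tolerance 1e-10), and the centered mean
determines $s_0^2$. Two boundary conventions matter:

* if the observed dispersion does not exceed its pure-sampling
  expectation, the prior is degenerate: $d_0 = \infty$ and $s_0^2$ is the
  arithmetic mean of the sample variances (complete shrinkage; p-values
  revert to the normal distribution);
* $d_0 = 0$ disables shrinkage and reproduces the ordinary pooled
  two-sample t exactly, which the tests assert at machine precision.

Multiplicity is controlled by Bonferroni, `q = min(1, p * m)` — the
conservative choice matching the family-wise error framing of the original
analysis — with the Benjamini-Hochberg alternative available through
`stats::p.adjust` if a user prefers FDR control. A miRNA is *over*
(*under*) expressed when `q < 0.05` and its log2 fold change is positive
(negative). The unbalanced 14-vs-2 design is handled by the pooled-variance
formulation; no Welch variant is offered because the moderation model is
itself built on a common within-group variance.

## Presence/absence set logic

Group-level expression calls use the strictest reading of exclusivity: a
miRNA is *present* in a group only when detected in **every** sample of
the group and *absent* only when detected in **none**. miRNAs with mixed
patterns are excluded from exclusive sets and from the three-group
partition, but reported on a side channel rather than silently dropped.
This makes region membership invariant to sample order and keeps the seven
regions of the three-group partition disjoint by construction.

## Cytoband intervals and containment

Call strings are parsed into one of four scopes: whole chromosome (`+8`),
whole arm (`-17p`), single band (`-9p21.3`), or band range
(`-17q12-q21.32`, with `pter`/`qter` as terminal anchors). Ranges are
canonicalized to reference (pter-to-qter) order, so `-1p13.3-p31.1`
becomes the span p31.1 -> p13.3. A `(uncontinuous)` suffix is carried as a
flag; for containment the interval is treated as covering its full span,
because the internal gaps of such calls are not published at band
resolution.

Containment queries resolve band names against the packaged UCSC hg19
cytoband table (862 bands). A query finer than the reference falls back to
its nearest named ancestor (`5q32.1 -> 5q32`); a query coarser than the
reference spans all its sub-bands (`17q21` covers `17q21.1..17q21.33`). A
band is contained when its full coordinate span lies inside the
interval's span; band-range endpoints are inclusive, so `-Xq12-q26.3`
covers `Xq26.3`. The reference build is configurable; hg19 is packaged
because the band names used in this class of call tables are stable at the
band resolution employed.

Within one sample, a gain and a loss whose spans share a band are flagged
as a conflict; the integration counter treats such a locus as neutral (it
contributes to neither the gain nor the loss count) with a warning, which
preserves the invariant `gain + loss + neutral = n_profiled`. The packaged
tables contain no such conflict, which the tests verify.

## Integration counting and association

For each miRNA locus, the integration stage counts the profiled samples
whose call set shows a gain, a loss, or no change at the locus band. "No
change" is defined relative to the call set — an uncalled region is
neutral — because segmentation output, not probe-level ratios, is what
this analysis consumes. The association rule mirrors the asymmetric
narrative thresholds of this study design: an up-regulated or
xenograft-exclusive miRNA in a region gained in at least 1 sample is
`overexpressed_in_gain`; a down-regulated or control-exclusive miRNA in a
region lost in at least 2 samples is `underexpressed_in_loss`. Both
thresholds are configurable. Expression categories combine the exclusivity
calls with the moderated-t calls, with exclusivity taking precedence (an
miRNA undetected in every xenograft has no meaningful fold change).

## qPCR quantification

Validation by qPCR uses plain 2^-ddCt against the U6 endogenous control:
replicate Cts are averaged per sample and assay, per-sample
dCt = Ct(target) - Ct(U6), group dCt is the mean of per-sample dCts
(respecting the pairing of target and control within a sample rather than
pooling wells), and RQ = 2^-(dCt_group - dCt_calibrator). No
amplification-efficiency correction is applied — the method is exactly the
closed form, and the tests assert its algebraic identities (per-sample Ct
offsets cancel; swapping groups inverts RQ; log RQ is additive across
chained calibrations).

## The simulator: what it emulates, and what it does not

`simulate_mirna_arrays()` emulates the feature-table level of an
866-miRNA array: per-miRNA baseline log2 levels spread with SD 1.5 around
a mean of 8 (the dynamic range of expressed miRNAs), per-measurement noise
with SD 0.35 (typical replicate variability for this platform class),
total gene error equal to `0.1 * signal` with log-normal jitter, a
negative-control population whose signal/error ratio never reaches 3, and
a seeded 10% of background miRNAs that are off on every array. Planted
effects place group shifts (`over`/`under`), exclusivity patterns
(on in every xenograft, off in every control, or the reverse), or
copy-number-coupled shifts in randomly chosen carrier samples whose call
sets are emitted alongside. The default group sizes are the study design:
11 primary-tumor and 3 metastasis xenograft passages versus 2 controls.

The split between the two variance components is a modeling choice the
configuration exposes separately, because the downstream statistics depend
on them differently: between-miRNA spread only sets the rank structure of
the array, while within-sample noise drives the power of the moderated t.
With the defaults, a planted log2 shift of 2 in the 14-vs-2 design is
recovered at Bonferroni q < 0.05 with sensitivity above 0.9, which the
acceptance checks measure over 20 seeded replicates.

The simulator does **not** emulate probe-level image artifacts, dye or
spatial effects, batch structure, correlated miRNA families, or viral
probes. Passing recovery tests on simulated data therefore demonstrates
the correctness and calibration of the pipeline's statistics under its own
noise model, not robustness to every artifact of real arrays.

## Numerical choices and problem sizes

* Quantile-normalization equality of sorted per-array vectors is asserted
  to 1e-9 (double-precision accumulation across a few hundred probes).
* The trigamma inverse iterates Newton steps to relative tolerance 1e-10,
  capped at 50 iterations.
* Sample variances of exactly 0 (constant probes, which quantile
  normalization can produce at the rank extremes) are floored at 1e-12
  with a warning before log-variance moment matching; constant miRNAs
  yield t = 0, p = 1 rather than NaN.
* Null calibration is checked with 2,000 miRNAs per replicate in the
  14-vs-2 design: a Kolmogorov-Smirnov uniformity test on one replicate
  and the Bonferroni family-wise error rate over 500 replicates, compared
  against 0.05 plus 2.58 Monte-Carlo standard errors. Prior recovery uses
  5,000 genes; power uses 20 full simulate-preprocess-test replicates at
  the 866-miRNA array size. These sizes give stable Monte-Carlo estimates
  while keeping the whole suite under a minute.
* Dendrogram tie-breaking is made deterministic by ordering columns by
  sample id before clustering; constant profiles get the maximal
  correlation distance of 1 with a warning.

## Known limitations

* The three gain-side locus rows on 1q whose published counts disagree
  with the per-sample union of the call tables (printed 5 where the
  tables imply 6) reflect segment boundaries finer than the published
  band-level calls; they cannot be reproduced from band-level data and
  are documented as such rather than special-cased.
* Exclusive-set results at the published scale depend on the detection
  matrix of the original raw arrays, which were never deposited; the
  package reproduces the set *logic* (and its cardinalities when the
  published membership lists are encoded as a detection pattern), not the
  original detection calls.
* Whether the original "moderated t-test" implementation matched the
  empirical-Bayes estimator used here cannot be established from the
  published description alone; the package's estimator is validated by
  parameter recovery, null calibration, and agreement with the standard
  independent implementation of the same model.
* Copy-number status is band-resolution: a focal event smaller than a
  cytoband is invisible, and an "uncontinuous" range is treated as its
  full span.
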