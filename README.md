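# mircnv

Integrated analysis of miRNA microarray expression and array-CGH copy-number
data from serially passaged tumor xenografts.

Tumor xenograft series — here, Ewing's sarcoma grown in nude mice — are a
standard source of tumor tissue when primary material is scarce. When the
same passages are profiled on both an miRNA array and aCGH, a natural joint
question arises: which miRNAs distinguish the xenografts from non-tumor
control cells, and how often does each such miRNA's genomic locus lie in a
gained or lost region of the same samples? `mircnv` implements that analysis
as a tested, reusable pipeline for anyone working with Agilent-style miRNA
feature tables and band-level copy-number calls:

* **Detection and filtering** — a probe is detected when
  signal/error ≥ 3; probes are kept only if non-control, detected
  somewhere, and exceeding the per-array negative-control floor
  (mean + 1.5 sd) at least once.
* **Normalization** — log2(signal + offset), then quantile normalization
  between all arrays.
* **Moderated t-tests** — empirical-Bayes variance shrinkage: per-miRNA
  pooled variance s²_g with d_g df, prior (d₀, s₀²) estimated by
  digamma/trigamma moment matching, posterior variance
  s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g), t = Δmean / √(s̃²_g(1/n₁+1/n₂))
  on d₀ + d_g df, Bonferroni-adjusted q-values.
* **Presence/absence set logic** — exclusive sets (detected in *all*
  samples of one group, *none* of another) and the seven-region partition
  across three groups.
* **Cytoband-interval calls** — parsing of signed call strings
  (`+8`, `-17p`, `-9p21.3`, `+1q21.1-qter`, `-2q35-q37.3 (uncontinuous)`),
  anchored on the packaged UCSC hg19 cytoband table, with containment
  queries, conflict detection, recurrence classification, and BED export.
* **Integration** — per-miRNA counts of profiled samples with gain / loss /
  no change at the miRNA's locus, joined with expression categories into
  association calls.
* **qPCR** — 2^-ΔΔCt relative quantification against the U6 control.
* **Simulation** — a seeded generator of feature tables with planted
  effects (over/under expression, exclusivity, CNV-coupled shifts) and
  ground truth for end-to-end recovery testing.

The study tables the pipeline was built around (sample sheet with 34
xenograft passages of which 14 are miRNA-profiled, per-sample CNV call
sets, a 19-miRNA locus table, and the 46 xenograft-exclusive miRNA ids)
ship with the package as plain TSV fixtures.

## Worked example

```r
library(mircnv)

ref <- load_cytoband_reference()          # packaged UCSC hg19 band table
fx  <- load_study_fixtures(ref = ref)     # packaged study tables
profiled <- mirna_profiled_samples(fx)    # the 14 miRNA-profiled passages

tab <- build_integration_table(fx$mirna_loci, fx$cnv_calls, profiled, ref = ref)
head(tab[c("mirna_id", "cytoband", "gain_count", "loss_count",
           "neutral_count", "expression_category", "association")], 8)
#>   mirna_id cytoband gain_count loss_count neutral_count expression_category           association
#> 1  miR-137   1p21.3          0          2            12               other                  none
#> 2  miR-765   1q23.1          6          0             8               other                  none
#> 3  miR-557   1q24.2          6          0             8      exclusive_xeno overexpressed_in_gain
#> 4 miR-135b   1q32.1          6          0             8               other                  none
#> 5 miR-29c*   1q32.2          6          0             8               other                  none
#> 6  miR-215     1q41          6          0             8      exclusive_xeno overexpressed_in_gain
#> 7 miR-143*     5q32          0          2            12               other                  none
#> 8 miR-145*     5q32          0          2            12               other                  none
```

Each row counts, over the 14 profiled passages, how many carry a gain or a
loss covering the miRNA's cytoband: `miR-557` at 1q24.2 sits inside the 1q
gains of two series (6 gained samples) and is detected in every xenograft
but neither control (`exclusive_xeno`), so it is called
`overexpressed_in_gain`; `miR-137` at 1p21.3 lies in a band-range loss
carried by 2 metastasis passages.

Containment works directly on parsed calls:

```r
iv <- parse_call("-Xq12-q26.3", ref)
contains_band(iv, "Xq26.3", ref)   # endpoint bands are inclusive
#> [1] TRUE
```

The full pipeline (preprocessing → moderated t → sets → CNV → integration,
plus qPCR when a Ct table is configured) runs from a single config and
writes stage TSVs, a BED file of calls, and a JSON manifest:

```r
run_pipeline(pipeline_config(out_dir = "out"))
```

A thin command-line wrapper with subcommands (`run`, `simulate`, `cnv`,
`integrate`, `qpcr`, `report`, ...) is installed at
`system.file("cli", "mircnv.R", package = "mircnv")`.

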