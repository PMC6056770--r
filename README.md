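# cnvar — compartment-normalized variation for comparative proteomics

Quantitative proteomics of whole-cell or tissue lysates confounds two very
different kinds of change. A protein's abundance can move because the
*composition* of its compartment changed — or simply because the whole
organelle changed in number or size between the compared states (more
mitochondria in hepatocytes, smaller nuclei in a carcinoma line). Standard
differential expression treats both the same way, so genuine composition
changes are masked by, or mistaken for, gross morphology.

`cnvar` separates the two:

1. **Compartment shift detection.** Proteins are assigned to cellular
   compartments from GO cellular-component annotation (root terms plus
   their `is_a`/`part_of` offspring over an OBO ontology) or any custom
   grouping. For each compartment the distribution of log2 fold changes is
   compared against the whole proteome with a Mann–Whitney test; a
   significant displacement of the entire distribution (mean log2FC) is the
   signature of a morphological, compartment-wide shift.

2. **Compartment normalization (CNV values).** For each compartment, the
   averaged log2 abundances in the two conditions are related by ordinary
   least squares,

   *y*ᵢ = β₀ + β₁ *x*ᵢ + *e*ᵢ,

   with *x* the reference and *y* the test condition. A wholesale shift of
   the compartment is absorbed by the intercept β₀; what remains in the
   standardized residual

   CNV*ᵢ* = (*e*ᵢ − ē) / sd(*e*)

   is the protein's change *relative to its compartment's trend*. CNV
   values get two-sided normal-null p-values and Benjamini–Hochberg
   q-values. Models are kept only when the regression is significant
   (slope test, p < 0.05 by default) and small compartments
   (< 10 proteins by default) are skipped, never silently used.

3. **Comparison against standard differential expression.** A built-in
   empirical-Bayes moderated-t comparator (variance shrinkage with
   moment-matched prior, quantile-normalized input) lets you classify each
   protein at a q-threshold as `both`, `standard-only` (compartment-wide
   abundance change), `cnv-only` (composition change revealed only after
   normalization), or `neither`.

4. **Time-course mode.** For common-reference SILAC designs (ratio per
   protein per timepoint), the package computes Δ ratios against the first
   timepoint, per-timepoint CNV models (x = baseline, y = later timepoint),
   compartment trajectory tests, and protein-group (complex) tests in both
   the Δ and the CNV readout — the two dissociate when a complex merely
   rides a compartment-wide drift.

A seeded synthetic-data generator with ground truth (compartment shifts,
composition outliers, replicate noise, missingness) makes every step
testable without external downloads.

## Worked example

Simulate a two-condition experiment in which the mitochondrion loses ~56%
of its mass (−1.2 log2) while 2% of each compartment's proteins are true
composition outliers (±6 residual SD):

```r
library(cnvar)

spec <- simulation_spec(
  compartments = c(mitochondrion = 200, nucleus = 300,
                   cytoplasm = 400, extracellular = 150),
  delta = c(mitochondrion = -1.2), n_background = 1000,
  f_out = 0.02, gamma = 6, seed = 42)
sim   <- generate_dataset(spec)
m     <- filter_by_replicate_coverage(sim$matrix, c("A", "B"))
means <- average_replicates(m)

shift_report(means, sim$annotation, c("A", "B"))$results
#>    compartment n_proteins mean_log2fc median_log2fc      U        p significant
#>        nucleus        300    -0.00199       0.00169 337204 6.81e-03        TRUE
#>      cytoplasm        400     0.00539       0.03273 458328 1.88e-04        TRUE
#>  mitochondrion        200    -1.19821      -1.18070  28695 6.86e-90        TRUE
#>  extracellular        150     0.02570       0.01395 171985 1.52e-02       FALSE
```

The injected −1.2 log2 shift is recovered (mean log2FC −1.20,
p ≈ 7·10⁻⁹⁰). Note that against a whole-proteome background even unshifted
compartments can reach small p-values, because the shifted mitochondrion
drags the background itself; a `background = "complement"` option
excludes the tested compartment.

```r
cnv <- run_cnv(means, sim$annotation, c("A", "B"))
cnv$models
#>    compartment   n slope intercept    R2   model_p retained
#>      cytoplasm 400 0.985     0.372 0.951 1.52e-263     TRUE
#>  extracellular 150 1.017    -0.400 0.967 5.32e-112     TRUE
#>  mitochondrion 200 1.008    -1.407 0.950 2.40e-130     TRUE
#>        nucleus 300 1.005    -0.120 0.957 1.53e-205     TRUE
```

The mitochondrial shift shows up as the intercept (−1.4 ≈ −1.2 plus the
drawn residuals), the slope stays ≈ 1, and the fits are strong (R² ≈ 0.95).
The top mitochondrial CNV records:

```r
rec <- subset(cnv$records, compartment == "mitochondrion")
head(rec[order(rec$q), c("protein", "x", "y", "cnv", "p", "q")], 4)
#>  protein    x    y   cnv        p        q
#>   P00131 26.2 22.8 -4.97 6.59e-07 0.000132
#>   P00138 27.3 28.1  4.37 1.26e-05 0.001258
#>   P00032 26.5 27.2  4.05 5.06e-05 0.003376
#>   P00177 22.0 19.0 -3.94 8.04e-05 0.004021
```

All four are injected composition outliers — proteins whose abundance
moved *relative to the rest of the mitochondrion*, invisible in the raw
fold changes which are dominated by the −1.2 organelle shift.

```r
de <- moderated_ttest(quantile_normalize(m), c("A", "B"))
ov <- classify_overlap(de$records, cnv_protein_summary(cnv$records))
subset(ov$percentages, threshold == 0.1)
#>  threshold         class    n percent
#>        0.1          both   20    0.98
#>        0.1 standard-only  830   40.49
#>        0.1      cnv-only    0    0.00
#>        0.1       neither 1200   58.54
```

The large `standard-only` block is the compartment-wide / proteome-wide
signal the comparator sees but the CNV approach correctly discounts.

## Command line

```sh
Rscript inst/cli/cnvar.R simulate --outdir data/ --seed 3
Rscript inst/cli/cnvar.R compare --matrix data/abundance.tsv \
    --design data/design.tsv --groups data/groups.tsv \
    --conditions A,B --outdir results/
Rscript inst/cli/cnvar.R timecourse --matrix ratios.tsv --groups ann.tsv \
    --outdir results_tc/
```

`compare` writes `models.tsv`, `cnv_records.tsv`, `shift_report.tsv`,
`de_records.tsv`, `overlap_classes.tsv`, `class_percentages.tsv` and a
`run_log.txt` with the config hash; identical configs reproduce identical
files.

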