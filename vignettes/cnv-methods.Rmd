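---
title: "Compartment-normalized variation: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment-normalized variation: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvar)
```

## The problem

In unfractionated comparative proteomics, the measured change of a protein
mixes two signals: a change in the *composition* of its cellular
compartment, and a change in the compartment itself — more or fewer
organelles, larger or smaller ones. The second signal is collective: it
displaces the fold-change distribution of *every* protein annotated to the
compartment by roughly the same amount. Global normalization schemes
(median scaling, quantile normalization) assume no such structured shifts
exist and, when they do, redistribute them across the whole proteome,
producing spurious apparent regulation.

`cnvar` models the collective signal explicitly and removes it per
compartment, leaving a per-protein statistic for the composition signal
alone.

## The model

Let $x_i$ and $y_i$ be the replicate-averaged log2 abundances of protein
$i$ in the reference and test condition. For each compartment $c$ with
member set $M_c$ we fit by ordinary least squares

$$y_i = \beta_0^{(c)} + \beta_1^{(c)} x_i + e_i, \qquad i \in M_c .$$

Two assumptions are made and are user-checkable from the reported model
statistics:

* **Linearity.** Within a compartment, log2 abundances in the two
  conditions are linearly related. The fit's $R^2$ and the slope-test
  p-value are reported per compartment; a model is *retained* only when
  the regression is significant (`retention_p`, default 0.05). Records
  from non-retained models are still emitted but carry a `retained =
  FALSE` flag — they are never silently used, and non-linear alternatives
  are deliberately out of scope.
* **Shared trend.** Proteins of one compartment respond as a group; a
  wholesale multiplicative change of the compartment (log-additive in
  log2) is absorbed by $\beta_0$. This is exactly the invariance the
  package tests: adding $\delta$ to all test-condition values of a
  compartment changes $\beta_0$ by $\delta$ and leaves every residual —
  and hence every CNV value — unchanged, as does any affine map
  $y \mapsto a\,y + b$ with $a > 0$ applied compartment-wide.

The **CNV value** of protein $i$ is its standardized residual

$$z_i = \frac{e_i - \bar e}{\operatorname{sd}(e)},$$

with the $n-1$ standard deviation. "Standardized" here is plain
z-scoring; an internally studentized variant (leverage-corrected,
$e_i / (\hat\sigma\sqrt{1-h_{ii}})$) is available via
`studentized = TRUE` for users who prefer exact finite-sample scaling,
but the default matches the simpler and more common reading. Under the
null that a protein follows its compartment's trend, $z_i$ is treated as
standard normal: $p_i = 2\,(1 - \Phi(|z_i|))$, and q-values are
Benjamini–Hochberg adjusted.

Two deliberate choices here:

* **Direction.** $x$ is always the *first* named condition and $y$ the
  second, so a positive CNV value means "relatively more abundant in the
  test condition than the compartment trend predicts". The convention is
  arbitrary but fixed and documented.
* **Multiplicity scope.** q-values are adjusted *within* each compartment
  by default (`q_scope = "per-compartment"`), because each model has its
  own residual distribution; a pooled mode adjusts across all records
  jointly for users comparing across compartments. For per-protein
  summaries (overlap classification), a protein annotated to several
  compartments is represented by its minimum q and the compartment
  achieving it — each (protein, compartment) record otherwise stands
  alone.
* **FDR estimator.** BH is deterministic, assumption-light and slightly
  conservative. An empirical-null option (`p_mode = "empirical-null"`)
  rescales the z-scores by their median absolute deviation before the
  normal-null conversion; use it when heavy contamination visibly inflates
  the plain residual SD. Because BH is conservative relative to empirical
  local-FDR methods, borderline composition outliers (around 3–4 residual
  SD in compartments of ~1000 proteins) are detected with moderate, not
  high, sensitivity at q < 0.1 — the trade is a tightly controlled false
  discovery proportion. Stronger outliers (≥ 5 SD) are recovered nearly
  completely.

## Compartment shift detection

Before (and independently of) normalization, the package tests each
compartment's fold-change distribution against the whole proteome with a
Mann–Whitney test and reports mean and median log2FC (the mean is the
headline estimate). Defaults follow the conventions of this analysis
style: significance at $\alpha = 0.01$, the four major compartments
(nucleus, cytoplasm, mitochondrion, extracellular) analyzed by default
and ten (adding ER, Golgi, cell membrane, nuclear membrane, lysosome,
peroxisome) by request.

The background *includes* the tested compartment by default — the literal
"compartment vs whole proteome" contrast. This overlaps the two samples
and is therefore conservative for large compartments and, conversely, can
make *unshifted* compartments look significant when another large
compartment drags the background. `background = "complement"` excludes
the compartment; the choice is exposed because neither convention
dominates.

Mann–Whitney p-values are exact (permutation distribution) when the
combined sample is at most 20 without ties, otherwise the normal
approximation with tie-corrected variance and continuity correction is
used; with both samples constant and identical the p-value is defined as
1.

## The moderated-t comparator

The standard differential expression reference is a two-sample
empirical-Bayes moderated t: per protein the pooled within-condition
variance $s_g^2$ (with $d_g$ residual df from the *observed* replicates)
is shrunk toward a prior,

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},
\qquad \tilde t_g = \frac{\Delta_g}{\tilde s_g\sqrt{1/n_A + 1/n_B}},$$

referred to $t_{d_0+d_g}$. The hyperparameters $(d_0, s_0^2)$ are
estimated by closed-form moment matching on $\log s_g^2$ (digamma/
trigamma inversion; the trigamma inverse by Newton iteration, relative
tolerance $10^{-10}$). The limits behave as expected: $d_0 = 0$ is the
ordinary pooled t, $d_0 \to \infty$ fixes all variances at $s_0^2$. The
implementation is self-contained and is verified in the test suite
against an independent empirical-Bayes reference implementation.

Per the pipeline contract, quantile normalization is applied *before* the
comparator, while the CNV branch runs on raw averaged replicates — a
compartment shift is signal for CNV, not a normalization artifact to be
erased. Only the explicit benchmarking mode
(`normalization = "comparison-quantile"`) feeds both branches the same
quantile-normalized matrix, so that performance differences cannot be
attributed to different inputs.

At a q-threshold $\tau$ (0.05, 0.1, 0.25 by default) proteins classify as
`both`, `standard-only` (significant proteome-wide but on the compartment
trend: a compartment-wide abundance change), `cnv-only` (composition
change revealed only after normalization), or `neither`.

## Preprocessing

* **Coverage filter.** A protein is kept only if quantified in strictly
  more than half of the replicates of *each* compared condition — a
  literal reading of the rule, so 2 of 4 fails and 1 of 1 passes. The
  filter is monotone in the required fraction.
* **Quantile normalization** delegates to the limma implementation: ties
  get the mean of the tied ranks' rank-wise means, samples with fewer
  observed values are interpolated at their quantile positions, and
  missing entries stay missing.
* **Missing values are never imputed.** All downstream statistics use
  observed values only, with observation counts carried along.

## Annotation

The ten built-in compartments are rooted at their canonical GO
cellular-component terms (e.g. GO:0005739 for mitochondrion; the
extracellular compartment unions GO:0005576, GO:0031012, GO:0044421,
GO:0044420) and expanded by the offspring closure over `is_a` and
`part_of` edges of an OBO ontology — other relation types (e.g.
`regulates`) are excluded because only containment-like relations express
sub-localization. Obsolete terms are dropped; NOT-qualified GAF rows are
skipped; evidence codes are not filtered by default (a flag restricts to
chosen codes). A protein annotated to $k$ compartments enters all $k$
compartment analyses; `restrict_exclusive()` supports the robustness
check of rebuilding models from single-compartment proteins only, and
`compare_model_variants()` correlates the two runs' CNV values per
compartment. Isoform suffixes (`P12345-2`) can optionally be stripped and
merged. Any two-column (protein, group) table can replace GO entirely —
groups behave exactly like compartments downstream, which is how curated
organelle catalogues and protein complexes are handled.

Exact reproduction of annotation sets retrieved through other toolchains
is not attempted: propagation rules differ between retrieval routes, so
compartment membership may differ at the margin.

## Time-course mode

For common-reference SILAC designs the data are log2 ratios $r_t$ per
protein per timepoint, with the first timepoint the baseline. Three
readouts:

* **Δ ratios** $\Delta r_t = r_t - r_{\text{baseline}}$ (identically zero
  at baseline; proteins missing the baseline are excluded and counted).
* **Per-timepoint CNV**: the pairwise machinery applied with
  $x = r_{\text{baseline}}$, $y = r_t$; all invariances carry over per
  timepoint.
* **Trajectory tests**: per compartment, Mann–Whitney of the ratio
  distribution at $t$ vs baseline; per protein group (complex), unpaired
  Mann–Whitney of the members' values at $t$ against the first
  non-baseline timepoint, in *both* the Δ and the CNV readout, at
  $\alpha = 0.05$. The reference is the first non-baseline point because
  in Δ mode the baseline column is identically zero (a degenerate
  comparison); reporting both readouts side by side is intentional — a
  compartment-wide drift turns the Δ test significant while the CNV test
  stays null, and that dissociation is precisely the diagnostic for
  "the complex follows its organelle" versus "the complex changes
  composition". A paired variant exists behind a flag; the unpaired test
  is the default. Group spread (variance across members per timepoint)
  supports a stoichiometry-loss readout: one member departing from an
  otherwise stable complex shows an extreme CNV value without moving the
  group test.

## The synthetic-data generator

`generate_dataset()` draws, per protein, a baseline log2 abundance
$a_i \sim N(25, 2^2)$ (an iBAQ-like scale: a wide, roughly normal log2
intensity distribution), then sets the test condition to
$b_i = a_i + \delta_{c(i)} + \varepsilon_i + o_i$ with compartment shift
$\delta_c$, residual $\varepsilon_i \sim N(0, \sigma_{\text{res}}^2)$,
and outlier offsets $o_i = \pm\gamma\,\sigma_{\text{res}}$ for exactly
$\operatorname{round}(f_{\text{out}} n_c)$ proteins per compartment, signs
alternating so the fitted slope stays unbiased. Replicates add
$N(0, \sigma_{\text{rep}}^2)$; missingness is applied last, MCAR by
default with an optional left-censoring mode (off by default so null
calibration stays clean, since abundance-dependent missingness biases
compartment means). Defaults — $\sigma_{\text{res}} = 0.3$,
$\sigma_{\text{rep}} = 0.2$, three replicates per condition, a 200-protein
compartment over a 2000-protein background for shift studies — are the
package's standard study conditions and are what the acceptance script
re-uses. `generate_timecourse()` analogously layers per-compartment drift
schedules and per-protein trajectory effects on baseline ratios
$\sim N(0, 1)$.

What the generator does *not* emulate: peptide-level sampling and
roll-up, fold-change compression, correlated (batch) replicate noise,
compartment-dependent abundance ranges, and annotation error (every
simulated protein's compartment is known exactly). Tests passing on this
generator therefore demonstrate the statistical machinery — invariances,
calibration, power under clean conditions — not performance on real data,
where annotation noise and structured missingness will lower sensitivity.

## Numerical choices and edge cases

* Degenerate fits: fewer than 3 points or constant $x$ are errors;
  compartments below `min_fit_size` (default 10, because model statistics
  from tiny organelles are unreliable) are skipped with a report entry.
* A perfect fit leaves residuals at rounding-error scale; residual SDs
  below $10^{-10}\max(1, \operatorname{sd}(y))$ are treated as zero and
  the CNV values returned as not computable (`NA`) with a warning rather
  than as amplified noise.
* Ties in the rank tests use midranks; the exact/approximate switch is at
  combined $n \le 20$ without ties.
* All simulations are seeded; identical configs produce byte-identical
  output files (the run log carries a hash of the configuration,
  excluding the output path).
* Problem sizes in the test suite (compartments of 100–2000 proteins,
  20–100 seeds per property) were chosen to make distributional
  assertions stable at the asserted thresholds while keeping the default
  run quick.

## Known limitations

* The method needs accurate localization annotation; poorly annotated
  organisms and proteins with wrong or missing compartments fall outside
  its reach, and it is not a tool for *building* organelle catalogues.
* Compartments represented by few proteins yield unstable models; they
  are skipped below the size floor, and retained-but-weak models should
  be judged by their reported $R^2$ and p-value.
* The normal null for CNV p-values is an approximation; heavy-tailed
  residual distributions inflate tail p-values (partly addressed by the
  empirical-null mode).
* Only simple linear per-compartment models between two conditions are
  supported — no robust/non-linear regression, no joint models across
  more than two conditions (time courses are handled pairwise against the
  baseline).
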