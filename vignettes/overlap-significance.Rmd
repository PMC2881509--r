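---
title: "Scoring gene-list overlaps against a hypergeometric null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring gene-list overlaps against a hypergeometric null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overlapEnrich)
```

## The question and the model

Two transcriptomics experiments each produce a list of upregulated genes.
If the underlying biology is shared — say, an engineered stromal cell
model and micro-dissected tumor stroma from patients — the lists should
share more members than two arbitrary lists of the same sizes would. The
package quantifies "more than arbitrary" with the classical sampling-
without-replacement null: fix list X of size $|X|$ inside a universe of
$N$ genes; draw a uniformly random subset of size $|Y|$; the overlap $K$
is hypergeometric, and the reported p-value is the upper tail at the
observed overlap $k$,

$$
P(K \ge k) \;=\; \sum_{j \ge k}
  \frac{\binom{|X|}{j}\binom{N-|X|}{|Y|-j}}{\binom{N}{|Y|}} .
$$

The upper (enrichment) tail is the right reading for this workflow: a
large observed overlap yields a small p-value. The same statistic scores
single intersections (`intersect_lists()`), every region-defining pair in
a Venn summary, and every gene set in a GMT collection scan (`enrich()`)
— the enrichment scan is pure overlap counting, deliberately not a
rank-based statistic.

Three modelling choices the user should be aware of:

* **Universe.** $N$ is caller-supplied, defaulting in the pipeline to the
  union of gene identifiers present in the expression input. The null is
  only coherent if both lists are subsets of the universe, so list
  members outside it are *dropped with a logged count* rather than
  silently inflating $N$. A too-large universe deflates p-values; when in
  doubt, use the measured genes, not the genome.
* **Independence.** The null treats Y as a uniform random set. Lists
  built from correlated experiments (shared samples, shared platform
  biases) violate this and can overlap "significantly" for uninteresting
  reasons. The p-value ranks overlaps; it is not a posterior probability
  of shared biology.
* **Harmonization.** Before any set operation, symbols are uppercased
  (so mouse-convention `Col1a1` meets human `COL1A1`) and optionally
  translated through a user-supplied two-column ortholog map; unmapped
  identifiers are dropped and counted. Uppercasing is a pragmatic
  convention, not true orthology — a curated map is better whenever one
  exists.

## Upregulation testing

Per gene, a one-sided two-sample t-test of case > control on log2
expression. Welch's unequal-variance form is the default because the
cohort designs this targets are unbalanced (53 vs 38, 11 vs 42 samples);
`var_equal = TRUE` gives the pooled form, and on balanced designs the two
nearly coincide. Up-lists take genes with $p < \alpha$ strictly
(default $\alpha = 0.05$), optionally also requiring a fold-change ratio
$2^{\bar{x}_\text{case}-\bar{x}_\text{control}} >$ a threshold.

* **Fold change** is the difference of log2 group means, reported also as
  the linear ratio; thresholds like "FC > 2.0" are applied on the ratio
  scale. Whether published thresholds of this kind are linear- or
  log-scale is often unstated; the ratio-scale reading is the stricter
  and more common one, and both the list-building and the heatmap
  thresholds are explicit arguments, not constants.
* **No multiple-testing correction by default.** The workflow this
  reproduces thresholds raw p-values, so the default matches it; a
  Benjamini–Hochberg flag exists (`adjust = "BH"`) for users who want
  FDR control, and then the threshold applies to the adjusted value.
* **Degenerate genes** (zero variance in both groups) get p = 0.5 when
  the means are equal, p = 0 (case above) or p = 1 (case below)
  otherwise, and are flagged. This keeps them rankable without a
  variance-floor heuristic.
* **Two-stage thresholds.** The heatmap selection step
  (`heatmap_selection()`) deliberately takes its own fold-change/alpha
  pair, separate from the list-building pair, because published
  cross-study heatmaps commonly filter the displayed genes more
  stringently than the overlap step that produced them; making both
  explicit avoids guessing a single rule.

## Numerical choices

The tail sum is accumulated in log space from `lchoose` terms with a
log-sum-exp reduction, then clamped at 1 to absorb last-bit roundoff.
This is exact to ~1e-15 relative against exhaustive subset enumeration
for every configuration with $N \le 13$ (and matches an independent
implementation over the full grid to $N \le 25$), and stays finite and
monotone at genome scale ($N \approx 2\times10^4$, overlaps in the
thousands), where naive binomial coefficients overflow. Extremely deep
tails can underflow double precision to 0; mathematically the p-value is
always positive. Enrichment tables sort by ascending p with ties broken
by larger overlap then set name, so output files are byte-deterministic.

## What the simulator emulates — and what it does not

`simulate_study()` draws log2 intensities $x_{gs} = \mu + \delta_g
\cdot 1[s \in \text{case}] + \varepsilon_{gs}$ with independent Gaussian
noise $\varepsilon_{gs} \sim N(0, \sigma^2)$, $\delta_g$ equal to
`effect` for a planted subset of genes and 0 otherwise. Defaults:

| parameter | default | units | rationale |
|---|---|---|---|
| `n_group1`, `n_group2` | 25, 25 | samples | the balanced metastasis-style contrast; 53/38 and 11/42 are the other cohort shapes of interest |
| `noise_sd` | 0.5 | log2 | a typical per-gene microarray SD after summarization |
| `effect` | 2.0 | log2 | a 4-fold shift — a strong, clearly recoverable signal |
| `frac_up` | 0.34 | fraction | ratio of a ~6,800-gene up-list to a ~20,000-gene array universe, the regime the real contrasts operate in |
| `shared_frac` | 0.5 | fraction | half the planted module shared between paired studies |
| `baseline_hyper_sd` | 0 (off) | log2 | optional Gaussian spread of per-gene baselines |

`simulate_paired_studies()` plants `round(shared_frac * n_up)` common
genes and disjoint remainders, with independent noise streams per study
(sub-seeds derived deterministically from the single global seed, so a
config + seed is bit-reproducible).

The generator emulates *already-summarized* expression: there are no
probe effects, background correction, normalization artifacts, batch
structure, gene–gene correlation, or heavy-tailed noise. Its per-gene
variance is homoscedastic by design, because the downstream statistic is
a per-gene t-test and nothing in the emulated studies' public record
constrains an error model. Consequently a green simulation-based test
establishes that the *pipeline arithmetic* is right — recovery of planted
truth, calibration of the null — not that the t-test is optimal for any
particular platform's noise.

Two published operating points anchor the defaults. First, with
`frac_up = 0` the fraction of genes flagged at $\alpha$ converges to
$\alpha$ (verified within 3 binomial SDs over 20 seeds), and intersection
p-values of two independent null up-lists are super-uniform. Second, at
the default operating point (effect 2.0, noise 0.5, 25 vs 25), up-list
recall of planted truth is ≥ 0.95 and the false-discovery fraction stays
near its expected value $0.05(1-f)/(0.05(1-f)+f) \approx 0.09$ for
$f = 0.34$ — note this bound is only attainable at all because $f$ is
large; rare-signal regimes need the BH flag.

## Curated panels

Five small panels transcribed from published cross-tabulations ship as
plain-TSV fixtures (three collagen panels, a glial panel, a proteomics
panel), with the printed p-value strings carried verbatim alongside
parsed floats, and the published bold membership marks stored as an
explicit logical column. `cross_tabulate()` *recomputes* flags from a
reference list, so the fixture flags act as a regression oracle and any
synthetic list can be cross-tabbed the same way. Blank p-value cells in
the multi-column panels are stored as missing (`NA`) — the source tables
do not distinguish "not tested" from "not significant", and the fixtures
do not invent that distinction. The panel p-values derive from external
patient cohorts and are *not* regenerated by this package.

The reference membership set behind the collagen bold flags
(`load_fixture_reference()`) is reconstructed from the printed flags
because the full upstream list is unpublished; it is exactly sufficient
to reproduce the printed 24/35, 12/16 and 1/1 counts, and is labelled as
a reconstruction in its file header.

## Known limitations

* The headline intersections of the motivating study (p = 1.6×10⁻³,
  1×10⁻³, 4.6×10⁻⁶, 9×10⁻⁵ over lists of 6,777/3,354/1,182 genes) cannot
  be recomputed here or anywhere: the universe size and the second list's
  size were never published. The package asserts nothing about them.
* Hypergeometric p-values across many sets in `enrich()` are reported
  raw by default (matching the emulated analysis); with hundreds of sets
  the minimum of many super-uniform draws is small by construction —
  use `adjust = "BH"` when the question is discovery rather than
  reproduction.
* `venn_regions()` supports 2 or 3 lists; higher-order partitions are out
  of scope, as is any graphics rendering (outputs are count tables).
* The one-sided test direction is fixed as case > control; swap the
  labels to test the other direction (the p-values map to their
  complements).
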