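---
title: "Models and methods behind riceseedtx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind riceseedtx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riceseedtx)
```

riceseedtx reimplements the analysis stack of a developing-rice-seed
transcriptome study as composable, tested functions. This vignette explains
the statistical models, the choices the package makes where the procedure
was genuinely open, what the synthetic-data generators emulate, and what
the passing tests do and do not demonstrate about real data.

## Detection calls and the expressed-gene rule

Probe-level detection algorithms operate on 25-mer probe pairs; this
package works at the gene level, where only the Present/Absent *labels*
matter downstream. `detection_call()` therefore applies a threshold rule:
Present where the log2 value strictly exceeds either a per-array quantile
(default mode, q = 0.30) or an absolute log2 cutoff (default 6.0). The
quantile mode adapts to each hybridization's intensity distribution, the
way rank-based detection scores do; strict inequality makes a degenerate
all-equal array all-Absent rather than arbitrarily split.

A gene is *expressed in a group* only when Present in **all** replicates of
that group — the conservative replicate rule — and expressed in a scope
(e.g. "seed" = all embryo plus endosperm groups) when expressed in at least
one group of the scope. "All replicates" rather than "two replicates" keeps
the rule sensible for designs with more than two replicates.
`expressed_percentage()` rounds shares of detected genes to whole percent,
the precision used in printed summaries (22,051 of 31,451 detected genes
gives 70%).

## Normalization and QC

Gene-level quantile normalization (`quantile_normalize()`) replaces each
column by the common distribution given by the row-wise mean of sorted
columns, with ties resolved by averaging bracketing target values; it is
idempotent and rank-preserving, and stands in for probe-level
multi-chip normalization, which needs raw probe intensities this package
does not consume. Replicate QC (`replicate_qc()`) is the whole-array
Pearson correlation between the two replicates of each sample group.
Z-scores use the sample (n−1) standard deviation; constant genes map to
zeros rather than errors so heatmap preprocessing never aborts.

## The moderated contrast

`fit_contrast()` computes, per gene, the difference of group means, the
pooled within-group variance $s_g^2$ on $d_g = n_A + n_B - 2$ degrees of
freedom, and the scale factor $v = 1/n_A + 1/n_B$. `moderate()` shrinks the
variances with the standard empirical-Bayes construction: marginally
$s_g^2 \sim s_0^2 F(d_g, d_0)$, so with
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$,

$$\mathrm{E}[e] = \log s_0^2 - \psi(d_0/2) + \log(d_0/2), \qquad
\mathrm{Var}[e] = \psi'(d_g/2) + \psi'(d_0/2).$$

The prior degrees of freedom $d_0$ come from inverting the trigamma
function on the excess variance of $e$ (Newton iteration, tolerance
1e-8, at most 50 steps); when the observed log-variances are *less*
dispersed than sampling alone predicts the excess is non-positive, $d_0$
is infinite, and every gene uses the common prior variance. The posterior
variance $\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ yields
$t_g = b_g / \sqrt{v\,\tilde s_g^2}$ on $d_g + d_0$ degrees of freedom.
The test suite verifies this implementation against limma's `eBayes` to
1e-10 on random data — limma is the cross-check, never the engine.

Numerical conventions: genes with exactly zero sample variance get a floor
of 1e-8 (all-zero variance degenerates to an ordinary t on the floor, with
a warning); p-values are clamped away from exact zero so −log10 transforms
stay finite. Note that the homoscedastic "all $s_g^2$ equal" limit
reproduces the ordinary t only once $d_g$ is large enough that the
log-variance bias correction $\exp(\log(d_g/2) - \psi(d_g/2))$ is close to
one; at $d_g = 2$ the moment estimator (identically in limma) reports
$s_0^2 \approx 1.78\,c$ by design of the log-scale correction.

## Thresholds and calls

`default_thresholds()` fixes the stringency settings: predominance at
FDR-adjusted p < 0.0005 **and** log2 fold > 1 (linear ratio > 2, positive
direction = higher in the seed tissue); time-course regulation at raw
p < 0.001 (deliberately *not* FDR-adjusted — exposed as a config choice);
cold regulation at raw p < 0.05 and |log2 fold| > 1, two-sided. "Change
ratio > 2" is interpreted on the log2 scale as |log2FC| > 1; whether the
original filter averaged on the linear or log scale is not stated, and the
log-scale reading is the one consistent with the linear-model estimates.

The predominance reference group is the union of root, leaf, seedling and
ovary samples, and the tissue group pools all stages of embryo (or
endosperm) — the contrast that matches how seed tissues are compared with
vegetative references throughout this kind of study. The exact design
matrix of the original analysis is not recoverable; this reference-group
choice is a documented assumption, not an inference.

`anova_timecourse()` is the fixed-effects one-way F over stage groups
(verified against `lm`/`anova` on a thousand random instances); direction
is the sign of last-stage minus first-stage mean. Equal means with zero
noise give F = 0 and p = 1 by convention; zero within-group variance with
real separation gives p = 0 rather than a silent infinity.

`bh_fdr()` is the plain step-up estimator
$q_{(i)} = \min_{j \ge i} m\,p_{(j)}/j$, capped at 1, verified against a
brute-force implementation and `p.adjust`.

## Enrichment

`chisq_enrichment()` builds, per category, the 2×2 table of set membership
against term membership over an explicit background and applies the
Pearson chi-square *without* continuity correction — the convention of the
tools of that era — flagging tables with any expected count below 5 rather
than silently switching tests (`exact_fallback = TRUE` opts into Fisher's
exact p for those). Enrichment is one-directional: depleted terms carry a
"not enriched" marker (rendered `-` on disk) in `enrichment_matrix()`, so
the terms × sets −log10 p matrix mirrors printed enrichment tables. The
background defaults to the genes of the analysed (filtered) matrix; a
whole-genome background is a config option, since either choice is
defensible and the original is unstated.

## Promoters and cis-elements

`extract_upstream()` takes "up to 3000 nt upstream of the translation
start": plus-strand genes get genomic bases $[\max(1, s-L), s-1]$,
minus-strand genes the reverse complement of $[e+1, \min(\text{contig},
e+L)]$, truncated only at contig boundaries — deliberately *not* clipped at
neighbouring genes. Promoters are reported 5′→3′ on the gene's sense
strand. The translation start is the CDS start when CDS features exist,
else the gene boundary. Coordinates are GFF3 1-based inclusive throughout.

`scan_motifs()` compiles IUPAC patterns to character-class regular
expressions and counts overlapping matches (look-ahead scanning) on the
promoter and its reverse complement. An `N` in the *sequence* matches
nothing except the pattern letter `N` — a conservative reading for masked
genome positions. The scanner is validated position-by-position against a
brute-force oracle.

`motif_enrichment()` compares, per element, the fraction of group genes
whose promoter contains at least one occurrence with the fraction in the
universe — gene-level presence, the only construction compatible with a
"ratio of genes vs the whole genome" chi-square — with BH-FDR across the
library and an enriched call at q < 0.05. An occurrence-count mode (total
hits over total scanned windows) is available as an option.

## Co-expression and the TF network

`pcc_profiles()` correlates each transcription factor with every gene
across a compendium filtered of all-Absent genes; zero-variance genes are
excluded with a warning and self-correlations never enter.
`top_k_neighborhood()` keeps the k = 500 most *positively* correlated
genes (negative-correlation ranking is intentionally not used; |PCC| mode
is a config flag), with ties at the boundary broken by ascending gene id —
determinism is mandatory for testing. `annotate_tf()` runs category
enrichment per neighborhood with BH-FDR per TF, and `build_network()`
draws a TF→term edge at q < 0.05 — a chosen convention, consistent with
the cis-element FDR rule, since no edge threshold is published for such
network figures.

## What the generators emulate

`simulate_compendium()` produces log2 values
`baseline + planted offsets + noise` over the 12-sample × 2-replicate
development layout:

* **Variance prior**: gene noise variances are scaled inverse-chi-square,
  $\sigma_g^2 = d_0 s_0^2 / \chi^2_{d_0}$, defaults $d_0 = 8$,
  $s_0^2 = 0.02$ — replicate standard deviations near 0.14, matching the
  very high replicate correlations (>0.99) good arrays show. A heavy-tail
  contamination switch (5% of residuals tripled) exists for robustness
  experiments.
* **Absent fraction** 0.30, mirroring the roughly one third of gene models
  never detected on a genome array (31,451 of 46,857 detected), drawn from
  a background distribution (mean 4, sd 0.5) well below the expressed
  baseline (truncated normal, mean 8.5, sd 1, minimum 6.5). The default
  30% detection quantile is calibrated to this mass: the per-array cut
  falls in the gap between the absent and expressed modes, so detection
  separates the two almost perfectly.
* **Predominance effects** +2 log2 (4-fold) added to all samples of the
  target tissue(s); classes (embryo / endosperm / both) are disjoint by
  construction, with fractions 0.045 / 0.035 / 0.012 approximating the
  observed prevalence of predominant genes.
* **Time-course effects** traverse 4 log2 units (16-fold first-to-last
  stage) through stage offsets centred on zero — centring keeps regulated
  genes from doubling as tissue-predominant, preserving disjoint truth
  classes. The 16-fold swing is typical of developmental regulation
  (storage-protein and cell-cycle programs swing far more) and was chosen
  once, a priori, by a power computation: the 4-stage × 2-replicate one-way
  F at p < 0.001 has only (3, 4) degrees of freedom, so smaller swings
  (e.g. 4-fold) sit near 30–50% power no matter how clean the assay —
  a genuine property of this design, worth knowing when interpreting
  recovery rates.
* **Cold experiment**: two cultivars (one cold-tolerant, with effects
  attenuated by 0.5), treated at 4 or 10 DAF with chronologically matched
  controls; planted counts default to 150 down / 50 up at the early stage
  and 75/75 later, the early-stage repression asymmetry characteristic of
  chilled young seed. Effects are additive on log2 and applied only to
  treated samples.

`simulate_coexpression_collection()` gives each module's TF a unit-variance
profile across arrays and sets members to
$\rho\,z_{TF} + \sqrt{1-\rho^2}\,\varepsilon$ so the expected member–TF
correlation is exactly $\rho$ (default 0.8). Module seed profiles are
centred and orthogonalized: planted modules represent distinct regulatory
programs, and without orthogonalization the chance TF–TF correlation at 60
arrays (±0.13) leaks each module's members into other TFs' neighborhoods.

`simulate_promoters()` writes a one-contig-per-gene genome (half the genes
on the minus strand) with i.i.d. background at the stated GC and plants
exactly one concrete instance of the chosen IUPAC motif per designated
target, at a uniform position and strand. Round-tripping through FASTA +
GFF3 and `extract_upstream()` recovers the planted promoters byte for
byte.

What the generators do **not** emulate: probe-level intensities, spatial
artifacts, batch and dye effects, correlated gene programs outside the
planted structure, GO-term overlap/DAG structure, and promoter sequence
composition beyond i.i.d. background. Passing recovery tests therefore
demonstrate that the *inference machinery* is correct and calibrated under
its stated model, not that real arrays meet those assumptions.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run at deliberate desk scale:
5,000-gene compendia, 2,000-gene co-expression collections with five
50-member modules over 60 arrays, 1,000 promoters of 500 nt over 100
replicates, 10,000-gene null simulations — sizes at which every Monte-Carlo
bound in the suite is comfortably stable. All randomness flows from
explicit seeds (default 17); the pipeline writes a JSON manifest with the
config hash and seed, and rerunning any pipeline with the same config and
seed reproduces every output file byte for byte.

## Known limitations

* Single-factor contrasts only: no multi-factor designs, random effects,
  spline time courses or surrogate-variable correction.
* GO terms are treated as flat sets — no true-path propagation up the
  ontology graph, and no gene-length or expression bias correction in
  enrichment.
* The scanner is exact-match IUPAC; no PWM scoring, de novo discovery or
  conservation filtering.
* Detection and normalization are gene-level stand-ins for probe-level
  algorithms; raw CEL-style inputs are out of scope by design.
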