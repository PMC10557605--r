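---
title: "Methods: context-aware variant-to-gene mapping from single-cell multiome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: context-aware variant-to-gene mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cremap)
```

`cremap` connects GWAS risk variants to candidate susceptibility genes
and disease-relevant cell types using barcode-matched single-nucleus
chromatin accessibility and gene expression. This vignette explains the
models behind each stage, the parameters that matter, the synthetic
data the package tests itself against, and the design choices made
where the methodology was genuinely open.

## Candidate causal variants

A locus's credible variants are compiled from summary statistics and
LD. The likelihood of a variant relative to the lead is approximated
through the 1-df chi-square quantiles of the two-sided p-values,

$$ LR = \exp\left(\tfrac{1}{2}\left(\chi^2_{variant} - \chi^2_{lead}\right)\right), $$

and variants with $LR \ge 10^{-3}$ (the 1:1000 rule) or $R^2 > 0.8$ to
the lead are retained; independent conditional signals enter as
singletons. Ties at either threshold are resolved inclusively ($\ge$,
with $R^2$ rounded to 6 decimals first), which makes the boundary
deterministic. Loci whose CCV footprints share any base pair are
merged. Both rules are monotone: relaxing a threshold never removes a
member, and the lead is always kept.

## The cCRE atlas and the quartile specificity rule

Peaks are annotated with the precedence promoter > exonic > intronic >
intergenic; the promoter window is TSS ± 3,000 bp. Variant positions
are 1-based and peaks are BED-style half-open, so a variant overlaps a
peak iff $start < pos \le end$ — the conversion happens in exactly one
place (`colocalize_ccvs`) to avoid off-by-one drift.

Specificity: a peak detected in one cell type belongs to that type; a
peak whose detected types share one category belongs to that category;
otherwise each category whose detected count strictly exceeds
$0.75\,n_c$ is assigned, with ties assigning several categories. For
the default 23-type taxonomy (8 epithelial, 7 immune, 4 endothelial,
4 stromal) the strict thresholds are 6, 5.25, 3 and 3. The rule's
description also mentions a 25th percentile; the only worked case pins
down the 75th-percentile criterion alone, so assignment uses only the
upper threshold and the package records categories below $0.25\,n_c$
in a `depleted` field without acting on it. A locus receives a category
only if every colocalized cCRE is assigned solely to it (unanimity;
a majority variant is available as an option).

## Allele-specific TF binding

Motif scoring uses information-content-weighted log-odds:
position $i$ contributes $IC_i \log_2(p_i(b)/bg(b))$, and the summed
score is min–max rescaled against the motif's attainable extremes so
the consensus scores exactly 1 and the anti-consensus exactly 0. The
best match per allele maximizes over all placements covering the
variant on both strands. The match p-value is the probability, under
the background base composition, of a random k-mer scoring at least as
high; for motifs up to 10 bp it is computed exactly by dynamic
programming over the full attainable-score support (deduplicated outer
sums), and for longer motifs by a lattice DP at $10^{-4}$ of the score
range, documented as approximate near ties. A reportable site needs
match p ≤ 1e-4; an allelic call needs |Δ| > 0.7 on the rescaled score.
The 0.7 threshold is interpreted on the [0, 1] scale (the scale the
underlying scoring convention reports); note this is a stringent
reading — a single substitution can only move the score by that
position's share of the motif's total range, so allelic calls require
motifs whose information is concentrated at the variant position.
Ambiguous bases (N) score as the background-weighted average.

TF abundance requires expression in > 50% of a cell type's cells and a
mean expression strictly above the 75th percentile of the means over
all candidate (TF, cell type) pairs — pair means, one of two readings
of the rule, chosen and fixed. When every pair is identical the strict
inequality yields no abundant pairs, which is the sensible degenerate
answer. Unmapped TFs are reported, never silently dropped.

### Footprinting

Observed per-base insertion counts around motif sites and the expected
Tn5 sequence-bias track are each normalized to mean 1 over the outer
flanks (±200–250 bp) and subtracted. The footprint statistic is the
mean corrected signal over the motif-flanking band (±50 bp outside the
core) minus the mean over the core; protection makes it positive. The
original procedure judged footprints by eye; the package replaces that
with a one-sided test (site-level bootstrap SE, t reference with
site-level degrees of freedom) *plus* a minimum-depth floor: the
statistic must exceed 0.15 of the flank level, about the shallowest
dip visual inspection would call. The floor exists because the plain
bootstrap z is slightly heavy-tailed at realistic site counts, and a
rule intended to emulate conservative visual calling should sit below,
not at, its nominal level. Power against a planted 40% core depletion
is unaffected.

## Modules, links and the six evidence levels

**Metacells.** Counts are aggregated over k-NN neighborhoods (default
k = 30) of an LSI embedding (TF-IDF + SVD), greedily sampled so any
two metacells share at most 10% of members; k = 1 degenerates to
single cells. Aggregation densifies near-binary accessibility profiles
before covariance estimation.

**Co-accessibility.** Within 500-kb windows stepped by 250 kb, the
correlation matrix of log-normalized metacell profiles is fed to a
graphical lasso whose elementwise penalty grows with genomic distance,
$\rho_{ij} = \rho_0 + s\,(d_{ij}/\mathrm{window})^2$ with
$\rho_0 = 0.12$ and $s = 0.2$; scores are the resulting partial
correlations, averaged across windows. The blockwise coordinate
descent is implemented in-package. The base penalty was fixed during
method development so that duplicated profiles score near the
attainable maximum while independent peaks are shrunk to (near) zero —
the same role the auto-tuned distance parameter plays in the standard
co-accessibility tool. Degenerate inputs (constant peaks within a
window) are dropped from that window. Modules are Louvain communities
of the graph thresholded at 0.32, discarding singletons, with a fixed
seed and module ids renumbered by first member for determinism; edges
above 0.5 are "directly co-accessible".

**Peak–gene links.** For each gene, candidate peaks lie within ±1 Mb
of the TSS and are detected in ≥ 10 cells. The observed Pearson r
between log-normalized accessibility and expression is standardized
against the r's of 200 background peaks matched by nearest neighbors
in the standardized (GC, mean accessibility, width) space, which
absorbs technical covariates including depth: $z = (r - \bar r_{bg}) /
sd(r_{bg})$, one-sided p. Links need p < 0.05 and |r| > 0.05.
Normalized counts are used (configurable); zero-variance or
under-detected peaks are skipped and counted. Constant raw profiles
are excluded before normalization, since depth scaling would
manufacture spurious variation for them.

**Tiers.** For each CCV-colocalizing cCRE `e` and gene `g` in cis:
level 1, `e`'s module contains a promoter cCRE of `g`; 2, a direct
(> 0.5) edge to a promoter cCRE of `g`; 3, `e` is itself the promoter;
4, `e`'s module contains an expression-linked cCRE of `g`; 5, a direct
edge to an expression-linked cCRE; 6, `e` itself is expression-linked —
the strongest evidence. Two conventions are fixed deliberately: the
promoter cCRE for levels 1–2 must differ from `e` (otherwise every
promoter peak would trivially earn levels 1–2 on top of 3), and level
6 does not imply level 5 (no self-edges). Both are pinned by a
hand-enumerated toy graph in the test suite.

## Trait relevance scores

Each locus distributes unit probability evenly over its CCVs; a peak's
weight is the sum of the weights of the CCVs inside it, so locus mass
is conserved up to CCVs outside all peaks. Per-cell deviations
$\sum_j w_j (x_{ij} - e_{ij})$, with $e_{ij}$ the depth-by-popularity
expectation, are standardized against 50 background weight vectors
that relocate each weighted peak within its (GC × mean accessibility)
equal-frequency bin (~50 bins). The top 5% of cells seed a random walk
with restart (restart 0.05, L1 tolerance 1e-6 by default; the
propagation-exactness test tightens the tolerance and checks against
dense power iteration) over a mutual kNN graph (k = 30) of the LSI
embedding. Scores are min–max scaled to [0, 1]; any published absolute
TRS scale is not reproducible from conventions alone, so only
orderings are interpreted. Cells disconnected from all seeds stay at
zero rather than receiving redistributed mass.

## MPRA allelic activity

Tag-level activity ratios are modeled as
`ratio ~ allele + strand + batch` by OLS; inference on the allele
coefficient uses a heteroskedasticity-consistent sandwich covariance
(HC0 by default, HC1–HC3 available) and a two-sided Wald test, with
BH correction across variants. Tags enter as rows, not random effects,
matching the fixed-effects formula; the default design is 25 tags ×
2 strands × 5 transfection batches per allele.

## What the synthetic generator emulates — and what it does not

The generator reproduces the study design at desk scale: 23 cell types
in 4 categories (~87 cells each, ≈ 2,000 cells), 250 peaks on a 10-Mb
chromosome with 37% cell-type-private peaks (the fraction reported for
real atlases of this kind), 60 genes, 5 planted peak–gene links with
latent loading 0.5, 3-peak co-accessible modules, LD blocks of 50
variants, 40% footprint core depletion, and a 0.5 allelic MPRA shift.
Accessibility is Bernoulli × Poisson with a per-cell depth factor;
expression is negative binomial (size 2) with cell-type effects. A
planted link's standard-normal latent factor enters the linked gene's
log-mean and both the open propensity (logit) and fragment intensity
(log) of its peak; the module gate is the dichotomized latent, so the
module co-activates exactly when the shared regulator is high — that
coupling is what makes an anchor peak co-accessible with its partners
*and* correlated with its gene. Module partners sit 1–3 kb from the
anchor so one LD block can span the module. LD is simulated by
thresholding a Gaussian AR(1) haplotype process (decay 0.003/kb) with
near-shared block allele frequencies, giving a few dozen $R^2 > 0.8$
proxies per lead — the scale of real credible sets; dosage $R^2$ is
computed from the genotypes themselves. The declared lead is the
variant with the smallest realized p (the index-SNP convention); the
planted causal index is stored separately in the ground truth.

Not emulated: read-level sequencing noise, doublets and ambient
contamination, batch effects, trans effects, multi-gene regulatory
programs, and realistic motif composition of the genome. Passing the
planted-truth suites therefore demonstrates the *machinery* is correct
and calibrated under the stated generative assumptions, not that
effect sizes or discovery rates transfer to real tissue.

A single master seed fans out into named child streams
(`child_seed`), so adding a component never perturbs another's draws
and identical configurations are byte-reproducible.

## Problem sizes and runtime choices

The test suite runs the full pipeline at the default ~2,000-cell scale
(10 seeds for planted-architecture recovery), link-test calibration on
a 1,000-cell / 500-peak / 50-gene null, 200 simulations each for
footprint calibration and power, 20 seeds for trait-relevance ranking
at 920 cells, and 500 null fits for MPRA p-value uniformity. These
sizes were chosen as the smallest at which the planted effects are
comfortably detectable and null calibration is measurable to ±0.02.

## Known limitations

- The graphical-lasso penalty schedule is a fixed quadratic in
  distance; the reference tool auto-tunes per dataset.
- Match p-values for motifs longer than 10 bp are lattice
  approximations (granularity $10^{-4}$ of the score range).
- The abundance percentile is computed over candidate pair means;
  other summaries of "values from all pairs" are defensible.
- Locus-level category assignment (unanimity) and the level-1/2
  self-exclusion are conventions the original description leaves open;
  both are explicit options or documented fixtures here.
- TRS values are reported on a [0, 1] min–max scale; absolute values
  are not comparable across datasets.
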