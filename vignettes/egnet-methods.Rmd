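---
title: "Models and conventions behind egnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind egnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egnet)
```

`egnet` predicts enhancer–gene (E–G) regulatory interactions and analyses
the resulting bipartite networks. This vignette documents the models it
implements, the conventions and defaults it fixes where the field leaves
choices open, what the synthetic-data generators do and do not emulate, and
the package's known limitations.

## Coordinates and candidate geometry

All intervals are 0-based half-open internally (BED convention); 1-based
inputs — VCF `POS`, motif-scanner `start`/`stop` — are converted exactly
once, at the I/O boundary. The midpoint of an interval is
`floor((start + end) / 2)`, a deterministic tie-break for even lengths.

Two resize operations exist because they serve different consumers:

* `resize_center()` cuts a fixed-length window about the midpoint and
  **shifts** it inward at chromosome ends, always preserving length. This is
  what a scoring element wants (500 bp candidates, 200 bp reporter-assay
  elements): the element must keep its width.
* `resize_on_summit()` centres on the peak summit and **truncates** at
  chromosome ends, reporting the clipped amounts as left/right pad counts,
  because a sequence model with a fixed receptive field (4096 bp) expects
  the consumer to pad with Ns rather than shift the window off the summit.
  The invariant `length + left_pad + right_pad = target` always holds.

Merging uses strict ≥ 1 bp overlap: half-open abutment does not merge. CREs
are classed with fixed priority promoter > genic enhancer > intergenic
enhancer; the promoter interval defaults to TSS ± 500 bp when the
annotation supplies none. Both the priority and the ± 500 bp flank are
package conventions — annotations rarely state them — and both are
configurable (`promoter_flank`).

Candidate selection takes the top 150 000 peaks by read count (ties broken
by chromosome then start, so re-runs are identical), resizes them to 500 bp
and appends one promoter CRE per gene. Candidate pairs are all same-
chromosome (CRE, gene) combinations with midpoint-to-TSS distance ≤ 5 Mb,
boundary inclusive. Measuring the window midpoint-to-TSS (rather than
edge-to-TSS) is a deliberate choice: it makes the pair set invariant to the
element's width.

## The activity-by-contact score

For CRE $e$ and gene $g$:

$$\mathrm{ABC}(e,g) = \frac{A_e\,C_{eg}}{\sum_{e'} A_{e'}\,C_{e'g}},
\qquad A = \sqrt{\mathrm{DNase} \times \mathrm{H3K27ac}}$$

with the sum over the candidate CREs in $g$'s window. The geometric mean for
activity and a pseudocount (default $10^{-6}$) on zero contacts follow the
established activity-by-contact formulation; both are configurable. Scores
are per-gene normalised, so each gene's candidates sum to 1 and uniform
rescaling of a gene's contact column cannot change its scores. A gene whose
candidates all have $A\,C = 0$ receives all-zero scores with a warning
rather than NaNs.

## Feature assembly

Pair-level feature tables are joined on (`cre_id`, `gene_id`), CRE-level
tables on `cre_id`. Reporter-activity scores are first orientation-averaged
(forward / reverse-complement, arithmetic mean — removes strand bias) and
ensemble-averaged over the replicate models (10 expected; fewer accepted
with a warning). Chromatin-probability outputs mapping to the same feature
are collapsed by row-wise mean. Missing values after the joins are imputed
with the per-column median and flagged by a per-source 0/1 indicator
column; median imputation keeps the logistic fit defined without letting
rare missing rows move the coefficient estimates, and the indicator lets
the model learn from missingness itself. Rows are canonically sorted by
(gene, CRE) so assembly is order-invariant.

## The classifier

The interaction model is logistic regression with an L2 penalty. Features
are z-scored on the training rows — necessary for a single penalty to mean
the same thing across features on wildly different scales (bp distances vs
probabilities) — and the intercept is unpenalised. The objective is

$$\frac{1}{n}\sum_i \ell(y_i, \eta_i) + \frac{\lambda}{2}\lVert\beta\rVert^2,
\qquad \lambda = \frac{1}{Cn}$$

so the inverse penalty $C$ (default 1.0) is sample-size free and $C \to
\infty$ approaches the MLE. Optimisation is damped Newton (IRLS with
half-step backtracking), convergence tolerance $10^{-8}$ on the objective,
at most 10 000 iterations. Five-fold cross-validated selection of $C$ over
a user grid is available (`cv_C`); class weighting is off by default (the
typical CRISPRi training sets are imbalanced, but unweighted fits are the
standard baseline) with a `"balanced"` option. The fit is deterministic
given the data; the seed only controls CV fold assignment. Tests cross-check
the solver against `glmnet` ridge at matched $\lambda$.

## Benchmark statistics

The precision–recall curve is evaluated at every distinct score (ties enter
together) and the area is the step-wise average-precision sum
$\sum_i (R_i - R_{i-1}) P_i$ — not trapezoidal, which can be optimistic for
PR curves. Confidence intervals are percentile bootstrap over resampled
pair lists (default 10 000 replicates); single-class resamples are redrawn
and counted. The operating threshold at a target recall (default 70 %) is
the largest threshold $t$ with $\mathrm{recall}(score > t) \ge$ target,
under strict-greater binarisation — the same strictness used for network
edges, so the benchmark threshold and the network threshold mean the same
thing. Score–effect association is Spearman's $\rho$ with average-rank
ties; it errors on constant input rather than returning a silent NA.

## Networks and substructures

Networks retain edges with score strictly above the threshold; two named
presets are exposed (0.283 for standard contact data, 0.234 for megamap
contact — operating points at 70 % recall). Promoter-class CREs keep only
the edge to their own gene: a promoter "regulating" a neighbour is almost
always a windowing artefact. Community detection is multi-level modularity
optimisation (Louvain, via igraph) on the bipartite graph treated as a
simple unweighted undirected graph; edge presence rather than score weights
is the default because thresholding has already binarised the evidence (a
weighted mode exists behind a flag). Resolution is fixed at 1.0 and the
seed is mandatory, making partitions reproducible. A community with exactly
one CRE is non-redundant (NR) — its genes have no enhancer buffering — and
one with several CREs is redundant (R); communities with no CRE (possible
only for isolated genes) are excluded from the %NR denominator.

## Matched-background permutation tests

Both permutation frameworks ask whether an observed statistic on the
network's CREs exceeds what matched random CREs would give.

* **Variant overlap.** The statistic is the number of unique variants
  (deduplicated by chromosome, position and id; variants with an
  association p-value are pre-filtered at $p < 0.01$) falling in ≥ 1
  network CRE. Each network CRE is replaced, with replacement, by a
  candidate peak from the same chromosome in the same length bin and
  distance-to-nearest-TSS bin. Default bins are deciles of the candidate
  distributions — with no stated bin widths, quantile bins guarantee evenly
  populated cells. When a cell is empty the search expands over rings of
  adjacent bins at increasing Chebyshev distance in (length, distance) bin
  space until a candidate exists; relaxation events are counted and
  reported.
* **eQTL concordance.** The statistic is the number of unique
  (variant, gene) pairs where the variant sits in a network CRE that has an
  edge to that gene. Matching additionally requires the same CRE class and
  predicted-target count: the count is matched exactly first, then relaxed
  by ± 1, ± 2, … jointly with the bin relaxation (level $L$ allows bin
  Chebyshev distance ≤ $L$ and count difference ≤ $L$); the class
  constraint is dropped only as a last resort and logged. Every sampled
  peak keeps its *own* model-predicted targets, reconstructed with the same
  threshold and promoter-self rule as the observed network, so the null
  preserves the model's regulatory structure while randomising which CREs
  carry it.

Significance is the +1-corrected empirical p-value
$p = (\#\{null \ge obs\} + 1)/(n_{perm} + 1)$, bounded below by
$1/(n_{perm}+1)$ (with the default 1000 permutations, $1/1001 \approx
9.9\times10^{-4}$); fold enrichment is $obs / \overline{null}$. Results are
bit-reproducible for a fixed seed.

A caveat worth knowing: when matched pools are very small, the observed CRE
is drawn back into its own null often, which pulls fold-enrichment
estimates toward 1. With genome-scale catalogs (hundreds of matched
candidates per cell) the effect is negligible; the package's own
calibration and recovery tests use universes dense enough that pools hold
≈ 10 candidates.

## Motif and gene-set enrichment

CREs from all conditions' networks are merged (≥ 1 bp overlap); a merged
region contributed by exactly one condition is condition-specific. A region
is TFBM-present if ≥ 1 scanner hit (p ≤ 10⁻⁵) from that condition's network
CREs falls in it — presence, not hit counts, because scanner hit
multiplicity mostly reflects region length. Per TF the 2×2 of presence ×
specificity is tested with a one-sided Fisher exact test (hypergeometric
upper tail; the empty table returns p = 1 by convention), the headline
effect size is the log2 odds ratio with 0.5 continuity correction (always
finite), the raw odds ratio is reported with explicit infinity when
$bc = 0$, and BH FDR is applied across TFs within each condition — never
pooled across conditions, whose tests share regions and would distort each
other's ranks.

Gene-set enrichment is the hypergeometric survival function
$P(X \ge x)$ for drawing $k$ network genes from a background of $M$ with
$n$ set members; sets are intersected with the background first.

## The synthetic-data generators

The simulation module produces every input the pipeline consumes, from one
top-level seed with fixed stream offsets (world +0, pair data +1, variants
+2, eQTLs +3, motif hits +4), so generators are independently reproducible
and never disturb the caller's RNG.

What is emulated, with defaults chosen as plausible desk-scale values:
uniform TSS placement with 5–50 kb gene bodies; log-normal peak lengths
(median 350 bp) in disjoint slots (peaks never overlap, keeping planted
overlap structure exact); gamma read counts; contact decaying as
$(d + d_0)^{-\gamma}$ with $\gamma = 1$, $d_0 = 5$ kb and log-normal noise,
the power-law behaviour contact-based models assume; true links drawn from
a known logistic model over the assembled feature columns (defaults plant
signal on the reporter-activity column, two pair-level features and one
chromatin column, intercept −2.5); labels flipped at a 5 % noise rate;
effect sizes centred at −30 % for true links. Variants are placed uniformly
within candidate peaks, entering network peaks with probability
$FE \cdot m/N$ so the planted fold enrichment is exact in expectation (and
infeasible values error with the maximum feasible FE). eQTLs are drawn from
network edges at the planted concordance rate. Motif presence in
condition-specific regions is log-odds-shifted so the population odds
ratio equals the planted value.

What is **not** emulated: realistic sequence content, chromatin covariance
between marks, overlapping or clustered peaks, LD between variants,
distance-dependent eQTL discovery bias, and correlated motif co-occurrence.
Passing calibration and recovery tests on these fixtures therefore shows
the statistics are implemented correctly and are well calibrated under
their own assumptions — not that the model will reach any particular
accuracy on real chromatin data.

## Problem sizes used by the test suite

The suite runs a planted-signal study of 300–500 peaks, 30–50 genes and two
2-Mb chromosomes (≈ 9 000–14 000 candidate pairs); coefficient recovery
uses ≈ 23 000 pairs; permutation calibration uses 200 studies of 200
permutations each; fold-enrichment recovery uses a 2 000-peak universe so
matched pools stay well populated. These sizes were chosen so every
statistical check has adequate power while the whole suite stays
interactive.

## Known limitations

* Chromosome names are matched exactly; no `chr1`/`1` normalisation.
* No sequence handling: reporter-activity and chromatin-probability scores
  are consumed as numbers, never computed from sequence.
* Contact values come from a per-pair table; native Hi-C file extraction is
  out of scope.
* Louvain is the only community algorithm offered.
* The eQTL null requires model predictions over the whole candidate
  universe; scoring only network CREs would silently degrade the matching.
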