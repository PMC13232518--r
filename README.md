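# egnet

Enhancer–gene (E–G) interaction prediction and regulatory network analysis
for epigenomics. Most disease-associated variants fall in non-coding
regulatory DNA, so linking cis-regulatory elements (CREs: enhancers and
promoters) to the genes they control, in a cell-type-specific way, is a core
problem in regulatory genomics. `egnet` is aimed at computational biologists
who have DNase-seq peaks, activity signals (DNase, H3K27ac), 3D contact
values, sequence-derived activity scores (e.g. reporter-assay or
chromatin-model predictions) and CRISPRi perturbation labels, and who want
to train, benchmark and dissect an E–G interaction predictor.

## What it computes

**Candidate geometry.** DNase peaks are resized to 500 bp about their
midpoints, the top peaks by read count are retained, and every gene promoter
is added to the candidate set. Candidate pairs are all (CRE, gene)
combinations with midpoint-to-TSS distance ≤ 5 Mb on one chromosome.
Fixed-width windows for sequence models are cut about peak centres (200 bp,
shift-clamped) or summits (4096 bp, truncated with N-pad accounting).

**Activity-by-contact score.** For CRE *e* and gene *g*,

```
ABC(e, g) = A_e · C_eg / Σ_{e'} A_e' · C_e'g ,   A = sqrt(DNase × H3K27ac)
```

with the sum over all candidate CREs in *g*'s window and a pseudocount on
zero contacts; per-gene scores sum to 1.

**Classifier.** A logistic regression with L2 penalty over the assembled
per-pair features (ABC score, distance, externally supplied activity and
chromatin-probability columns), trained on CRISPRi outcomes (1 = the
perturbation significantly reduced the target gene's expression). Features
are z-scored on the training rows; the fit is damped Newton on the penalised
log-loss with an unpenalised intercept.

**Benchmarking.** Precision–recall with step-wise (average-precision) AUPRC,
10 000-replicate percentile bootstrap confidence intervals, the operating
threshold at 70 % recall, and the Spearman correlation between scores and
measured perturbation effect sizes.

**Networks.** Thresholded bipartite CRE–gene graphs (promoter CREs keep only
their self edge), Louvain community detection, and classification of each
community as non-redundant (NR: exactly one CRE) or redundant (R: several
CREs), with `%NR` summaries.

**Enrichment statistics.** Chromosome-stratified matched-background
permutation tests (variant-in-CRE overlap, and eQTL variant–gene concordance
with per-CRE matching on class, length, TSS distance and predicted-target
count), with `p = (#{null ≥ obs} + 1) / (n_perm + 1)` and fold enrichment
`obs / mean(null)`; one-sided Fisher motif enrichment in condition-specific
merged regions with 0.5-continuity-corrected log2 odds ratios and BH FDR;
and hypergeometric (survival-function) gene-set enrichment.

**Simulation.** Every input above can be generated with planted structure
(a known logistic model behind the labels, a known variant fold enrichment,
a known motif odds ratio), so calibration and recovery are testable without
any external data.

## Worked example

```r
library(egnet)

cfg    <- sim_config(seed = 42)          # synthetic study, planted signal
world  <- sim_world(cfg)
pd     <- sim_pair_data(world, cfg)

model  <- train_eg_model(pd$features, pd$labels, C = 1)
scores <- predict(model, pd$features)
bench  <- benchmark_predictions(scores, pd$labels$label,
                                effects = pd$labels$effect_size,
                                n_boot = 2000, seed = 1)
print(model)
print(bench)
```

```
E-G ridge-logistic model: 10 features, C = 1
  trained on 8800 pairs ( 1466 positive / 7334 negative )
AUPRC 0.4209 (95% CI 0.3960-0.4481); precision 0.2954 at recall 0.70 (threshold 0.1620)
```

The AUPRC of 0.42 against a label prevalence of 0.17 shows the classifier
recovering the planted signal; the threshold 0.162 is the score cutoff at
which 70 % of true links are recovered, at precision 0.30. Building and
dissecting the network of confident predictions:

```r
cls    <- setNames(classify_cre(pd$cres, world$genes), pd$cres$cre_id)
scored <- data.frame(cre_id = pd$features$matrix$cre_id,
                     gene_id = pd$features$matrix$gene_id, score = scores)
net    <- build_eg_network(scored, threshold = 0.7, cres = pd$cres, cre_class = cls)
part   <- detect_communities(net, seed = 1)
subs   <- classify_substructures(net, part)
summarize_network(net, subs, part$modularity)
```

```
E-G network: 20 edges, 16 CREs, 17 genes (threshold 0.7)
$n_unique_cres  16    $n_unique_genes 17    $n_pairs 20
$pct_nr 76.9          $n_communities  13    $modularity 0.905
```

76.9 % of the 13 regulatory substructures contain a single CRE (NR): genes
in those modules depend on one enhancer with no regulatory buffering.

A thin command-line wrapper over the same functions is installed at
`inst/cli/egnet.R` (subcommands `simulate`, `run-all`, `benchmark`,
`network`, `enrich-variants`).

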