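---
title: "Detecting driver genes from multiplex networks and pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting driver genes from multiplex networks and pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pandriver)
```

## The model

Functional pathway databases list the genes that carry out a cellular
function, but treat every member as equally important.  Interaction
networks, on the other hand, record which gene products actually talk to
each other — physically, genetically, through shared protein domains,
co-localization, or shared reactions.  `pandriver` combines the two: a gene
that is connected to *more of its pathway co-members than chance predicts*
is a candidate driver of that pathway's function, and demanding that the
signal appears in several independent interaction layers guards against the
biases of any single evidence type.

For a gene $i$, an interaction layer $N$ with $m$ nodes, and a pathway $P$
with $k$ genes, the package computes three degree quantities:

* $d_i^N$ — the degree of $i$ in the whole layer;
* $d_i^P$ — the degree of $i$ counting only edges to pathway co-members;
* $d_i^E = d_i^N \cdot k / m$ — the degree expected among the pathway's
  genes if edges were equally probable everywhere ($d_i^N / m = d_i^E / k$).

The driver criterion, in its default (**literal**) form, calls $i$ a
potential driver of $P$ in layer $N$ when

$$\frac{d_i^P}{k} > d_i^E,$$

with strict inequality, and a gene is a **network driver** when this holds
in at least two layers (`min_layers = 2`).  The inequality as printed mixes
a pathway-normalised left side with an unnormalised expectation; the
dimensionally matched variant $d_i^P > d_i^E$ is available as
`criterion_mode = "unnormalized"`.  We implement the literal form as the
default and do not guess which variant original implementations executed;
the consequences of the choice are quantified below.

Aggregation across layers is `per_gene` by default — the gene may qualify
through different pathways in different layers, which matches reporting
driver sets per layer and intersecting them — while `per_pathway` (the same
pathway must pass in `min_layers` layers) is available as the stricter
reading.

## Operating regime of the literal criterion

Because $d_i^P \le d_i^N$ always, the literal inequality
$d_i^P / k > d_i^N k / m$ can only hold when

$$k^2 < m \cdot \frac{d_i^P}{d_i^N} \le m .$$

So pathways larger than $\sqrt{m}$ can never yield drivers under the
literal form, whatever the data.  With genome-scale networks
($m \approx 1.5\times10^4$) and typical curated pathways
($k \approx 30$–$300$) the bound is rarely binding, but in scaled-down
simulations it matters: at the package's reference simulation size
($m = 600$, pathways of 15–40 genes) most pathways sit beyond
$\sqrt{600} \approx 24.5$ and the literal criterion is structurally unable
to recover planted drivers there (measured sensitivity is a few percent,
with essentially zero false positives).  The unnormalized variant recovers
all planted drivers at those settings but, because $d_i^E < 1$ for
background genes, a single stray within-pathway edge passes it, giving a
false-positive rate around 0.35.  Neither mode is "fixed" by the package:
both are reported as measured by `scripts/acceptance.R`.

End-to-end demonstrations therefore use bundles inside the operable regime
— pathways of 8–14 genes ($k < \sqrt{m}$) with strong planted enrichment
(within-pathway edge probability 0.9) — where the literal criterion attains
sensitivity ~1 at a false-positive rate of ~0.03.

## The synthetic study generator

`simulation_config()` describes a complete study: a gene universe, pathway
collection, multiplex layers, and a tumour/normal count matrix, with ground
truth recorded for every planted signal.  Defaults (the reference
conditions used throughout the package's evaluation):

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 600 | gene universe size |
| `n_pathways`, `pathway_size_range` | 12, 15–40 | pathway collection |
| `layer_names` | 3 layers | interaction types |
| `background_edge_prob` | 0.02 | Erdős–Rényi background density |
| `planted_drivers` | 3 per pathway | designated driver genes |
| `planted_within_pathway_prob` | 0.5 | driver-to-co-member edge probability |
| `n_layers_planted` | 2 | layers carrying each driver's enrichment |
| `n_samples_per_class` | 40 | samples per class |
| `nb_dispersion` | 0.1 | NB dispersion (var $= \mu + \mu^2\phi$) |
| `planted_log_fc` | 2 | planted |log2 FC| on DE genes |
| `fraction_drivers_de` | 0.25 | drivers that are also deregulated |
| `n_decoy_de` | 40 | deregulated non-pathway decoys |

Choices worth explaining:

* **`fraction_drivers_de = 0.25`.** In any one condition only a minority of
  network drivers is deregulated; per-condition driver-DEG fractions of
  roughly 10–30% of the full driver set are what pan-cancer compendia show,
  and 0.25 sits in that range.
* **Decoys are drawn outside all pathways.**  They emulate differential
  expression unrelated to pathway-central genes, keep the driver/decoy
  ground truth disjoint, and make the driver∩DEG intersection a meaningful
  test rather than a tautology.
* **Planting in exactly `n_layers_planted = 2` layers** makes the
  at-least-two-layers rule testable on both sides (drivers qualify at
  `min_layers = 2`, would not at 3).
* **Negative binomial counts** with mean–dispersion parameterisation are
  the standard RNA-seq count model; baseline means are log-uniform on
  20–2000 so that both low- and high-expressed genes occur.
* With `planted_log_fc = 0` the generator records *empty* DE truth — the
  null configuration used for calibration checks.

What the generator does **not** emulate: GC-content and library-preparation
biases, batch effects, correlated co-expression modules, paired
tumour/normal designs, or scale-free degree distributions.  Passing tests
on these bundles show the pipeline's logic and calibration, not performance
on real tumour compendia.

## Differential expression

The paper-scale normalization stack (GC-content within-lane plus
between-lane normalization) is citation-delegated in the original protocol
and out of scope here; the package uses a transparent, self-contained
substitute that it documents exactly:

$$x_{gs} = \log_2\!\left(10^6\,\frac{c_{gs} + 1}{\ell_s + G}\right)$$

(log2 counts-per-million with pseudo-count 1; $\ell_s$ raw library size,
$G$ the number of genes).  Per-gene testing is a two-sided Welch $t$-test
on this scale, BH-adjusted; a gene is a DEG when $|\mathrm{logFC}| > 1$
(strict) and FDR $< 0.01$ (strict), both thresholds configurable.  Genes
with zero variance in both classes get $p = 1$ by contract, and all-zero
genes are dropped before testing.  The module boundary (normalize → test →
adjust → select) makes the test a drop-in replacement point.  DEA is
unpaired, matching the tumour-versus-normal two-class design.

Calibration, as recomputed by the acceptance script: a 1000-gene null
bundle yields on average fewer than 2 DEGs per 1000 genes over 20 seeds
(usually 0), and 50 genes planted at $|\mathrm{logFC}| = 2$ with 40 samples
per class are recovered with sensitivity ≥ 0.9 (measured 1.0).

## Per-gene classifier validation

Each candidate driver DEG is validated as a single-feature tumour/normal
classifier: a random forest (`ntree = 500`,
`mtry = max(1, ceiling(sqrt(p)))`, here $p = 1$) trained under stratified
10-fold cross-validation.  The out-of-fold tumour-class probability scores
are pooled across folds and the AUC is computed once from them by the
Mann–Whitney rank statistic — pooling is more stable than averaging
per-fold AUCs when folds hold only a few samples.  Constant genes are
reported as AUC 0.5 with a warning.  If the smaller class has fewer than
$k$ members, $k$ is reduced to that size with a warning.  Ranking is by
descending AUC with alphabetical tie-break; `rank_band_mean_auc()` gives
band summaries (e.g. the mean AUC of ranks 11–50).

Numerical notes: every gene gets its own RNG stream derived
deterministically from the configured seed and the gene symbol, so AUC
tables are bitwise reproducible and independent of the order genes are
scored in.  The AUC is exactly invariant under affine transforms of the
expression values; under nonlinear monotone transforms (log, exp) it is
invariant only up to the position of tree split midpoints, which is why
the test suite asserts exact equality for affine maps but a 0.05 band for
nonlinear ones.

## Pipeline, sizes and determinism

`run_drivers()` executes pathway + multiplex → centrality records →
criterion calls → per-layer sets → multiplex driver set → Venn region
counts; `run_condition()` executes DEA → driver∩DEG intersection → FDR
comparison (drivers versus all DEGs) → per-gene AUC → top-$k$.  Every run
emits a JSON summary whose cardinalities satisfy
$|\text{driver DEGs}| \le \min(|\text{DEGs}|, |\text{drivers}|)$.  All
randomness descends from one top-level seed (stage seeds are `seed`,
`seed + 1`, `seed + 2` for pathways, layers and expression; per-gene
classifier seeds add a stable hash of the symbol).

The evaluation sizes used by the test suite and acceptance script — 600 to
1000 genes, 10–20 simulation seeds per quantity, three layers — were
chosen so a full evaluation completes in well under a minute while leaving
binomial/Monte-Carlo noise far from every asserted margin.

## Known limitations

* The literal criterion's $k^2 < m$ operating bound (above) is inherent to
  the printed inequality, not to the implementation.
* The Welch-on-logCPM test is a simplification; count-model tests (e.g.
  negative-binomial GLMs) will differ in power on real data.
* Venn regions are reported as counts only; no diagram rendering.
* External driver-catalogue comparison is pure set arithmetic over supplied
  gene lists; the package never runs the catalogued tools.
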