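---
title: "Scoring disruptive genes on an interaction network: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring disruptive genes on an interaction network: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genesurrounder)
```

## The question the method answers

Differential-expression analysis asks *which genes change* with a phenotype.
This package asks a different question: *which genes look like sources of the
change*? A gene that dysregulates a disease process should leave two
signatures on a molecular interaction network:

1. **Sphere of influence.** Its expression should be unusually correlated
   with that of its network neighbors — more than with a random set of
   genes.
2. **Decay of differential expression.** Genes near it should be
   differentially expressed, with the magnitude of differential expression
   fading as one moves farther away in the network.

Neither signature alone is convincing: hubs are correlated with many genes
for purely topological reasons, and a differentially expressed neighborhood
may simply sit downstream of the true source. The method therefore tests
both signatures independently and combines the evidence.

## The two tests

Let $d_{ij}$ be the geodesic (hop) distance between genes $i$ and $j$ on the
undirected interaction graph, reduced to its largest connected component.
All radii $r = 1, \dots, D$ are scanned, where $D$ is the component
diameter.

**Sphere of influence.** With $\rho_{ij}$ the Spearman correlation between
genes $i$ and $j$ over all samples pooled, the observed statistic at radius
$r$ is the total absolute correlation

$$C_i(r) = \sum_{j\,:\,0 < d_{ij} \le r} |\rho_{ij}|.$$

Its null distribution is obtained by resampling: $n_r$ values are drawn with
replacement from gene $i$'s own pool $\{|\rho_{ij}| : j \ne i\}$ and summed,
$B$ times. This is a *competitive* null — it asks whether the genes that
happen to be $i$'s neighbors are more correlated with it than a random set
of the same size would be. The empirical p-value is upper-tail with add-one
smoothing, $p^{S}_i(r) = (1 + \#\{C^* \ge C_i(r)\})/(B+1)$, so it can never
be exactly zero.

**Decay of differential expression.** Each gene gets a magnitude of
association with the phenotype, $g_j = |t_j|$ from a two-sample Welch test
(the pooled-variance variant is available via `var.equal = TRUE`; any
magnitude statistic would do, since only ranks enter what follows). The
discordance between differential expression and distance is Kendall's
tau-b,

$$D_i(r) = \tau_B\big(\{g_j\}, \{d_{ij}\}\big), \qquad 0 < d_{ij} \le r,$$

with the tie correction mandatory because the distances are small integers.
Decay means $D_i(r) < 0$. Significance comes from a *self-contained* null:
the phenotype labels are permuted $B$ times, all $g_j$ recomputed, and
$D^*_i(r)$ re-evaluated; the p-value is the lower-tail add-one fraction
$p^{D}_i(r) = (1 + \#\{D^* \le D_i(r)\})/(B+1)$. Permuting labels leaves
the expression matrix — and hence every inter-gene correlation — untouched,
which is exactly why this null is orthogonal to the gene-resampling null of
the sphere test. A `strict = TRUE` flag switches to the unsmoothed strict
fraction $\#\{D^* < D_i\}/B$ for users who want the raw tail count.

**Combined evidence.** Because the two tests randomize orthogonal axes
(genes versus samples), their p-values are treated as independent and
combined with Fisher's method, $X^2 = -2(\ln p^S + \ln p^D)$, referred to a
$\chi^2_4$ distribution. A gene's final score is
$p^{\mathrm{GS}}_i = \min_r p^{\mathrm{Comb}}_i(r)$, reported with the
smallest radius attaining the minimum. Scanning $D$ radii is a multiplicity
of $D$ tests per gene, so the significance call compares
$p^{\mathrm{GS}}_i$ to $\alpha / D$ — at $\alpha = 0.05$ and $D = 34$ that
is $-\log_{10} p \ge 2.83$, as `bonferroni_threshold(0.05, 34)` reports.
The reported $p^{\mathrm{GS}}$ itself is deliberately *not* adjusted; the
threshold is. An optional gene-level family-wise adjustment
(`genewise_fwer()`, min-p over outer label permutations) is available but
off by default: it costs a full re-analysis per permutation.

## Numerical and procedural choices

* **Empirical p-values** use $(1+\text{count})/(1+B)$ everywhere. The floor
  is $1/(B+1)$ per test, hence the smallest attainable combined p-value at
  the default $B = 1000$ is `fisher_combine(1/1001, 1/1001)$p_comb`
  ($\approx 1.5\times10^{-5}$); result tables should be read with that
  floor in mind.
* **Radius grid.** Every gene is scanned over the same grid $1..D$ even
  where its eccentricity is smaller; beyond it the neighborhood saturates
  and the curves flatten, but the uniform grid keeps the Bonferroni factor
  identical for all genes.
* **Center exclusion.** The center gene is excluded from its own
  neighborhood in both tests: $\rho_{ii} \equiv 1$ and $g_i$ at distance 0
  would only add constants.
* **Small neighborhoods.** Tau-b needs variation in both arguments: radii
  whose assayed neighborhood has fewer than 3 genes, or whose inputs are
  all tied (every neighbor at distance 1, say), carry no rank information
  and are reported with $D$ undefined and $p^D = 1$.
* **Zero-variance genes** get $\rho = 0$ and $g = 0$ with a warning rather
  than being dropped, so neighborhood sizes stay comparable.
* **Unassayed network nodes** stay in the graph as conduits: they carry
  geodesic distance but are never scored and never enter a correlation pool
  or a neighborhood sum. Scored genes are the intersection of the assayed
  genes with the component.
* **Shared permutations.** One set of $B$ permuted label vectors is drawn
  per run and reused across all center genes and radii. Each column is a
  complete label permutation, so every per-gene, per-radius marginal null
  is untouched; the saving is a factor of (number of genes) in t-test
  recomputations. Per-radius taus over nested neighborhoods are computed
  incrementally (distance-sorted sweep with prefix counts), which is what
  makes a full $B \times \text{genes} \times D$ scan affordable.
* **Per-gene streams.** Under a master seed, each gene's resampling stream
  is derived from the seed and the gene id, so scoring a subset of genes
  reproduces the full run's numbers exactly.
* **Missing data.** Following common practice for two-channel-era cohorts,
  `filter_missing()` drops genes with more than 25% missing values, then
  samples (gene filter first — the order matters and is documented), then
  imputes survivors by the gene-wise median. Analysis functions require
  complete data; pairwise-complete correlation was considered and rejected
  because it would make the resampling pool's size gene-pair-dependent.

## What the synthetic generator emulates

`make_study()` plants a single latent factor $z \sim N(0,1)$ per sample.
The driver gene is $z + \varepsilon$; a gene at distance $d \le$ `cutoff`
loads on the factor with $\lambda(d) = \lambda_0\gamma^d$ and carries a
class-mean shift $\delta(d) = \delta_0\gamma_{DE}^d$; genes beyond the
cutoff are pure noise. One construction thus induces both signatures with
closed-form moments — e.g. the pooled correlation between driver and a
distance-$d$ gene is
$\lambda(d)/\sqrt{(1+\sigma^2)(\lambda(d)^2+\sigma^2+\delta(d)^2/4)}$ —
which the tests verify against sample estimates.

Defaults: $\lambda_0 = 0.8$, $\gamma = 0.6$, $\delta_0 = 1.5$,
$\gamma_{DE} = 0.6$, $\sigma = 1$, 30+30 samples, cutoff 4. The default
network is sparse preferential attachment (one edge per new node, 200
nodes) with 75% of genes assayed: this reproduces the regime the method is
designed for — assayed neighborhoods that grow gradually over many radii,
so the decay pattern only becomes detectable once neighborhoods are large
enough. The planted driver defaults to the best-connected node whose
cutoff-ball covers at most a quarter of the network and whose eccentricity
exceeds the cutoff: planted dysregulation is then genuinely *local* (the
correlation pool is mostly unrelated genes, and genes beyond the boundary
exist). A hub driver would violate both conditions — most of its pool would
be its own signal, which the competitive null by construction cannot
distinguish.

What the generator does **not** emulate: platform noise models, batch
effects, structured missingness, multiple or interacting drivers,
condition-dependent networks. Passing the synthetic benchmarks therefore
demonstrates internal correctness and statistical calibration, not
performance on any particular real cohort.

## Reference problem sizes

The validation suite runs, as the package's chosen reference conditions:
null calibration on two 100-node small-world studies (20+20 samples,
$B = 200$, 200 replicate genes, fixed radius 3, exact binomial 99%
interval); planted-driver recovery on 25 seeds of the default 200-node
study at $B = 500$ (driver in the top 5 of ~150 scored genes, best radius
within $\pm1$ of the cutoff); and cross-study concordance on 25 pairs of
studies sharing a truth but not noise, also at $B = 500$, where the
Spearman concordance of $p^{\mathrm{GS}}$ is compared against that of the
plain differential-expression p-values. $B = 500$ for the paired
comparisons keeps the granularity of the empirical p-values from dominating
the cross-study rank correlations.

## A small worked run

```{r example, eval = FALSE}
net <- make_network("scale_free", n_nodes = 200, seed = 11)
study <- make_study(net, synthetic_truth(), seed = 12)
fit <- gene_surrounder(study, net, B_sphere = 500, B_decay = 500, seed = 42)
fit
attr(study, "truth")$driver            # the planted driver
head(fit$results)                      # is it at the top?
subset(fit$curves, gene == attr(study, "truth")$driver)
```

## Known limitations

* Edges are undirected and untyped; activating and inhibiting interactions
  are indistinguishable, and distances ignore direction.
* The network is assumed identical across conditions.
* Genes absent from the network cannot be scored at all.
* The independence of $p^S$ and $p^D$ rests on the orthogonal-axes
  argument; it is verified empirically (the combined p-value is calibrated
  on null data) rather than proven for arbitrary dependence structures.
* With empirical p-values, $p^{\mathrm{GS}}$ has a hard floor determined by
  $B$; ranks below that floor are ties broken lexicographically.
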