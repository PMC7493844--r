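---
title: "Inferring ceRNA interactions: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ceRNA interactions: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

## The competing-endogenous-RNA model

miRNAs repress transcripts post-transcriptionally by binding miRNA response
elements. When two transcripts carry binding sites for the same miRNAs,
they compete for a finite miRNA pool: raising the abundance of one partner
titrates miRNAs away from the other and de-represses it. A ceRNA pair —
here always anchored by a protein-coding gene (ceRNA-A), with a sponge
partner (ceRNA-B) drawn from protein-coding genes, lncRNAs and pseudogene
transcripts — therefore shows three statistical signatures in expression
data:

1. the partners are positively correlated with each other;
2. each partner is negatively correlated with the shared miRNAs;
3. the partner–partner correlation is *explained* by the shared miRNAs —
   it collapses under conditioning.

`cernet` screens for all three signatures in order, each with its own
test, over (i) a gene expression matrix with per-feature biotypes, (ii) a
miRNA expression matrix over the same samples, and (iii) a catalog of
miRNA–target edges from interaction databases. Expression is assumed
already normalized and log-scale; the readers offer an optional
`log2(x + 1)` transform (off by default) but no other preprocessing, since
normalization pipelines are a data-preparation concern.

## Stage A: shared-miRNA enrichment

For a target pair $(a, b)$, let $N$ be the number of available miRNAs,
$K$ and $O$ the sizes of the two targets' catalog miRNA sets, and $x$ the
overlap. Under random membership, $x$ is hypergeometric, and we use the
upper tail

$$p = 1 - \sum_{i=0}^{x-1}
  \frac{\binom{K}{i}\binom{N-K}{O-i}}{\binom{N}{O}} = P(X \ge x).$$

Two definitional choices:

* **$N$ counts expressed catalog miRNAs** — the catalog universe
  intersected with the miRNA expression matrix. Only expressed miRNAs can
  participate in the downstream correlation stages, so including silent
  ones would deflate every p-value. Per-target sets $K$, $O$ are restricted
  the same way.
* **Raw p-values by default.** The pair-level threshold is `alpha_hyper`
  (default 0.05) on the unadjusted p-value; Benjamini–Hochberg across all
  tested pairs is available (`adjust_hyper = "BH"`). Stage A is a screen
  whose false positives are still confronted with two further, independent
  filters; adjusting at the screen makes retention of genuinely competing
  pairs depend strongly on how many background pairs the catalog happens
  to generate, which we judged the wrong trade-off for a first-stage
  filter. Users wanting family-wise control over the *final* table can
  instead set `adjust_mscor = "BH"`.

Each unordered pair is tested once, oriented with the coding gene first
(lexicographic for coding–coding pairs); `min_shared` (default 1) sets the
minimal overlap worth testing — single-miRNA sponges are biologically
plausible and retained by default. The tail sum is evaluated in log-space
(`lchoose` with a log-sum-exp reduction), exact to ~1e-14 against direct
enumeration and stable for catalogs of thousands of miRNAs where binomial
coefficients overflow double precision.

## Stage B: the negative-correlation filter

A real miRNA–target interaction should anti-correlate the two expression
profiles. Each candidate edge is tested with a score-type global test: with
response $y$ (target) and centred covariates $X_c$ (miRNAs),

$$Q = \frac{\lVert X_c^\top y_c \rVert^2}{p \cdot \widehat{var}(y)},$$

and significance by permutation of $y$'s sample labels,
$p = (1 + \#\{Q^{perm} \ge Q\}) / (n_{perm} + 1)$. $Q$ is an omnibus
(direction-free) statistic, so the sign requirement is enforced separately:
an edge is retained iff $r < 0$ **and** $p \le$ `alpha_gt` (default 0.05,
`n_perm` default 1000, giving a p-value floor of ~0.001).

The covariate set is a genuinely open design point: the default tests each
edge with its single miRNA (`gt_mode = "per_edge"`), matching the edge-wise
retention semantics of the downstream intersection; `"per_target"` tests a
target once against all its candidate miRNAs jointly and shares the joint
p-value across its edges. With one covariate, ranking edges by $Q$ is
equivalent to ranking by $r^2$ once covariate scale is factored out, which
the unit tests assert.

Only edges incident to some stage-A candidate are tested — edges that
cannot reach stage C are skipped for speed; this is result-equivalent to
testing all edges.

## Stage C: multiple sensitivity correlation

For a surviving pair with shared miRNA set $M$,

$$mscor(g_a, g_b, M) = cor(g_a, g_b) - pcor(g_a, g_b \mid M).$$

mscor near zero means conditioning changes nothing — the pair's
correlation is direct. mscor near $cor(g_a, g_b)$ means the correlation is
routed through the miRNAs — the ceRNA signature. Before scoring, each
candidate's shared set is intersected with the stage-B survivors (a miRNA
counts only if **both** its edges to $a$ and $b$ were retained); candidates
with an empty intersected set are dropped. Requiring every stage-A miRNA to
survive instead would be stricter; we intersect, because stage B operates
edge-wise and a partially supported miRNA set is still evidence of
competition through the supported part.

Partial correlation is computed from the inverse of the joint correlation
matrix ($-P_{12}/\sqrt{P_{11}P_{22}}$), with a regression-residual route
kept as an independent cross-check (the test suite demands agreement to
1e-10); a rank-deficient conditioning set falls back to the Moore–Penrose
pseudo-inverse with a warning (or errors under `strict = TRUE`).

### The empirical null

The finite-sample spread of mscor under "no competition" depends on the
sample count $n$, the number of conditioning miRNAs $m$, and the pair
correlation $k$. We therefore simulate a stratified null: for each
$(m\text{-bin}, k\text{-bin})$ stratum, draw the gene pair bivariate normal
with correlation at the bin centre and $m$ miRNA vectors independent of
both genes, all of length $n$, and record mscor. Under this null the
population partial correlation equals the population correlation, so mscor
is centred at zero. The observed statistic gets the one-sided, add-one
p-value $(1 + \#\{null \ge obs\}) / (n_{draws} + 1)$ — one-sided because
only positive mscor indicates miRNA-mediated correlation; negative values
are never called significant. An interaction must additionally have
$cor(g_a, g_b) > 0$ (signature 1); non-positive correlations are dropped
before any null query, which also keeps the null strata confined to
$k \in (0, 1]$.

Defaults: $m$-bins $\{1,\dots,8\}$ with everything above 8 mapped to the
top bin; correlation bins of width 0.1 over $(0, 1]$; 10,000 draws per
stratum (`null_draws`), the add-one convention bounding p-values away from
zero at ~1e-4. The pipeline simulates only the strata its candidates
actually query. Simulating at bin centres rather than at each observed
correlation introduces a within-bin approximation; with 0.1-wide bins the
calibration error is small — the test suite checks that the rejection
rate at 0.05 over 1000 null pairs (with 500 draws per stratum) stays
inside the exact binomial confidence band. No multiplicity adjustment is
applied to the final table by default; `adjust_mscor = "BH"` is available.

## The synthetic generator

`generate_dataset()` draws from a Gaussian linear model: miRNAs i.i.d.
normal; each planted triplet picks a disjoint block of
`shared_per_triplet` miRNAs and sets both partners to
$\mu_g - \beta \sum_j m_j + \varepsilon$ with independent noise; decoy
pairs get the same *catalog* wiring but $\beta = 0$ expression; background
genes are pure noise; random background edges are sprinkled at density
`background_edge_density` so stage A has non-trivial rejection behaviour.
Closed forms used by the tests: with unit-variance miRNAs and noise, a
planted pair has
$cor = \beta^2 m_{shared} / (\beta^2 m_{shared} + \sigma^2_\varepsilon)$
and, conditionally on its miRNAs, the partners are independent, so
population mscor equals the correlation itself; decoys have mscor 0.

Generator defaults — 200 samples, 150 miRNAs, 100 genes across the three
biotypes, 5 planted triplets with 2 shared miRNAs each, 20 decoys,
$\beta = 0.8$, unit noise — describe a regime where planted pairs have
population correlation ≈ 0.56 and per-edge $|r| ≈ 0.53$: strong but not
trivial signals at TCGA-cohort-like sample counts. What the generator does
**not** emulate: count noise (expression is Gaussian on the log scale by
construction), batch effects, correlated miRNA co-expression, competition
saturation/non-linearity, and tumour-vs-normal differential structure
(run the generator twice with different $\beta$ for that). Passing tests
on this generator therefore demonstrate the statistical machinery is
correct and calibrated under its assumptions, not that real tissues meet
those assumptions.

## Determinism and numerical choices

* One master seed in `cerna_config()`; stage and per-test seeds are
  derived by hashing stage names, so stages are individually reproducible
  and two identical runs produce byte-identical output files.
* Zero-variance features are dropped (warning) before any correlation.
* Ties in the output ordering break by p-value, then mscor descending,
  then identifiers — total and deterministic.
* Expression TSVs are written with `%.17g`, making read/write round-trips
  lossless.
* Degenerate inputs (constant response, misaligned vectors, overlap counts
  violating $\max(0, K+O-N) \le x \le \min(K,O)$, missing null strata)
  are errors, not silent NA propagation.

## Problem sizes in the test suite

The suites run the closed-form mscor check at $n = 10{,}000$, the
dual-route partial-correlation check on 1000 random instances
($n = 100$, up to 5 conditioners), null calibration on 1000 pairs with
500 draws per stratum, and the end-to-end recovery run at the generator
defaults (5 planted / 20 decoys, $n = 200$) — sizes chosen so the whole
suite completes in well under a minute while keeping every binomial
confidence interval tight enough to be meaningful.

## Known limitations

* The catalog is taken at face value: no sequence-based binding-site
  prediction, no identifier alias resolution, no evidence weighting.
* Stage B's permutation test is exchangeable-samples based; it does not
  model confounders (purity, batch) that could induce or mask
  anti-correlation.
* The null model conditions on $(m, k)$ but not on the miRNA–gene
  correlation structure of the observed data; a permutation-based null
  (shuffling miRNA columns) would preserve it and is a natural extension.
* circRNAs and tsRNAs are outside the supported biotype set.
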