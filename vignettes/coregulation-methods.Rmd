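---
title: "Co-regulation networks from heterogeneous contrasts: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-regulation networks from heterogeneous contrasts: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Public RNA-seq repositories hold tens of thousands of small two-group
experiments, run in different labs under different conditions. Most of these
studies have 10 or fewer samples per group, far too few to estimate a
per-study gene–gene correlation, and the batch structure is completely
confounded with the experimental designs, so pooling samples and computing
Pearson correlations mostly measures batch trends. `coregnet` takes a
different route: it asks, across many independent contrasts, *how often two
genes are differentially expressed together*, and assesses that count
against a null model that preserves each gene's overall propensity to be a
DEG and each contrast's DEG yield.

This sidesteps batch effects entirely (each contrast is analysed only
against itself), and it is agnostic to the *direction* of co-regulation, so
it can find pairs that move together in some conditions and apart in others
— relationships that pooled correlation is structurally unable to see.

## The model

**Binary DEG matrix.** Each contrast contributes one column: a gene is 1 if
it passes the configured differential-expression test in that contrast,
else 0. A signed companion matrix records the direction of change
({−1, 0, +1}), nonzero exactly where the binary matrix is 1. The default
caller is a Welch t-test on log2 values with BH adjustment
(`alpha = 0.05`) and a fold-change floor (`min_lfc = 1`); because
everything downstream consumes only the binary/signed matrices, any
external DE caller can be substituted via `read_deg_matrix()`.

**Co-regulation count.** For a pair of genes, `n` is the number of
contrasts where both are 1, out of `K` contrasts, and `n_discordant` counts
the co-DEG contrasts with opposite signs.

**Fixed-margin null.** Under the null, genes are DEGs as often as they are
in the real data, and each contrast yields as many DEGs as it really does —
only the joint placement is random. Operationally: sample random 0/1
matrices with *exactly* the observed row and column sums, using curveball
trades (pick two rows, pool the columns unique to either, reshuffle and
deal back in the original amounts). Each sampling is an independent restart
from the observed matrix with `5 × nnz` trades, where `nnz` is the number
of 1s; restarts make the ensemble embarrassingly parallel and trivially
reproducible, and the mixing of this default is validated against
exhaustive enumeration of small state spaces in the test suite. A naive
checkerboard-swap sampler serves as an independent oracle there.

**Beta-binomial fit.** The per-contrast co-occurrence probability of a pair
varies across contrasts (contrasts have very different DEG yields), so the
null count over `K` contrasts is modelled as beta-binomial: the latent
success probability is Beta(α, β) and

$$P(X=n \mid K,\alpha,\beta)=\binom{K}{n}
  \frac{B(n+\alpha,\,K-n+\beta)}{B(\alpha,\beta)}.$$

Each retained pair's null vector (its co-occurrence count in each of the
1000 samplings, the default) is fitted by the method of moments: with mean
`m` and variance `v`, solve `m = Kα/(α+β)` and the beta-binomial variance
identity. Moments were chosen over maximum likelihood because millions of
pairs must be fitted and a 1000-point moment fit is closed-form and
accurate at that sample size. Two boundary cases need care:

* *No overdispersion* (`v` at or below the binomial variance): the
  fixed-margin ensemble is often slightly *under*dispersed relative to a
  binomial, in which case the beta parameters diverge. The fit falls back
  to a binomial-matching limit, `α + β = 10⁶` at the observed mean.
* *Constant-zero vector*: flagged degenerate; the pair's p-value is 1 when
  its observed count is 0 and the machine floor otherwise.

The p-value is the inclusive upper tail `P(X ≥ n)`.

**FDR family.** BH adjustment is computed with the family size set to all
`choose(G, 2)` gene pairs, not just the pairs retained by the `min_obs`
filter. The filter (`min_obs = 2` by default) conditions on the test
statistic itself — every retained pair necessarily has a small upper-tail
p-value — so adjusting within the filtered set alone would reject
essentially everything even on pure noise. Treating filtered-out pairs as
non-rejections restores the intended family and, on fully null synthetic
matrices, brings the realised false-positive fraction to (well below) the
nominal level; this is verified in the test suite. `compute_fdr()` exposes
the family size as an argument for users who import an externally filtered
table.

**Non-linear score.** For a significant pair,

$$\mathrm{score} = 1 - \left|1 - \frac{2\,N_{+/-}}{N}\right|,$$

which is 1 when concordant and discordant co-regulation are equally common
and 0 when the pair is purely one or the other. Pairs at or above
`score_cutoff = 0.5` are labelled `nonlinear`; below it, the discordant
fraction decides `linear_concordant` vs `linear_discordant`. The 0.5 split
is a convention, exposed as a parameter.

**Simpson's-paradox screening.** A pair follows Simpson's paradox when its
genes correlate with one sign inside every contrast but with the opposite
sign when the samples are pooled — the pooled trend being a
between-contrast confounder. Unlike a visual judgement from a scatter
plot, a reproducible boolean needs explicit thresholds; the defaults are
`|r| ≥ 0.3` within each contrast (all sharing one sign, over at least 3
contrasts, both groups of a contrast pooled) and `|r| ≥ 0.3` with the
opposite sign for the pooled correlation. All three are parameters of
`detect_simpson()`.

**Scale-free cutoff and modules.** The final network keeps pairs with
`fdr ≤` a cutoff chosen by scanning candidates and scoring each network's
degree distribution with the standard scale-free topology fit: degrees are
binned logarithmically (powers of 2), and `log10` frequency density is
regressed on `log10` bin centre; the candidate maximising R² subject to a
negative slope wins, ties breaking toward the stricter cutoff. Modules come
from Louvain detection, re-applied recursively to any module above
`max_module_size = 1000` until none exceeds the bound or a subgraph
refuses to split; modules below `min_module_size = 3` are labelled
unassigned. Biological coherence is checked by the annotation interaction
density — the fraction of edges whose endpoints share a term, among edges
with both endpoints annotated — compared against Erdős–Rényi networks on
the same genes with the same edge count (a degree-preserving rewiring null
is available behind a flag).

## The synthetic benchmark

`simulate_contrast_set()` generates the study conditions under which the
package's guarantees are stated: by default 100 contrasts of 5 + 5
samples, 200 genes, a 5% background DEG rate with random sign, Gaussian
log2-scale expression with within-group sd 0.5 and DEG effects of 3 log2
units. Effects that size give the default caller essentially complete
per-gene power (the Welch t statistic has noncentrality ≈ 9.5), so the DEG
truth table is deterministic in practice and pipeline failures cannot hide
behind caller noise.

Planted pairs are jointly DEG with a configurable `co_deg_rate` per
contrast: `concordant` pairs always share the sign, `discordant` always
oppose, `mixed` pairs flip a fair coin per co-event (the non-linear
pattern), and `simpson` pairs are discordant within every contrast while
both genes share a baseline drift along the contrast index.

The drift default (5 × the effect size) comes from the construction's
geometry: with effect `e`, noise `σ` and total drift `D`, the pooled
covariance over co-regulated contrasts is approximately
`D²/12 − e²/2` (the discordant group shifts contribute `−e²/4` at the
sample level and another `−e²/4` through the random per-contrast sign of
the contrast means), against per-gene variances `≈ D²/12 + e²/2 + σ²`. At
the defaults this predicts a pooled r of ≈ 0.6 alongside within-contrast
r ≈ −0.9, comfortably on the paradox side of the 0.3 screening thresholds.

What the generator deliberately does **not** emulate: count-distribution
realism (expression is Gaussian on the log scale, not negative binomial —
the method consumes only DEG calls and signs, so count realism is not
load-bearing), library-size or gene-length effects, correlated background
structure, and repository-scale cardinality (thousands of studies).
Passing tests therefore demonstrate the statistical machinery — margin
preservation, null calibration, power against planted signal, score
separation — not robustness to upstream quantification artefacts.

## Problem sizes and numerical choices

The test suite and the reproduction script run at desk scale, chosen as
the smallest sizes at which the statistical claims are meaningful: 200
genes × 100 contrasts with 1000 fixed-margin samplings for calibration and
power (20 seeds each), exhaustive enumeration on ≤ 4×4 matrices (10 000
samplings) for null uniformity, 10⁵–10⁶ draws for distributional oracles,
and a 2000-node planted power-law graph for the cutoff scan. Other
numerical choices: p-values are clamped to [0, 1] after tail summation;
the beta-binomial pmf is computed on the log scale via `lchoose` and
`lbeta`; the degree fit requires at least 3 occupied bins and networks of
at least 10 nodes; `coregnet_run()` falls back to the most permissive
candidate cutoff (with a warning) when every candidate yields fewer than
10 nodes, which happens routinely on small simulations.

## Known limitations

* The beta-binomial is a smooth approximation to the exact fixed-margin
  null, which is combinatorially intractable; underdispersed pairs are
  handled by the binomial-limit fallback rather than a dedicated
  underdispersed family.
* Per-pair fitting cost is linear in retained pairs × samplings; at
  repository scale the `min_obs` filter is what keeps this tractable, and
  the FDR family correction above is the price of that filter.
* Module counts depend on the Louvain resolution and the recursion bound;
  they are reproducible under a fixed seed but not canonical.
* The DEG caller is deliberately simple; for counts-with-replicates designs
  a dedicated DE tool's calls can be imported instead.
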