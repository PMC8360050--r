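---
title: "Library-size dependence of log-ratio analysis: model, diagnostics and design choices"
author: "clrDiag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Library-size dependence of log-ratio analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clrDiag)
```

## The problem

Amplicon-sequencing count tables record, for I samples and J taxa, how many
reads of each taxon were observed. The per-sample total (the library size)
is a technical artefact of the sequencing platform and carries no biological
information, so the data are compositional: only ratios between taxa are
meaningful. The standard compositional workflow transforms each sample with
the centred log-ratio (clr), `log(y_i / g(y_i))` with `g` the geometric
mean, and then applies least-squares machinery — PCA for unconstrained
ordination, redundancy analysis (RDA) for testing an explanatory variable.
Writing `L = log(Y)`, `r = rowMeans(L)`, `c = colMeans(L)` and `m` for the
grand mean, the input to log-ratio PCA is the double-centred matrix

    S[i, j] = L[i, j] - r[i] - c[j] + m,

decomposed by SVD as `S = U diag(d) t(V)`. For strictly positive data this
is exactly total-free. Real amplicon tables, however, are 40–90% zeroes, and
a pseudo-count (conventionally 1, added to every cell) must precede the log.

The pseudo-count breaks the proportionality to the library size for low
counts. For a zero cell, `L[i, j] = 0`, so after row centring
`S[i, j] ~ -r[i] + const`: every column dominated by zeroes (and by ones and
twos) carries a copy of `-r`. When library sizes — and hence `r` — vary
substantially, a sizeable share of the variance of S is the artefactual
effect of `r`. In an unconstrained analysis this effect can dominate the
first axis; in a constrained analysis it reduces power for explanatory
variables uncorrelated with `r`, and inflates the type-I error for
variables correlated with `r`.

## The diagnostics

`correlationDiagnostic()` computes, per taxon, the Pearson correlation over
samples between column j of S and `r` (written rho_Sr), paired with the
natural log of the taxon's mean count. Leakage shows as strongly negative
rho_Sr among low-abundance taxa with an increasing trend towards the
abundant taxa; in extreme regimes many abundant taxa show positive
correlations (up to about 0.5), whose mechanism — plausibly compensation
forced by the zero-sum constraint of the clr — is reproduced here, not
explained.

`contributionDiagnostic()` reports the contribution of taxon j to axis k as
`V[j, k]^2` (columns of V are unit norm, so contributions sum to one per
axis). A suspicious axis has near-equal elevated contributions across all
rare taxa — they contribute through their shared `-r` component, not
through biology — yielding a V-shaped pattern against log abundance in
extreme cases.

`varianceExplainedByR()` fits an RDA of S on `r` itself and reports the
constrained-inertia fraction. There is no universal threshold for a
"high" value, so it is most useful in matched comparisons.

`flagLibSizeDependence()` operationalizes the visual rule "increasing trend
starting from a low value". Two components must both hold: a positive
Spearman rank correlation between rho_Sr and log mean abundance at
one-sided p < 0.05, and a median rho_Sr below `rhoThreshold` (default
-0.5) within the lowest-abundance tercile. The pattern description is
inherently visual; the rank-correlation-plus-tercile rule is this package's
own sharpening of it, and both components are reported so a user can apply
a different rule.

## The simulator

`drawEffects()` / `simulateCounts()` generate counts from

    Y[i, j] ~ NB(mean = mu[i, j], size = k),
    log(mu[i, j]) = a[i] + t[j] + b[j] * x[i],

with `a ~ N(0, sigmaA^2)` the library-size effect, `t ~ N(0, sigmaT^2)` the
taxon abundance effect, and `b[j]` equal to `+log(foldChange)` or
`-log(foldChange)` (equal probability) for `nDA` randomly chosen taxa, zero
otherwise. `x` is a balanced binary treatment. The defaults — I = 50,
J = 500, sigmaT = 2, nDA = 100, NB size 1 (variance `mu + mu^2`), removal
of taxa present in fewer than 5 samples — are the reference study
conditions; `sigmaA` in 0–1 spans the regimes from no library-size
variability to a hundred-fold library-size range. All sigmas are standard
deviations. The NB size is exposed (`dispersionSize`) for robustness
studies but fixed at 1 in the reference setting.

Treatment–library-size coupling is generated by
`x[i] ~ Bernoulli(min(1, g * plogis(gamma * a[i])))`. The balancing scalar
`g` solves `sum(min(1, g * plogis(gamma * a))) = I/2` — found by root
bisection, with probabilities clipped at 1 where the product exceeds it —
and the draw is rejected until `sum(x) = I/2` exactly (cap 1e5 attempts,
then an error reporting the achieved balance). The mechanism by which
exact balance is reached is a design choice: rejection sampling preserves
the stated Bernoulli model conditionally on balance. With `gamma = 2`, the
mean correlation between `x` and `r` grows from about 0.23 at
`sigmaA = 0.25` to about 0.58 at `sigmaA = 1`
(`correlationXRSummary()`; `r` is computed from the filtered,
pseudo-counted log table, and both signed and absolute means are reported
since they differ in principle).

What the generator emulates: overdispersed counts, realistic sparsity
(around 40–45% zeroes after filtering in the reference setting), large
library-size spread, and a treatment coupled to the library size. What it
does not emulate: sequencing error, chimeras, taxonomic misassignment,
phylogenetic or co-occurrence correlation between taxa, and
compositional closure of the sequencer (counts are independent NB given
the effects, not multinomial). Passing tests therefore demonstrate the
behaviour of the methods under the stated generative model, not under all
features of real data.

## Ordination and testing

`lrPCA()` is a plain SVD of S: no column standardization (the contribution
diagnostic is only meaningful on the unscaled matrix) and uniform row
weights (matching the double-centring algebra). Whether to standardize
columns is genuinely open in practice — many PCA front ends default to
scaling — and results differ; this package fixes scale-off.

`rdaConstrained()` column-centres the response, projects it onto the
centred explanatory design by least squares, and reports
`||fitted||^2 / ||response||^2` (constrained inertia over total inertia).
`ccaConstrained()` is standard canonical correspondence analysis: the
chi-square standardized residual matrix is projected onto the
weighted-centred design with row weights proportional to library sizes.
`permutationTest()` permutes the rows of `x` freely and uses the add-one
convention `p = (1 + #(perm >= observed)) / (nPerm + 1)`, ties counted as
greater-or-equal; under an exchangeable null the test is exact. For a
single numeric explanatory vector the permuted statistics are computed in
one matrix product. Only single-factor designs are exercised by the
experiment harness; the design-matrix path is general but deliberately
unadorned (no partial RDA, no restricted permutation schemes).

With `nPerm = 199` the p-values live on the grid k/200, so rejection at
"p < 0.05" occurs with probability 9/200 = 0.045 under the null — inside
any practical calibration band, but worth knowing when comparing to runs
with 999 permutations.

## Alternative transforms

The putative mitigations wrap the same RDA/CCA machinery around different
matrices: `gbmImpute()` (geometric Bayesian-multiplicative zero
replacement, on counts or on proportions), `logProportions()`
(`log((y + 1) / n_i)`), and CCA on raw or square-rooted counts. The GBM
prior here is the normalized per-taxon geometric mean of observed
proportions with prior strength `s_i = 1`; published implementations vary
in both (some use leave-one-out priors and data-driven strengths), so both
are arguments rather than constants, and no exact equivalence to any
particular implementation's defaults is claimed. An imputed zero always
receives less mass than any observed count in its row, and observed taxa
keep their ratios exactly.

## Numerical choices and degenerate inputs

* Natural logarithm throughout; the base cancels in every correlation and
  inertia fraction.
* The pseudo-count is added to every cell, not only zeros.
* Double-centring tolerances: row/column sums of S are checked to
  `1e-10` times the opposite dimension by the class validity method.
* A constant column of S has an undefined rho_Sr; it is reported as `NA`
  and flagged rather than failing the whole table. A constant `r` is an
  error: no diagnostic is defined there.
* `assignTreatment()` with `gamma = 0` short-circuits to `g = 1` exactly.
* Overflowing NB means (`exp(a + t + b)` non-finite) abort with the
  offending cell rather than producing `NA` counts.
* Empty grids, all-zero rows/columns, constant explanatory variables and
  out-of-range axes raise informative errors at the boundary of each
  operation.

## Randomness and reproducibility

All stochastic operations draw from R's global RNG, the idiom of the
language's simulation ecosystem, rather than threading an explicit
generator object. Reproducibility enters at three levels: `SimParams@seed`
(or `simulateDataset(seed = )`) pins one dataset; `runScenario(seed = )`
pins one scenario; `runGrid(seed = )` draws independent sub-seeds per
scenario, so a grid is reproducible as a whole while scenarios with an
explicit `seed` of their own are reproducible individually. The
command-line interface exposes `--seed` and logs the seed, the config
hash and the package version.

## Scale of the built-in checks

The package's own calibration checks run the reference conditions at
reduced replication: around 1000 draws for the coupling correlations, 50
replicate draws for the sparsity summaries, 400 simulations per power
setting and 900 pooled null simulations, all with 199 permutations. At
these sizes the binomial Monte Carlo standard error of a rejection rate
is at most about 0.025, sufficient for the calibration bands asserted;
the full-scale
setting (2000 simulations, 999 permutations) is available through the same
arguments.

## Known limitations

* The experiment harness treats the analysis method as a black box
  returning one p-value per dataset; method-specific failures are counted
  and reported per scenario, not diagnosed.
* The GBM settings are a configurable family, not a pinned reference
  implementation (see above).
* CCA supports a single explanatory vector in the permutation path.
* The diagnostics flag is a heuristic decision rule on top of a visual
  pattern; near the threshold it should be read together with the plots,
  not instead of them.
* The positive rho_Sr values among abundant taxa in extreme regimes are
  reproduced but not mechanistically explained.
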