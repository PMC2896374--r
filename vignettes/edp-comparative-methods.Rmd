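---
title: "Methods: phylogenetic analysis of embryonic developmental period"
author: "edphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic analysis of embryonic developmental period}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edphylo)
```

# Scientific question and model

Auks (Alcidae) and penguins (Spheniscidae) incubate their eggs far
longer than egg size alone predicts. This package implements the
comparative analysis behind that observation: it quantifies how much
slower each species' embryonic developmental period (EDP, days) is than
an allometric expectation, and asks which life-history traits explain
the variation once shared ancestry is accounted for.

## Allometric residuals

The expectation comes from the Charadriiform interspecific power law

$$\widehat{\mathrm{EDP}} = 17.18 \, m^{0.119},$$

where $m$ is fresh egg mass in grams. The residual
$\mathrm{EDPr} = \mathrm{EDP} - \widehat{\mathrm{EDP}}$ (days) is the
response of all downstream models; positive values mean
slower-than-predicted development. The constants 17.18 and 0.119 are
taken as fixed, externally estimated quantities, not refit here
(`predicted_edp()` exposes them as arguments so the sensitivity can be
explored).

## Phylogenetic generalized least squares with Pagel's $\lambda$

Residuals are regressed on four predictors — clutch size (1 or 2 eggs),
foraging habitat (0 inshore / 1 offshore), activity pattern at the
colony (0 diurnal / 1 nocturnal) and nest type (0 open / 1 enclosed) —
under the model

$$y = X\beta + \varepsilon, \qquad
  \varepsilon \sim \mathcal{N}\!\left(0, \sigma^2 V(\lambda)\right),$$

where $V(1)$ is the Brownian-motion covariance implied by the tree
(entry $(i,j)$ = shared root-to-MRCA path length) and $V(\lambda)$
multiplies only the off-diagonal entries by $\lambda \in [0, 1]$.
$\lambda = 0$ recovers ordinary least squares on a star phylogeny;
$\lambda = 1$ is pure Brownian motion. $\lambda$, $\beta$ and
$\sigma^2$ are estimated jointly by maximum likelihood
(`fit_pgls()`).

Assumptions worth stating explicitly:

* trait evolution is adequately described by a single $\lambda$-scaled
  Brownian process on a known, error-free tree;
* predictors are treated as fixed design variables (their own
  evolution is not modeled);
* residual variance is homogeneous across the tree after the
  $\lambda$ transform.

# Consensus-tree machinery

The analysis tree in the original workflow is a majority-rule consensus
of a Bayesian posterior sample. `consensus_workflow()` chains the four
standard steps: discard a burn-in fraction, root every tree on an
outgroup, prune the outgroup, and build the consensus.

Design choices, each of which can matter:

* **Rooted-clade counting.** Because trees are rooted on the outgroup
  before summarization, clades are counted as rooted tip sets, not
  unrooted bipartitions. On rooted trees the two views coincide for
  every informative group.
* **Strict majority.** A clade is kept only if its frequency is
  *strictly* greater than 0.5 (plain majority rule, not the "extended"
  variant that greedily adds compatible minority clades). Ties at
  exactly 0.5 are therefore collapsed into polytomies.
* **Supports and lengths.** Node labels carry the clade frequency
  rounded to 3 decimals; a consensus branch length is the mean over the
  trees that contain that clade (so lengths on low-support branches
  average over fewer trees).
* **Burn-in.** `discard_burnin()` drops the first
  `ceiling(fraction * N)` trees; the fraction is a parameter (default
  0.25) rather than an absolute generation count, so it applies to a
  sample of any size.

# Synthetic-data generators

The package ships no posterior sample and no sequence data, so every
stochastic claim is checked on synthetic data with known truth.

* `simulate_yule_tree(n_tips, birth_rate, seed)` — pure-birth tree
  built forward in time: start with 2 lineages, wait
  $\mathrm{Exp}(k b)$ between splits, choose the splitting lineage
  uniformly, and add a final $\mathrm{Exp}(n b)$ wait so the tree is
  ultrametric with non-zero terminal branches. Expected depth is
  $\sum_{k=2}^{n} 1/(k b)$, which the tests verify empirically.
* `simulate_bm_traits(tree, lambda, sigma2, seed)` — multivariate
  normal draw with covariance $\sigma^2 V(\lambda)$, factorized by
  Cholesky with an eigenvalue-clipping fallback for semi-definite
  cases (duplicated tips).
* `simulate_regression_dataset()` — the full stand-in for the trait
  table: a Yule tree, Bernoulli(0.5) binary predictors (clutch coded
  1/2), a linear predictor with user-chosen coefficients, and
  $\lambda$-BM noise. Defaults (33 tips,
  $\beta = (0, -8, 2, -3.5, -4)$, $\sigma^2 = 10$) mimic the scale of
  the empirical problem: effects of a few days against ~3-day residual
  noise. An optional mode draws predictors by thresholding independent
  BM traits, giving them phylogenetic signal.
* `simulate_tree_sample()` — pseudo-posterior for the consensus tests:
  independent copies of a base tree, each internal edge NNI-rearranged
  with probability `perturb_prob`. This emulates *topological*
  posterior scatter only; it does not emulate branch-length
  uncertainty, autocorrelation along an MCMC chain, or non-uniform
  clade frequencies.

Reproducibility contract: one root seed is split into independent
sub-seeds for tree, predictors and noise (`substream_seeds()`), so
e.g. switching the predictor mode never changes the simulated tree.
All generators restore the caller's RNG state.

# Numerical choices

* **GLS by whitening, never by inversion.** $V$ is Cholesky-factorized;
  the model is solved by QR on the whitened design. A rank-deficient
  whitened design or a non-positive-definite $V$ is an error naming
  the offending columns, not a silent pseudo-inverse. The test suite
  checks the factorized path against an explicit-inverse oracle and
  against `nlme::gls` + `ape::corPagel`.
* **$\lambda$ optimization.** The profile log-likelihood is maximized
  by Brent search (`optimize`, tolerance $10^{-8}$) restarted on five
  sub-intervals of $[0,1]$, with both endpoints evaluated explicitly —
  the profile can be bimodal, and boundary optima ($\hat\lambda = 0$
  or $1$) are common at small $n$.
* **Star-tree guard.** When $V$ is diagonal, $\lambda$ is
  unidentifiable; `fit_pgls()` reports `lambda_hat = NA` with
  `lambda_identifiable = FALSE` and returns the OLS fit rather than an
  arbitrary boundary value.
* **$\sigma^2$ and standard errors.** The ML $\sigma^2$ (divisor $n$)
  enters the likelihood; coefficient standard errors use the unbiased
  divisor $n - k$, matching standard GLS practice.
* **$r^2$** is computed in the whitened space as $1 - RSS/TSS$ with
  the TSS taken around the GLS intercept-only fit, so it reduces to
  the classical coefficient of determination when $V = I$.
* **Canonical Newick.** `write_newick()` orders children by their
  lexicographically smallest descendant label, making serialization a
  pure function of the tree — byte-identical output for
  topologically identical trees, which the round-trip tests rely on.

# Resolved ambiguities

Several conventions in this literature are genuinely ambiguous; the
package picks a default and exposes the alternative:

* **Degrees of freedom.** Reference analyses of this dataset used
  $df = n_{\mathrm{taxa}}$ for coefficient $t$-tests. That is the
  default (`df_convention = "n_taxa"`); the conventional
  $df = n - k$ is available as `"n_minus_k"`, and both one- and
  two-sided $p$-values are always reported side by side.
* **One-sided tests.** Directional predictions (all predictors were
  expected to slow or speed development in a known direction) motivate
  the one-sided default for significance markers (`**` $p<0.01$,
  `*` $p<0.05$); `coefficient_tests(fit, tail = "two")` switches.
* **"Standardized" coefficients.** `standardized_coefficients()`
  returns $z$-scored (per-SD) slopes; the raw per-unit slopes remain
  the primary report, since all predictors are binary and per-unit
  effects are directly interpretable in days.
* **31 vs 33 taxa.** Two penguins lack foraging-habitat data. The
  default policy drops those taxa ($n = 31$); `drop_variable` keeps
  all 33 and omits the predictor; `impute_mode` is available for
  sensitivity analysis. The policies give materially similar
  coefficients on the packaged data (see
  `analysis/03_pgls_fit.R`).
* **Burn-in size.** Absolute burn-in counts depend on chain length, so
  the workflow takes a fraction (default 0.25) instead.

# Problem sizes

The simulation studies in the tests and in `analysis/04_simulation_study.R`
use sizes chosen for statistical resolution within a short runtime:
recovery at $n = 100$ tips (where $\hat\lambda$'s sampling error is
small enough that a $\pm 0.1$ check on its mean is meaningful over a
few hundred replicates), type-I calibration at $n = 50$ over 200–400
null replicates (binomial SE on a 5% rate of about 1 point), and
oracle agreement on hundreds of small random instances ($n \le 10$)
where explicit-inverse arithmetic is well-conditioned.

# Limitations

* The published consensus tree's branch lengths are not available, and
  the sequence data needed to re-infer them are outside this package's
  scope. The packaged tree (`standin_tree()`) is a synthetic stand-in:
  the accepted family-level topology with Grafen-style branch lengths.
  Numbers computed on it (the $\hat\lambda$, coefficients and $r^2$
  printed by `run_paper_analysis()`) characterize the method on a
  plausible tree; they are companions to, not reproductions of, the
  published fit.
* The NNI pseudo-posterior is a deliberately simple model of
  topological uncertainty (see above).
* $\lambda$ is searched on $[0, 1]$; values above 1 are representable
  in `lambda_transform()` when the matrix stays positive definite but
  are not part of the ML search space.

# Worked example

```{r example, eval = FALSE}
traits <- auk_penguin_traits()
head(residual_table(traits))

report <- run_paper_analysis(traits, standin_tree())
print(report)
write_report(report, "results/pgls_drop_taxa")
```

The numbered scripts under `analysis/` run the full workflow and write
their tables under `results/`.
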