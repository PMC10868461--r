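---
title: "Inference for the weighted Pearson correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inference for the weighted Pearson correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wpcor)
```

## The problem

Given paired observations $(X_i, Y_i)$ with probability weights $w_i > 0$,
$\sum_i w_i = 1$, the weighted Pearson correlation is

$$\hat\rho_w = \frac{\sum_i w_i (X_i - \bar X_w)(Y_i - \bar Y_w)}
  {\sqrt{\sum_i w_i (X_i - \bar X_w)^2 \sum_i w_i (Y_i - \bar Y_w)^2}},
  \qquad \bar X_w = \sum_i w_i X_i.$$

Weights arise naturally — population sizes behind aggregate rates,
down-weighting of suspect observations — and with $w_i = 1/n$ the
estimator is the classic $\hat\rho$.  Both are consistent for the same
population correlation $\rho$, but they do **not** share a sampling
distribution: $\hat\rho_w$ has asymptotic variance proportional to
$\sum_i w_i^2$ rather than $1/n$.  Statistical software that feeds
$\hat\rho_w$ into the usual $t$-statistic
$\hat\rho_w\sqrt{(n-2)/(1-\hat\rho_w^2)}$ therefore produces an invalid
test whose type-I error is inflated even under bivariate normality — the
failure this package exists to repair.

## Large-sample theory

Writing $\hat\rho_w = g(V)$ with
$V = (\bar X_w, \bar Y_w, \overline{X^2}_w, \overline{Y^2}_w,
\overline{XY}_w)$, the delta method gives

$$\hat\rho_w \sim \mathrm{AN}\Bigl(\rho,\; \textstyle\sum_i w_i^2 \,
  d\,\Sigma\,d'\Bigr),$$

where $\Sigma$ is the $5\times 5$ covariance matrix of
$(X, Y, X^2, Y^2, XY)$ and $d$ is the gradient of $g$
([gradient_d()]).  Under bivariate normality $d\Sigma d' = (1-\rho^2)^2$,
recovering the familiar form.  The asymptotic relative efficiency of
$\hat\rho_w$ to $\hat\rho$ is $(1/n)/\sum_i w_i^2 \le 1$
([are_fixed()]); for uniform-spacing random weights
$E(\sum_i W_i^2) = 2/(n+1)$, so the efficiency tends to $1/2$.

The plug-in estimate $\widehat{\mathrm{Var}}(\hat\rho_w) = \sum_i w_i^2\,
d\hat\Sigma d'$ uses weighted moment estimators with an $n/(n-1)$
correction so every ingredient reduces to its unbiased unweighted
counterpart at equal weights ([sigma_hat()], [variance_rhohat()]).  The
same estimator serves random weights, whose observed values are moment
estimates of their means.

## The tests

* **Asymptotic** — $(\hat\rho_w - \rho_0)/\widehat{\mathrm{se}}$ against
  the standard normal, a Wald-type test with $\hat\rho_w$ plugged into
  the gradient.  It is anticonservative in small and moderate samples:
  in this package's own study grid its one-sided size under bivariate
  normality with spacing weights is about 0.077 at $n = 50$, 0.066 at
  $n = 100$ and 0.057 at $n = 200$ ($10^4$ replications) — and the
  equal-weight version behaves the same (0.073 at $n = 50$), so this is
  a property of the delta-method normal approximation itself, not of the
  weighting.  (A score-type variant that plugs the null value into the
  gradient sits closer to nominal, 0.055 at $n = 50$, but the Wald form
  is the canonical "asymptotic test" here and is what the comparisons
  report.)  Prefer the permutation tests unless $n$ is large.
* **Naive permutation** — permute $y$, compare $\hat\rho_w$ to its
  permutation distribution.  Exact only under exchangeability
  (e.g. equal weights and independent marginals); can be badly mis-sized
  when correlation-zero does not imply independence.
* **Studentized permutation (Perm-1, Perm-2)** — the statistic
  $\hat\rho_w$ divided by the root of the plug-in variance, recomputed on
  every permuted sample, which makes the permutation and sampling
  distributions share a normal limit regardless of exchangeability.
  Perm-1 plugs $\hat\rho_w$ into the gradient; Perm-2 plugs in the null
  value 0.
* **Fisher-Z variants (Perm-Z1, Perm-Z2)** — studentize
  $z(\hat\rho_w) = \tfrac12\log\{(1+\hat\rho_w)/(1-\hat\rho_w)\}$ with the
  delta-method variance $\widehat{\mathrm{Var}}(\hat\rho_w)/(1-\rho^2)^2$.
  Perm-Z2 (plug-in 0) has the most robust small-sample type-I error
  control across the validation scenarios and is the package default.
* **Perm-ave** — instead of holding weights fixed to $x$, each replicate
  uses $w_i^* = (w_i + w_{\pi(i)})/2$.  Averaged weights of two
  probability vectors again sum to one, so no renormalization is applied.
* **Comparators** — the conventional $t$-test and a delete-one jackknife
  test are included for benchmarking only; neither is recommended.

Two conventions deserve a note.  The Fisher transform is implemented with
the **positive** sign, $z = +\tfrac12\log\{(1+\rho)/(1-\rho)\}$, so the
one-sided rejection direction agrees with the raw estimator; and the
variance of the transformed statistic is the delta-method form
$\mathrm{Var}(\hat\rho)/(1-\rho^2)^2$, the only version dimensionally
consistent with studentization (with plug-in $0$ the choices coincide, so
Perm-Z2 is unaffected either way).  For Perm-ave, which needs a variance
plug-in that neither extreme pins down, we use the $\hat\rho_w$ plug-in
(the Perm-1 convention) since the variant is defined by its weight rule,
not its studentization.  The studentized statistic itself is read as
$(\hat\rho_w - \rho_0)/\sqrt{\sum_i w_i^2\, d\hat\Sigma d'}$, the only
normalization consistent with the large-sample variance above.

### Non-zero nulls

A permutation test cannot target $H_0: \rho = \rho_0 \ne 0$ directly.
[decorrelate()] standardizes both variables and applies
$A(\rho_0) = \bigl(\begin{smallmatrix}1 & 0\\
-\rho_0/\sqrt{1-\rho_0^2} & 1/\sqrt{1-\rho_0^2}\end{smallmatrix}\bigr)$,
which maps a pair with correlation $\rho_0$ to an uncorrelated pair; the
original hypotheses become $H_0: \rho(U,V) = 0$ versus
$H_1: \rho(U,V) > 0$ and any zero-null test applies ([test_nonzero()]).

The standardization step admits two conventions: plain sample moments or
weighted ones.  Weighted moments have the algebraic appeal that
de-correlating at $\rho_0 = \hat\rho_w$ yields weighted correlation
exactly zero.  But in a level study (bivariate normal data transformed to
$\rho = 0.3$, $n = 50$, spacing weights, Perm-Z2, $10^4$ replications)
the weighted convention rejects at 0.038 versus 0.050 for the unweighted
one — entangling the weights with the standardization makes the
downstream permutation test noticeably conservative.  The package
therefore standardizes with the **unweighted** sample mean and SD by
default and exposes `standardize = "weighted"` for the algebraic
identity.

## Numerical choices

* Weights are validated to be strictly positive and renormalized to sum
  one; a deviation beyond $10^{-6}$ triggers a warning rather than an
  error, since frequency-style weights are a common and recoverable slip.
* If the quadratic form $d\hat\Sigma d'$ is non-positive (possible at
  very small $n$ through cancellation), it is clamped to $10^{-12}$ with
  a warning, so studentized statistics remain defined in every
  permutation replicate and the permutation distribution keeps exactly
  $B$ points.
* The Fisher-Z path clamps $|\hat\rho_w|$ at $1 - 10^{-8}$ before
  `atanh`, so perfectly correlated permuted replicates produce large
  finite statistics instead of `NaN`.
* Monte Carlo p-values use add-one smoothing $(1 + \#\{T^\pi \ge
  T\})/(B+1)$ — always valid, never zero; full enumeration uses the exact
  count over $n!$; ties count toward the null; two-sided p-values double
  the smaller tail, capped at 1 (only the one-sided test has a canonical
  definition here).
* Default $B = 1000$ permutations; reproducibility is by explicit seeds,
  and seeded calls restore the caller's RNG stream.

## The simulation harness

[sample_scenario()] implements six zero-correlation bivariate
distributions: standard bivariate normal; an elliptical heavy-tailed law
$r\,\mathrm{diag}(2,1)\,u$ with $r \sim \mathrm{Exp}(1)$ and $u$ uniform
on the unit circle (read as the product $r\,S\,u$; the variables are
dependent with correlation zero); the uniform distribution **on** the
unit circle ($X^2 + Y^2 = 1$, strongly dependent); sum/difference of iid
$t_{4.1}$ variables (uncorrelated, barely-finite fourth moments);
bivariate $t_5$ with identity **scale** matrix (covariance $\tfrac53 I$ —
the scale reading keeps the standard construction $Z/\sqrt{\chi^2_5/5}$);
and independent $\mathrm{Uniform}(0,1)$.  These probe exactly the ways a
correlation test can fail: heavy tails, bounded support, and dependence
without correlation.

[induce_correlation()] standardizes by the **analytic** population
moments of each scenario (normal: 1; uniform: $1/\sqrt{12}$; circular:
$1/\sqrt2$; $t_{4.1}$ sums: $\sqrt{2\cdot 4.1/2.1}$; $t_5$:
$\sqrt{5/3}$; the elliptical law: $\sigma_X = 2$, $\sigma_Y = 1$ from
$E r^2 = 2$) and applies the lower-triangular factor $B(\rho)$ of the
target correlation matrix, so the output has population correlation
exactly $\rho$.

[type1_error_study()] and [power_study()] record rejection-rate grids
over (scenario $\times$ $n$ $\times$ method).  Study conditions follow
the validation design: one-sided tests at $\alpha = 0.05$; spacing
weights from $\mathrm{Beta}(1,1)$ order statistics regenerated every
1000 replications (leverage weights $1 - h_{ii}$, recomputed per
replicate, are the data-dependent alternative; the hat matrix includes
an intercept column, the convention under which $1 - h_{ii} > 0$ is
guaranteed); every method in a cell sees the same replicates; every cell
is seeded by a hash of its own identity, so results replay exactly and
do not depend on execution order.

The full published design uses $n \in \{10, 20, 50, 100, 200\}$ with
$10^4$ replications and $10^3$ permutations per test.  The package's own
validation suite runs a scaled grid — 2000 replications and 500
permutations over $n \in \{10, 20, 50\}$ — which bounds each cell's
Monte Carlo standard error at about $0.005$ and keeps the whole suite in
the minutes range; the conclusions (t-test inflation, asymptotic-test
convergence by $n = 50$, Perm-Z2 robustness) are invariant to this
scaling.

### What the generator does and does not emulate

The scenarios cover tail weight, boundedness, and zero-correlation
dependence, under weights that are independent of the data (spacings) or
leverage functions of $x$.  They do not emulate measurement error,
clustered or serially dependent sampling, missingness, or weights
correlated with $y$ — a passing grid says nothing about those settings.
Real weighted analyses (e.g. country-level rates weighted by population)
also involve weights spanning orders of magnitude, which lower
$\sum w_i^2$ efficiency further than the spacing scheme does.

## Limitations

* The asymptotic test is anticonservative below $n \approx 50$; use
  Perm-Z2 there.
* No confidence intervals are provided — the variance theory supports
  them, but the testing problem is the scope here.
* The jackknife comparator is a convention (delete-one, renormalized
  weights, normal reference), not a published procedure; it is labelled
  non-canonical in its output.
* Power of the permutation tests trails the asymptotic test at moderate
  effect sizes; the trade is type-I validity.
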