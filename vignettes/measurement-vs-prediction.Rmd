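---
title: "Measurement versus prediction in questionnaire construction: methods"
author: "cttselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement versus prediction in questionnaire construction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cttselect)
```

## The model

`cttselect` works inside classical test theory: an observed sum score
decomposes as $X = T + E$, with the true score $T$ defined as the expected
score over hypothetical replications and $E$ the replication error. Over a
population of respondents, reliability is the squared sum-score/true-score
correlation, $\rho^2_{XT} = \sigma^2_T / \sigma^2_X$. True scores are
unobservable, so reliability is estimated through internal consistency:
coefficient alpha,
$$
\alpha = \frac{n}{n-1}\left(1 -
  \frac{\sum_i \sigma_i^2}{\sum_i\sum_j \sigma_i\sigma_j\rho_{ij}}\right),
$$
which equals the reliability when items are parallel and is otherwise a
lower bound (given mutually uncorrelated errors). Criterion validity of the
sum score against an external criterion $Y$ is
$$
\rho_{XY} = \frac{\sum_i \sigma_i \rho_{iY}}
  {\sqrt{\sum_i\sum_j \sigma_i\sigma_j\rho_{ij}}}.
$$
Both formulas need only the first- and second-order item statistics, which
is why the package's central container, `corr_structure()`, holds exactly
that: a correlation matrix, optional SDs, optional item–criterion
correlations. Analyses can therefore start from a published table as well
as from raw data (`estimate_structure()`).

Assumptions worth keeping in mind: errors are uncorrelated across items
(alpha's lower-bound property needs this), the criterion relation is
linear-in-correlation (a binary diagnosis enters through ordinary Pearson,
i.e. point-biserial, correlations), and all statistics are population
plug-ins — no sampling variance or confidence intervals are computed.

## Standardized versus covariance mode

When a structure carries no SDs, all $\sigma_i$ are set to 1 and alpha
becomes the standardized alpha $n\bar r/(1+(n-1)\bar r)$. This is the
default because published correlation tables typically omit SDs; it is also
the only mode in which results from such tables are exactly reproducible.
When SDs are available (raw data, or a table that prints them), supply them
and every formula switches to the covariance metric unchanged. The bundled
ten-item depression example ships in standardized mode for precisely this
reason: its source published correlations only. Consequences we accept and
document rather than hide:

- the published prediction-based scale's validity evaluates to 0.392 at
  unit SDs where its source reports 0.40 (computed from raw data with
  unpublished SDs), and
- the corrected item-total column recomputes only approximately (item 9:
  0.287 vs a printed .28).

## Item selection

`backward_select()` implements the field's standard stepwise procedure: at
each step, compute the objective with each surviving item deleted
(alpha-if-item-deleted under the measurement objective,
validity-if-item-deleted under the prediction objective) and remove the
item whose deletion maximizes it. Two stop rules are supported, mirroring
the two clauses used in practice — a target number of final items `k`, or
an objective `threshold` ("the minimal value deemed sufficient"), checked
*before* each removal so an already-sufficient pool is not shortened. When
both are given, `k` wins. An unreachable threshold terminates at the
minimum defensible scale size of 2 with `threshold_unreached = TRUE`.

Numerical choices:

- **Tie-break.** Deletions equal within `1e-12` are resolved toward the
  smallest item label. The procedure is otherwise order-independent, so
  this makes runs fully deterministic.
- **Near-tie flagging.** Steps where the best and runner-up deletion differ
  by less than 0.01 are flagged in the trace. With correlations published
  to two decimals, such steps are exactly where selected-set membership is
  an artifact of rounding: on the bundled example the greedy trajectories
  land on sets differing from the originally selected ones in one or two
  near-tied items, while the headline statistics of the published sets
  (alpha 0.80/0.63, validity 0.33) reproduce exactly. The flags make this
  fragility visible instead of silently reporting one of several
  rounding-equivalent answers.
- **Enumeration cap.** `exhaustive_best_subset()` refuses pools where
  `choose(n, k)` exceeds `1e6` subsets (configurable), reporting the total
  subset count $2^n - 1$ — the combinatorial reason stepwise selection
  exists. `count_subsets()` returns that count with an exact decimal string
  attached, since past $n = 53$ a double no longer represents it exactly.
- **Replayability.** Traces store the structure and every per-step
  objective value; tests re-evaluate each recorded step and require exact
  equality.

Forward selection is not implemented; backward elimination is the procedure
in standard use, and the exhaustive search covers small-pool needs.

## The paradox module

`true_score_model()` specifies a population model by the true-score
covariance matrix plus per-item error variances (errors uncorrelated by
construction), making reliability, alpha, and criterion validity exactly
computable — no estimation involved. `build_orthogonal_model(n, r)` is the
extremal case: unit-variance items with mutually orthogonal true scores,
each individually reliable. Its sum score has reliability $r$ while alpha
is exactly 0 (the implied covariance matrix is the identity, so the
numerator and denominator of alpha's variance ratio coincide). This
realizes the endpoint claim that a reliability of .8 can coexist with an
alpha of zero. `alpha_gap_curve()` interpolates between this orthogonal
pole and parallel items via the inter-trait correlation, showing the
alpha–reliability gap shrinking monotonically to zero. The criterion in
these models is a weighted sum of true scores plus independent noise —
the simplest structure under which the bound
$\rho_{XY} \le \sqrt{\rho^2_{XT}}$ provably holds; equal weights are the
default.

`check_validity_bound()` reports the bound's slack and, on violation,
points at the correct reading: a validity above $\sqrt{\alpha}$ signals
alpha underestimating reliability, not broken mathematics.

## The simulator

`simulation_design()` emulates the data-collection setting the package is
aimed at: $q$ correlated standard-normal factors, continuous item responses
$\lambda_i' f + \sqrt{1 - \lambda_i'\Phi\lambda_i}\,\varepsilon_i$ (unit
total variance), discretized at per-item thresholds into ordered categories,
and a binary criterion from thresholding a liability $w'f + e$ at its
population prevalence quantile. Defaults, chosen once as a realistic
emulation of a depression-screening study and not revisited:

| parameter | default | rationale |
|---|---|---|
| categories | 0–3, thresholds `qnorm(c(.25,.5,.75))` | four-point Likert convention; equal-probability cuts |
| items / factors | 10 items, 2 factors, $r_{F} = .4$ | mixed (not unidimensional) pool like the bundled example |
| loadings | 0.5–0.8, five items per factor | moderate-to-strong symptom loadings |
| criterion | equal factor weights, noise var 1, prevalence 0.25 | diagnosis drawing on both factors; the source study's prevalence is unpublished, so this is a configurable convention |
| n | 242 | the bundled example's sample size |

Under these defaults the implied item–criterion correlations span
~0.25–0.40 and inter-item correlations ~0.09–0.51, comparable to the
bundled table (.13–.35 and .10–.57).

`implied_structure()` computes the *exact* population Pearson structure of
the discretized scores — univariate category moments from normal tail
areas, cross-moments from bivariate-normal rectangle probabilities
(evaluated by one-dimensional quadrature of
$\phi(z)\Phi\!\big((k-\rho z)/\sqrt{1-\rho^2}\big)$ with
`stats::integrate`, accurate to ~1e-10) — so recovery tests compare sample
statistics against the correct attenuated targets rather than against
latent loading products. Reproducibility is contractual: a given
`(design, seed)` yields identical output, and the global RNG state is
restored afterwards.

What the generator does **not** emulate: item-specific response styles,
missing data, differential item functioning, longitudinal structure, or
the ordinal-vs-interval debate (correlations are Pearson on integer
scores, matching how published item tables are built, not polychoric).
Passing recovery and trade-off tests therefore show that the machinery is
correct under a clean factor model — not that any particular real data set
behaves this way.

## Problem sizes and tolerances in the test suite

Closed-form statistics are checked against an independent brute-force
oracle (explicit loops over covariance entries) to 1e-12. Property checks
use 1,000 random positive-semidefinite structures and 1,000 random
true-score models under fixed seeds. Recovery uses one sample of
$n = 10^5$ respondents (sampling error per correlation ~0.003, tested
against a 0.02 band) and the trade-off experiment uses 20 replications at
the design's native $n = 242$, $k = 5$ — sizes at which the whole suite
runs in well under a minute while leaving order-of-magnitude headroom
between expected and tolerated error.

## Limitations

- No sampling theory: alpha and validity are plug-in statistics; no
  standard errors, confidence intervals, or corrections for the chance
  capitalization that any data-driven subset search invites.
- Reliability estimation for low-inter-correlation scales is exactly the
  thing alpha cannot do — the paradox module demonstrates the failure but
  the package deliberately does not offer an alternative estimator
  (test–retest or multidimensional-model based), as those need designs and
  data beyond a correlation table.
- Guttman's lambdas, polychoric/ordinal alpha, and IRT information-based
  selection are out of scope.
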