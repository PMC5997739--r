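# cttselect

Classical test theory (CTT) statistics and goal-directed item selection for
questionnaire construction.

Patient-reported outcome questionnaires serve two distinct goals. For
**measurement**, the sum score should represent the respondent's attribute
precisely, so construction methods maximize internal consistency. For
**prediction**, the sum score should forecast an external criterion (for
instance a gold-standard clinical diagnosis), so construction methods
maximize criterion validity. These two goals reward *opposite* inter-item
correlation patterns, and selecting items for one goal degrades the other.
`cttselect` makes both construction routes, and the tension between them,
directly computable from either raw respondent data or a published
correlation table.

## The statistics

For items with standard deviations σᵢ, inter-item correlations ρᵢⱼ, and
item–criterion correlations ρᵢY:

- **Coefficient alpha** (internal consistency, a lower bound to sum-score
  reliability):

  α = n/(n−1) · (1 − Σᵢσᵢ² / ΣᵢΣⱼσᵢσⱼρᵢⱼ)

- **Predictive validity** of the sum score X against criterion Y:

  ρ_XY = ΣᵢσᵢρᵢY / √(ΣᵢΣⱼσᵢσⱼρᵢⱼ)

High inter-item correlations push α up but push ρ_XY down; that is the
trade-off. Both statistics drive a stepwise backward selection
(`backward_select()`): at each step the item whose deletion maximizes the
objective — alpha-if-item-deleted (α₋ᵢ) or validity-if-item-deleted
(ρ_{X₋ᵢY}) — is removed, until a target length or threshold is reached.
`exhaustive_best_subset()` enumerates all subsets of a given size for small
pools (there are 2ⁿ−1 candidate subsets: 1023 at n = 10, over a trillion at
n = 40, hence the stepwise procedure).

The package also makes the **reliability–validity paradox** computable.
Validity can never exceed √(reliability), which seems to make high
reliability a prerequisite of prediction — yet prediction-optimal scales
have *low* alpha. The resolution is that alpha is only a lower bound:
`build_orthogonal_model(5, 0.8)` constructs a population true-score model
whose sum score has true reliability 0.8 while coefficient alpha is exactly
0, and `alpha_gap_curve()` traces how the alpha–reliability gap grows as
inter-item correlations fall. A Likert-item simulator
(`simulation_design()`, `simulate_sample()`) with latent factors and a
dichotomized liability criterion lets you study all of this on synthetic
respondent samples with known population structure.

## Worked example

The package bundles the published correlation matrix of ten four-point
Likert depression items and a binary diagnostic-interview criterion
(n = 242; only correlations were published, so statistics use unit item
SDs — "standardized mode"):

```r
library(cttselect)
fix <- depression_items()
describe_structure(fix)
#> Item pool description (n = 242)
#>   inter-item correlations: 0.10 to 0.57
#>  item item_total r_criterion
#>     1       0.45        0.22
#>     ...
#>    10       0.67        0.35
#>   full pool: alpha = 0.83, validity = 0.38

compare_goals(fix, k = 5, reference = list(alpha = 0.93, validity = 0.40))
#> Goal comparison at k = 5 (backward search)
#>   measurement: Scale {2,3,4,8,10}: alpha = 0.80, validity = 0.35
#>   prediction:  Scale {1,4,6,7,10}: alpha = 0.69, validity = 0.40
#>   overlap: 4,10 (2 items)
#>   measurement vs reference: alpha -14% validity -11%
#>   prediction vs reference:  alpha -25% validity -1%
```

The measurement-built five-item scale has the higher alpha, the
prediction-built scale the higher validity, and the two scales share only
two items: the construction goal determines the questionnaire. The
`reference` here is the published full-length (20-item) questionnaire the
ten items were drawn from (alpha 0.93, validity 0.40). Several deletion
steps in this pool are near-ties at the published two-decimal precision;
`backward_select()` flags them, because set membership (not the headline
statistics) is sensitive to rounding there. The published five-item sets
`{2,3,5,8,10}` and `{4,6,7,9,10}` evaluate to alpha 0.80 / 0.63 and
validity 0.33 / 0.39 on this table:

```r
round(cronbach_alpha(fix, c(2, 3, 5, 8, 10)), 2)      # 0.80
round(cronbach_alpha(fix, c(4, 6, 7, 9, 10)), 2)      # 0.63
round(predictive_validity(fix, c(2, 3, 5, 8, 10)), 2) # 0.33
```

And the paradox in two lines:

```r
m <- build_orthogonal_model(5, 0.8)
c(model_reliability(m), model_alpha(m))  # 0.8  0
```

A thin command-line wrapper over these functions ships at
`inst/cli/cttselect.R` (verbs `describe`, `select`, `compare`,
`count-subsets`, `paradox`, `simulate`, `experiment`).

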