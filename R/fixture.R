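#' Bundled example: ten depression-questionnaire items and a diagnosis
#'
#' The published Pearson correlation matrix of ten four-point Likert items
#' drawn from a depression questionnaire, together with each item's
#' correlation with a binary depression diagnosis from a gold-standard
#' diagnostic interview (n = 242 patients). Only the correlations were
#' published -- raw item standard deviations were not -- so the structure
#' is returned in standardized mode (unit SDs), which is the only mode in
#' which its statistics are exactly reproducible. Inter-item correlations
#' range from .10 to .57, item--criterion correlations from .13 to .35.
#'
#' Two published reference values accompany the matrix as attributes:
#' `full_scale`, the alpha (0.93) and predictive validity (0.40) of the
#' full-length 20-item questionnaire these ten items were drawn from, and
#' `published_item_total`, the corrected item-total correlations as
#' printed. The printed item-total column was computed from the raw data
#' with the unpublished SDs, so unit-SD recomputation via
#' [corrected_item_total()] agrees only approximately (e.g. item 9: 0.287
#' recomputed vs .28 printed).
#'
#' @return A [corr_structure()] with labels `"1"`-`"10"`, unit SDs,
#'   criterion correlations and `n_obs = 242`.
#' @examples
#' fix <- depression_items()
#' cronbach_alpha(fix, c(2, 3, 5, 8, 10))   # 0.80 (2 dp)
#' predictive_validity(fix, c(2, 3, 5, 8, 10))  # 0.33 (2 dp)
#' @export
depression_items <- function() {
  lower <- list(
    `2`  = c(0.32),
    `3`  = c(0.27, 0.50),
    `4`  = c(0.41, 0.31, 0.31),
    `5`  = c(0.27, 0.32, 0.38, 0.34),
    `6`  = c(0.15, 0.42, 0.36, 0.15, 0.30),
    `7`  = c(0.22, 0.38, 0.27, 0.29, 0.31, 0.28),
    `8`  = c(0.36, 0.42, 0.44, 0.42, 0.49, 0.28, 0.44),
    `9`  = c(0.19, 0.19, 0.18, 0.10, 0.20, 0.10, 0.14, 0.33),
    `10` = c(0.42, 0.46, 0.44, 0.57, 0.41, 0.27, 0.35, 0.55, 0.26))
  R <- diag(10)
  for (i in 2:10) R[i, seq_len(i - 1)] <- lower[[as.character(i)]]
  R[upper.tri(R)] <- t(R)[upper.tri(R)]
  r_crit <- c(0.22, 0.21, 0.23, 0.28, 0.20, 0.22, 0.26, 0.25, 0.13, 0.35)
  out <- corr_structure(R, labels = as.character(1:10),
                        r_crit = r_crit, n_obs = 242L)
  attr(out, "full_scale") <- c(alpha = 0.93, validity = 0.40)
  attr(out, "published_item_total") <-
    stats::setNames(c(0.45, 0.59, 0.56, 0.51, 0.53, 0.40, 0.47, 0.67,
                      0.28, 0.68), as.character(1:10))
  out
}
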