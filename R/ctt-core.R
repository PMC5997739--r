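#' Coefficient alpha of a sum score
#'
#' Cronbach's coefficient alpha for the sum score over a set of items,
#' computed in closed form from the item correlation matrix and standard
#' deviations:
#' \deqn{\alpha = \frac{n}{n-1}\left(1 -
#'   \frac{\sum_i \sigma_i^2}{\sum_i \sum_j \sigma_i \sigma_j \rho_{ij}}\right)}
#' With unit SDs (the default of [corr_structure()]) this is the
#' standardized alpha \eqn{n\bar r / (1 + (n-1)\bar r)}. Alpha is a lower
#' bound to the sum-score reliability when item errors are uncorrelated; it
#' may be negative, and never exceeds 1 for a positive-semidefinite input.
#'
#' @param structure a [corr_structure()].
#' @param items item labels forming the scale (default: all items); at
#'   least 2.
#' @return Coefficient alpha (dimensionless scalar).
#' @seealso [alpha_if_deleted()], [predictive_validity()]
#' @examples
#' fix <- depression_items()
#' cronbach_alpha(fix, c(2, 3, 5, 8, 10))
#' @export
cronbach_alpha <- function(structure, items = NULL) {
  items <- resolve_items(structure, items)
  n <- length(items)
  if (n < 2L)
    stop("alpha requires at least 2 items", call. = FALSE)
  S <- implied_cov(structure, items)
  total <- sum(S)
  if (total < .Machine$double.eps)
    stop("sum-score variance is zero; degenerate input", call. = FALSE)
  n / (n - 1) * (1 - sum(diag(S)) / total)
}

#' Corrected item-total correlation
#'
#' Correlation of each item score with the sum score of the *remaining*
#' items of the scale (the item-rest correlation), computed in closed form
#' from the correlation structure. This is the statistic questionnaire
#' constructors scan to find items that "measure the same thing": items
#' with high item-rest correlations drive alpha up.
#'
#' @inheritParams cronbach_alpha
#' @param item item label(s) to evaluate; default: every item of the scale.
#' @return Named vector of item-rest correlations.
#' @examples
#' corrected_item_total(depression_items())
#' @export
corrected_item_total <- function(structure, item = NULL, items = NULL) {
  items <- resolve_items(structure, items)
  if (length(items) < 2L)
    stop("item-rest correlation requires at least 2 items", call. = FALSE)
  item <- if (is.null(item)) items else as.character(item)
  bad <- setdiff(item, items)
  if (length(bad))
    stop("item(s) not in the scale: ", paste(bad, collapse = ", "),
         call. = FALSE)
  S <- implied_cov(structure, items)
  out <- vapply(item, function(i) {
    rest <- setdiff(items, i)
    cov_ir <- sum(S[i, rest])
    v_rest <- sum(S[rest, rest])
    v_i <- S[i, i]
    if (v_rest < .Machine$double.eps)
      stop("rest-score variance is zero; degenerate input", call. = FALSE)
    cov_ir / sqrt(v_i * v_rest)
  }, numeric(1))
  names(out) <- item
  out
}

#' Alpha if item deleted
#'
#' Coefficient alpha of the scale after removing one item: the step
#' statistic of measurement-oriented backward selection. Exactly equal to
#' `cronbach_alpha(structure, setdiff(items, item))`.
#'
#' @inheritParams corrected_item_total
#' @return Named vector of alpha-if-deleted values.
#' @seealso [backward_select()]
#' @export
alpha_if_deleted <- function(structure, item = NULL, items = NULL) {
  items <- resolve_items(structure, items)
  if (length(items) < 3L)
    stop("alpha-if-deleted requires at least 3 items (deletion must leave 2)",
         call. = FALSE)
  item <- if (is.null(item)) items else as.character(item)
  bad <- setdiff(item, items)
  if (length(bad))
    stop("item(s) not in the scale: ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- vapply(item, function(i)
    cronbach_alpha(structure, setdiff(items, i)), numeric(1))
  names(out) <- item
  out
}

#' Predictive validity of a sum score
#'
#' Correlation between the scale's sum score and an external criterion,
#' computed in closed form from item--criterion correlations:
#' \deqn{\rho_{XY} = \frac{\sum_i \sigma_i \rho_{iY}}
#'   {\sqrt{\sum_i \sum_j \sigma_i \sigma_j \rho_{ij}}}}
#' Validity rises with the item--criterion correlations (numerator) and
#' falls as inter-item correlations rise (denominator) -- the opposite of
#' what maximizing alpha rewards.
#'
#' @inheritParams cronbach_alpha
#' @param items item labels forming the scale (default: all); at least 1.
#' @return Sum-score--criterion correlation.
#' @examples
#' fix <- depression_items()
#' predictive_validity(fix, c(2, 3, 5, 8, 10))
#' @export
predictive_validity <- function(structure, items = NULL) {
  if (is.null(structure$r_crit))
    stop("structure carries no item-criterion correlations ('r_crit')",
         call. = FALSE)
  items <- resolve_items(structure, items)
  if (length(items) < 1L)
    stop("validity requires at least 1 item", call. = FALSE)
  S <- implied_cov(structure, items)
  total <- sum(S)
  if (total < .Machine$double.eps)
    stop("sum-score variance is zero; degenerate input", call. = FALSE)
  sum(structure$sd[items] * structure$r_crit[items]) / sqrt(total)
}

#' Predictive validity if item deleted
#'
#' Sum-score--criterion correlation of the scale after removing one item:
#' the step statistic of prediction-oriented backward selection. Exactly
#' equal to `predictive_validity(structure, setdiff(items, item))`.
#'
#' @inheritParams corrected_item_total
#' @return Named vector of validity-if-deleted values.
#' @seealso [backward_select()]
#' @export
validity_if_deleted <- function(structure, item = NULL, items = NULL) {
  items <- resolve_items(structure, items)
  if (length(items) < 2L)
    stop("validity-if-deleted requires at least 2 items", call. = FALSE)
  item <- if (is.null(item)) items else as.character(item)
  bad <- setdiff(item, items)
  if (length(bad))
    stop("item(s) not in the scale: ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- vapply(item, function(i)
    predictive_validity(structure, setdiff(items, i)), numeric(1))
  names(out) <- item
  out
}

#' Spearman-Brown prophecy formula
#'
#' Predicted reliability after multiplying a test's length by
#' `length_factor`, assuming the added (or removed) parts are parallel:
#' \eqn{k\rho / (1 + (k-1)\rho)}. Strictly increasing in `k` for
#' \eqn{\rho \in (0,1)}: halving a test lowers its reliability, doubling
#' raises it.
#'
#' @param reliability reliability of the current test, in `[0, 1)`.
#' @param length_factor positive ratio of new length to current length.
#' @return Predicted reliability.
#' @examples
#' spearman_brown(0.5, 2)  # 2/3
#' @export
spearman_brown <- function(reliability, length_factor) {
  assert_scalar(reliability, "reliability")
  assert_scalar(length_factor, "length_factor")
  if (reliability < 0 || reliability >= 1)
    stop("'reliability' must lie in [0, 1)", call. = FALSE)
  if (length_factor <= 0)
    stop("'length_factor' must be positive", call. = FALSE)
  length_factor * reliability / (1 + (length_factor - 1) * reliability)
}

#' Check the validity upper bound
#'
#' The predictive validity of a sum score can never exceed the square root
#' of the sum-score reliability (the validity--reliability inequality).
#' This reports whether \eqn{|\rho_{XY}| \le \sqrt{\rho_{XX'}}} holds and
#' the slack. A "violation" computed with an *alpha estimate* in place of
#' the reliability is not a contradiction: it signals that alpha is
#' underestimating the true reliability (which happens precisely when
#' inter-item correlations are low).
#'
#' @param validity sum-score--criterion correlation.
#' @param reliability reliability (or an alpha estimate of it) in `[0, 1]`.
#' @return Object of class `validity_bound`: list with `validity`,
#'   `reliability`, `bound` (`sqrt(reliability)`), `slack`
#'   (`bound - |validity|`), `satisfied`, and `note` (non-`NA` when
#'   violated).
#' @examples
#' check_validity_bound(0.40, 0.63)
#' @export
check_validity_bound <- function(validity, reliability) {
  assert_scalar(validity, "validity")
  assert_scalar(reliability, "reliability")
  if (reliability < 0 || reliability > 1)
    stop("'reliability' must lie in [0, 1]", call. = FALSE)
  bound <- sqrt(reliability)
  slack <- bound - abs(validity)
  satisfied <- slack >= 0
  structure(list(
    validity = validity, reliability = reliability, bound = bound,
    slack = slack, satisfied = satisfied,
    note = if (!satisfied)
      paste("validity exceeds sqrt(reliability): if 'reliability' is a",
            "coefficient-alpha estimate, alpha is underestimating the true",
            "reliability (expected when inter-item correlations are low)")
    else NA_character_), class = "validity_bound")
}

#' @export
print.validity_bound <- function(x, ...) {
  cat(sprintf("validity %.3f vs bound sqrt(%.3f) = %.3f: %s (slack %.3f)\n",
              x$validity, x$reliability, x$bound,
              if (x$satisfied) "satisfied" else "VIOLATED", x$slack))
  if (!is.na(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Percent reduction of a statistic against a reference
#'
#' Reporting convenience for shortened scales: by how many percent a
#' statistic (alpha, validity) of the short scale falls below the full
#' scale's value, `100 * (1 - value / reference)`.
#'
#' @param value statistic of the shortened scale.
#' @param reference statistic of the reference (full) scale; nonzero.
#' @return List with `percent` (unrounded) and `rounded` (nearest integer
#'   percent, the conventional reporting format).
#' @examples
#' percent_reduction(0.63, 0.93)$rounded  # 32
#' @export
percent_reduction <- function(value, reference) {
  assert_scalar(value, "value")
  assert_scalar(reference, "reference")
  if (reference == 0)
    stop("'reference' must be nonzero", call. = FALSE)
  pct <- 100 * (1 - value / reference)
  list(percent = pct, rounded = round(pct))
}

#' Evaluate a scale: alpha and predictive validity of an item subset
#'
#' @inheritParams cronbach_alpha
#' @return Object of class `scale_evaluation`: list with `items`,
#'   `n_items`, `alpha` and `validity` (`NA` when the structure carries no
#'   criterion correlations).
#' @examples
#' evaluate_scale(depression_items(), c(4, 6, 7, 9, 10))
#' @export
evaluate_scale <- function(structure, items = NULL) {
  items <- resolve_items(structure, items)
  structure(list(
    items = items,
    n_items = length(items),
    alpha = if (length(items) >= 2L) cronbach_alpha(structure, items)
            else NA_real_,
    validity = if (!is.null(structure$r_crit))
      predictive_validity(structure, items) else NA_real_),
    class = "scale_evaluation")
}

#' @export
print.scale_evaluation <- function(x, digits = 2, ...) {
  cat(sprintf("Scale {%s}: alpha = %s, validity = %s\n",
              paste(x$items, collapse = ","),
              formatC(x$alpha, digits = digits, format = "f"),
              if (is.na(x$validity)) "NA"
              else formatC(x$validity, digits = digits, format = "f")))
  invisible(x)
}
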