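#' Correlation structure of a questionnaire item pool
#'
#' Bundles the item-by-item Pearson correlation matrix of a pool of
#' questionnaire items with, optionally, per-item standard deviations,
#' item--criterion correlations (point-biserial when the criterion is a
#' binary diagnosis), and the sample size the correlations were estimated
#' from. All classical-test-theory statistics in this package operate on
#' this object, so analyses can start from either raw respondent data (see
#' [estimate_structure()]) or a published correlation table.
#'
#' When `sd` is omitted every item standard deviation is taken to be 1
#' ("standardized mode"): coefficient alpha then equals the standardized
#' alpha computed from the correlation matrix alone, which is the only mode
#' available when a published table reports correlations but not SDs.
#'
#' The matrix must be square and symmetric (tolerance 1e-12) with a diagonal
#' of exactly 1. A matrix that is not positive semidefinite (smallest
#' eigenvalue below -1e-8) triggers a warning rather than an error, because
#' published matrices rounded to two decimals are routinely slightly
#' indefinite; statistics are computed as written.
#'
#' @param R square symmetric correlation matrix, unit diagonal.
#' @param labels item identifiers, one per row of `R`; defaults to the
#'   rownames of `R` or `"1"`, `"2"`, ... Items are addressed by these labels
#'   everywhere in the package.
#' @param sd optional positive per-item standard deviations (score units).
#' @param r_crit optional per-item item--criterion correlations in `[-1, 1]`.
#' @param n_obs optional sample size (metadata only; not used in formulas).
#' @return An object of class `corr_structure`: a list with elements
#'   `labels`, `R`, `sd`, `r_crit`, `n_obs` and `min_eigenvalue`.
#' @seealso [cronbach_alpha()], [predictive_validity()], [depression_items()]
#' @examples
#' R <- matrix(c(1, .5, .5, .5, 1, .5, .5, .5, 1), 3, 3)
#' s <- corr_structure(R)
#' cronbach_alpha(s)
#' @export
corr_structure <- function(R, labels = NULL, sd = NULL, r_crit = NULL,
                           n_obs = NULL) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R))
    stop("'R' must be a square matrix", call. = FALSE)
  p <- nrow(R)
  if (p < 1L) stop("'R' must have at least one item", call. = FALSE)
  labels <- as.character(labels %||% rownames(R) %||% seq_len(p))
  if (length(labels) != p)
    stop("length of 'labels' must match dim(R)", call. = FALSE)
  if (anyDuplicated(labels))
    stop("item labels must be unique", call. = FALSE)
  if (anyNA(R) || any(!is.finite(R)))
    stop("'R' contains missing or non-finite entries; complete structures are required",
         call. = FALSE)
  if (max(abs(R - t(R))) > 1e-12)
    stop("'R' is not symmetric within tolerance 1e-12", call. = FALSE)
  R <- (R + t(R)) / 2
  if (any(diag(R) != 1))
    stop("diagonal of 'R' must be exactly 1", call. = FALSE)
  off <- R[upper.tri(R)]
  if (length(off) && (any(off < -1) || any(off > 1)))
    stop("off-diagonal correlations must lie in [-1, 1]", call. = FALSE)
  if (is.null(sd)) sd <- rep(1, p)
  sd <- as.numeric(sd)
  if (length(sd) != p)
    stop("length of 'sd' must match the number of items", call. = FALSE)
  if (anyNA(sd) || any(sd <= 0))
    stop("all item standard deviations must be positive", call. = FALSE)
  if (!is.null(r_crit)) {
    r_crit <- as.numeric(r_crit)
    if (length(r_crit) != p)
      stop("length of 'r_crit' must match the number of items", call. = FALSE)
    if (anyNA(r_crit) || any(abs(r_crit) > 1))
      stop("item-criterion correlations must lie in [-1, 1]", call. = FALSE)
    names(r_crit) <- labels
  }
  dimnames(R) <- list(labels, labels)
  names(sd) <- labels
  ev_min <- if (p > 1L)
    min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) else 1
  if (ev_min < -1e-8)
    warning(sprintf(paste0(
      "correlation matrix is not positive semidefinite ",
      "(smallest eigenvalue %.3g); statistics are computed as written"),
      ev_min), call. = FALSE)
  structure(
    list(labels = labels, R = R, sd = sd, r_crit = r_crit,
         n_obs = n_obs, min_eigenvalue = ev_min),
    class = "corr_structure")
}

#' @export
print.corr_structure <- function(x, digits = 2, ...) {
  p <- length(x$labels)
  cat(sprintf("Correlation structure: %d items%s\n", p,
              if (!is.null(x$n_obs)) sprintf(" (n = %d)", x$n_obs) else ""))
  if (p > 1L) {
    off <- x$R[upper.tri(x$R)]
    cat(sprintf("  inter-item correlations in [%.2f, %.2f]\n",
                min(off), max(off)))
  }
  if (!all(x$sd == 1))
    cat("  item SDs supplied (covariance mode)\n")
  else
    cat("  unit item SDs (standardized mode)\n")
  if (!is.null(x$r_crit))
    cat(sprintf("  criterion correlations in [%.2f, %.2f]\n",
                min(x$r_crit), max(x$r_crit)))
  if (x$min_eigenvalue < -1e-8)
    cat(sprintf("  WARNING: not positive semidefinite (min eigenvalue %.3g)\n",
                x$min_eigenvalue))
  invisible(x)
}

# Resolve a user-supplied item set against the structure's labels.
resolve_items <- function(x, items) {
  if (!inherits(x, "corr_structure"))
    stop("'structure' must be a corr_structure object", call. = FALSE)
  if (is.null(items)) return(x$labels)
  items <- as.character(items)
  unknown <- setdiff(items, x$labels)
  if (length(unknown))
    stop("unknown item label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(items))
    stop("duplicate item labels in subset", call. = FALSE)
  items
}

# Model-implied covariance matrix over a subset: diag(sd) %*% R %*% diag(sd).
implied_cov <- function(x, items) {
  s <- x$sd[items]
  x$R[items, items, drop = FALSE] * outer(s, s)
}

#' Restrict a correlation structure to a subset of items
#'
#' @param x a [corr_structure()].
#' @param items item labels to keep (order preserved).
#' @return A `corr_structure` over the selected items.
#' @export
subset_structure <- function(x, items) {
  items <- resolve_items(x, items)
  corr_structure(x$R[items, items, drop = FALSE], labels = items,
                 sd = x$sd[items],
                 r_crit = if (!is.null(x$r_crit)) x$r_crit[items],
                 n_obs = x$n_obs)
}
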