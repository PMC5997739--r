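#' Population true-score model
#'
#' A classical-test-theory population model in which each observed item
#' score decomposes as true score plus error, X = T + E: specified by the
#' covariance matrix of the item true scores, per-item error variances
#' (errors mutually uncorrelated and uncorrelated with true scores, by
#' construction), and optionally a criterion defined as a weighted sum of
#' the item true scores plus independent noise. At this population level
#' both the true reliability and coefficient alpha are exactly computable,
#' which makes the reliability-versus-alpha paradox demonstrable rather
#' than merely arguable.
#'
#' @param Sigma_T symmetric positive-semidefinite true-score covariance
#'   matrix (score units squared).
#' @param error_var nonnegative per-item error variances.
#' @param crit_weights optional weights defining the criterion
#'   Y = w'T + noise; default equal weights when a criterion quantity is
#'   requested.
#' @param crit_noise_var variance of the independent criterion noise
#'   (default 0: the criterion is exactly the weighted true score).
#' @return Object of class `true_score_model`.
#' @seealso [model_reliability()], [model_alpha()], [build_orthogonal_model()]
#' @export
true_score_model <- function(Sigma_T, error_var, crit_weights = NULL,
                             crit_noise_var = 0) {
  Sigma_T <- as.matrix(Sigma_T)
  p <- nrow(Sigma_T)
  if (ncol(Sigma_T) != p)
    stop("'Sigma_T' must be square", call. = FALSE)
  if (max(abs(Sigma_T - t(Sigma_T))) > 1e-10)
    stop("'Sigma_T' must be symmetric", call. = FALSE)
  Sigma_T <- (Sigma_T + t(Sigma_T)) / 2
  ev <- eigen(Sigma_T, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("'Sigma_T' must be positive semidefinite", call. = FALSE)
  error_var <- as.numeric(error_var)
  if (length(error_var) == 1L) error_var <- rep(error_var, p)
  if (length(error_var) != p)
    stop("length of 'error_var' must match dim(Sigma_T)", call. = FALSE)
  if (anyNA(error_var) || any(error_var < 0))
    stop("'error_var' must be nonnegative", call. = FALSE)
  if (!is.null(crit_weights)) {
    crit_weights <- as.numeric(crit_weights)
    if (length(crit_weights) != p)
      stop("length of 'crit_weights' must match dim(Sigma_T)", call. = FALSE)
  }
  assert_scalar(crit_noise_var, "crit_noise_var")
  if (crit_noise_var < 0)
    stop("'crit_noise_var' must be nonnegative", call. = FALSE)
  structure(list(Sigma_T = Sigma_T, error_var = error_var,
                 crit_weights = crit_weights,
                 crit_noise_var = crit_noise_var, n_items = p),
            class = "true_score_model")
}

#' @export
print.true_score_model <- function(x, ...) {
  cat(sprintf("True-score model: %d items\n", x$n_items))
  cat(sprintf("  reliability = %.4f, alpha = %.4f\n",
              model_reliability(x), model_alpha(x)))
  if (!is.null(x$crit_weights))
    cat(sprintf("  criterion validity = %.4f (noise var %.3g)\n",
                model_validity(x), x$crit_noise_var))
  invisible(x)
}

# Model-implied observed-score covariance: Sigma_T + diag(error_var).
implied_obs_cov <- function(model) {
  model$Sigma_T + diag(model$error_var, model$n_items)
}

#' Population sum-score reliability of a true-score model
#'
#' The squared correlation between the sum score and its true score,
#' equal to true-score variance over total sum-score variance:
#' \eqn{\rho^2_{XT} = \sigma^2_T / \sigma^2_X}. Always in `[0, 1]`.
#'
#' @param model a [true_score_model()].
#' @return Reliability coefficient.
#' @export
model_reliability <- function(model) {
  stopifnot(inherits(model, "true_score_model"))
  var_T <- sum(model$Sigma_T)
  var_X <- var_T + sum(model$error_var)
  if (var_X < .Machine$double.eps)
    stop("degenerate model: zero sum-score variance", call. = FALSE)
  var_T / var_X
}

#' Coefficient alpha of a true-score model
#'
#' Alpha evaluated on the model-implied observed item covariance matrix.
#' For parallel items alpha equals the reliability; otherwise (with
#' uncorrelated errors) alpha is strictly a lower bound, and the gap grows
#' as the inter-item covariances shrink -- down to alpha = 0 for mutually
#' uncorrelated but individually reliable items.
#'
#' @inheritParams model_reliability
#' @return Coefficient alpha (may be negative).
#' @export
model_alpha <- function(model) {
  stopifnot(inherits(model, "true_score_model"))
  if (model$n_items < 2L)
    stop("alpha requires at least 2 items", call. = FALSE)
  S <- implied_obs_cov(model)
  total <- sum(S)
  if (total < .Machine$double.eps)
    stop("degenerate model: zero sum-score variance", call. = FALSE)
  n <- model$n_items
  n / (n - 1) * (1 - sum(diag(S)) / total)
}

#' Population criterion validity of a true-score model
#'
#' Correlation between the sum score X and the criterion Y = w'T + noise.
#' Because Y depends on the items only through their true scores, this
#' validity can never exceed the square root of the model reliability.
#'
#' @inheritParams model_reliability
#' @param weights criterion weights; default: the model's `crit_weights`,
#'   or equal weights if none were set.
#' @param noise_var criterion noise variance; default: the model's.
#' @return Sum-score--criterion correlation.
#' @export
model_validity <- function(model, weights = NULL, noise_var = NULL) {
  stopifnot(inherits(model, "true_score_model"))
  w <- weights %||% model$crit_weights %||% rep(1, model$n_items)
  nv <- noise_var %||% model$crit_noise_var
  var_X <- sum(implied_obs_cov(model))
  var_Y <- as.numeric(t(w) %*% model$Sigma_T %*% w) + nv
  if (var_X < .Machine$double.eps || var_Y < .Machine$double.eps)
    stop("degenerate model: zero variance", call. = FALSE)
  cov_XY <- sum(model$Sigma_T %*% w)
  cov_XY / sqrt(var_X * var_Y)
}

#' Orthogonal true-score model: high reliability, zero alpha
#'
#' Builds the extremal model behind the paradox: `n` unit-variance items
#' whose true scores are mutually uncorrelated (each item measures its own
#' trait) but individually reliable, with `Sigma_T = diag(item_reliability)`
#' and `error_var = 1 - item_reliability`. The sum score's true reliability
#' equals `item_reliability`, yet coefficient alpha is exactly zero: with
#' no inter-item covariance, internal consistency sees nothing, even
#' though the measurement itself is precise. With reliability 0.8 one
#' obtains alpha 0 -- the sharpest possible illustration that alpha is a
#' lower bound, not the reliability.
#'
#' @param n number of items (at least 2).
#' @param item_reliability per-item reliability in `(0, 1)`.
#' @return A [true_score_model()] with equal criterion weights and zero
#'   criterion noise (so its criterion is the sum true score, attaining
#'   the validity bound exactly).
#' @examples
#' m <- build_orthogonal_model(5, 0.8)
#' model_reliability(m)  # 0.8
#' model_alpha(m)        # 0
#' @export
build_orthogonal_model <- function(n, item_reliability) {
  assert_scalar(n, "n")
  if (n < 2 || n != trunc(n))
    stop("'n' must be an integer >= 2", call. = FALSE)
  assert_scalar(item_reliability, "item_reliability")
  if (item_reliability <= 0 || item_reliability >= 1)
    stop("'item_reliability' must lie in (0, 1)", call. = FALSE)
  true_score_model(Sigma_T = diag(item_reliability, n),
                   error_var = rep(1 - item_reliability, n),
                   crit_weights = rep(1, n), crit_noise_var = 0)
}

#' Gap between true reliability and alpha across inter-trait correlation
#'
#' Evaluates a family of unit-variance item models interpolating between
#' the orthogonal construction (inter-trait correlation 0) and parallel
#' items (inter-trait correlation 1): true-score covariance
#' `Sigma_T = c * ((1 - r) I + r J)` with `c = item_reliability`, error
#' variance `1 - c` per item. Returns alpha, true reliability, and their
#' gap at each grid point. The gap shrinks monotonically from
#' `item_reliability` (orthogonal: alpha 0) to 0 (parallel: alpha equals
#' reliability), quantifying how badly alpha underestimates reliability as
#' inter-item correlations fall.
#'
#' @param n number of items.
#' @param item_reliability per-item reliability in `(0, 1)`.
#' @param grid inter-trait correlations in `[0, 1]`.
#' @return Data frame (class `alpha_gap_curve`) with columns
#'   `inter_trait_corr`, `inter_item_corr` (implied observed-score
#'   correlation), `alpha`, `reliability`, `gap`.
#' @examples
#' alpha_gap_curve(5, 0.8, grid = c(0, 0.5, 1))
#' @export
alpha_gap_curve <- function(n, item_reliability,
                            grid = seq(0, 1, by = 0.1)) {
  assert_scalar(n, "n")
  if (n < 2 || n != trunc(n))
    stop("'n' must be an integer >= 2", call. = FALSE)
  assert_scalar(item_reliability, "item_reliability")
  if (item_reliability <= 0 || item_reliability >= 1)
    stop("'item_reliability' must lie in (0, 1)", call. = FALSE)
  grid <- as.numeric(grid)
  if (!length(grid) || anyNA(grid) || any(grid < 0 | grid > 1))
    stop("'grid' values must lie in [0, 1]", call. = FALSE)
  rows <- lapply(grid, function(r) {
    c_ <- item_reliability
    Sigma_T <- c_ * ((1 - r) * diag(n) + r * matrix(1, n, n))
    m <- true_score_model(Sigma_T, rep(1 - c_, n))
    a <- model_alpha(m)
    rel <- model_reliability(m)
    data.frame(inter_trait_corr = r, inter_item_corr = c_ * r,
               alpha = a, reliability = rel, gap = rel - a)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("alpha_gap_curve", "data.frame")
  out
}

#' @export
plot.alpha_gap_curve <- function(x, ...) {
  graphics::matplot(x$inter_trait_corr, cbind(x$reliability, x$alpha),
                    type = "b", pch = c(19, 1), lty = 1,
                    col = c("black", "grey40"),
                    xlab = "inter-trait correlation",
                    ylab = "coefficient", ...)
  graphics::legend("bottomright", legend = c("true reliability", "alpha"),
                   pch = c(19, 1), col = c("black", "grey40"), bty = "n")
  invisible(x)
}
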