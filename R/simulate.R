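#' Simulation design: Likert items, latent factors, binary criterion
#'
#' Specifies the generating model of the synthetic-data module: correlated
#' standard-normal latent factors, continuous item responses built as
#' loading-weighted factors plus unique noise (unit total variance),
#' discretized into ordered Likert categories by per-item thresholds, and a
#' binary gold-standard criterion obtained by thresholding a liability
#' (weighted factors plus independent noise) at its population prevalence
#' quantile. This emulates the structure of a depression-screening study --
#' four-point Likert symptom items, a diagnostic interview as criterion --
#' without claiming to reproduce any particular raw data set.
#'
#' @param loadings item-by-factor loading matrix; each item's communality
#'   (loading' factor_corr loading) must not exceed 1.
#' @param factor_corr factor correlation matrix (default: identity).
#' @param thresholds ordered cut points on the latent item response, either
#'   a single vector recycled to all items or a list per item; default
#'   `qnorm(c(.25, .5, .75))`, i.e. equal-probability four-point categories
#'   scored 0-3.
#' @param crit_weights factor weights of the criterion liability.
#' @param crit_noise_var variance of the liability's independent noise.
#' @param prevalence population proportion of positives, in (0, 1).
#' @param n number of respondents (at least 2).
#' @return Object of class `simulation_design`.
#' @seealso [simulate_sample()], [default_design()], [implied_structure()]
#' @export
simulation_design <- function(loadings, factor_corr = NULL,
                              thresholds = stats::qnorm(c(.25, .5, .75)),
                              crit_weights = NULL, crit_noise_var = 1,
                              prevalence = 0.25, n = 242) {
  loadings <- as.matrix(loadings)
  p <- nrow(loadings)
  q <- ncol(loadings)
  if (p < 1L || q < 1L) stop("'loadings' must be a nonempty matrix", call. = FALSE)
  if (is.null(factor_corr)) factor_corr <- diag(q)
  factor_corr <- as.matrix(factor_corr)
  problems <- character()
  if (nrow(factor_corr) != q || ncol(factor_corr) != q)
    problems <- c(problems, "factor_corr dimensions do not match loadings")
  else {
    if (max(abs(factor_corr - t(factor_corr))) > 1e-12 ||
        any(diag(factor_corr) != 1))
      problems <- c(problems,
                    "factor_corr must be symmetric with unit diagonal")
    else if (min(eigen(factor_corr, symmetric = TRUE,
                       only.values = TRUE)$values) < -1e-8)
      problems <- c(problems, "factor_corr must be positive semidefinite")
  }
  if (!is.list(thresholds)) thresholds <- rep(list(as.numeric(thresholds)), p)
  if (length(thresholds) != p)
    problems <- c(problems, "thresholds must have one cut vector per item")
  else for (i in seq_len(p)) {
    th <- thresholds[[i]]
    if (!length(th) || anyNA(th) || is.unsorted(th, strictly = TRUE))
      problems <- c(problems,
                    sprintf("thresholds for item %d must be strictly increasing", i))
  }
  if (is.null(crit_weights)) crit_weights <- rep(1, q)
  crit_weights <- as.numeric(crit_weights)
  if (length(crit_weights) != q)
    problems <- c(problems, "crit_weights must have one weight per factor")
  if (!is.numeric(crit_noise_var) || length(crit_noise_var) != 1L ||
      is.na(crit_noise_var) || crit_noise_var < 0)
    problems <- c(problems, "crit_noise_var must be a nonnegative scalar")
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      is.na(prevalence) || prevalence <= 0 || prevalence >= 1)
    problems <- c(problems, "prevalence must lie strictly in (0, 1)")
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2 || n != trunc(n))
    problems <- c(problems, "n must be an integer >= 2")
  if (!length(problems) && nrow(factor_corr) == q) {
    comm <- vapply(seq_len(p), function(i)
      as.numeric(t(loadings[i, ]) %*% factor_corr %*% loadings[i, ]),
      numeric(1))
    over <- which(comm > 1 + 1e-12)
    if (length(over))
      problems <- c(problems, sprintf(
        "communality exceeds 1 for item(s): %s",
        paste(over, collapse = ", ")))
  }
  if (length(problems))
    stop("invalid simulation design:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(list(loadings = loadings, factor_corr = factor_corr,
                 thresholds = thresholds, crit_weights = crit_weights,
                 crit_noise_var = crit_noise_var, prevalence = prevalence,
                 n = as.integer(n), n_items = p, n_factors = q),
            class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf(paste0(
    "Simulation design: %d Likert items (0-%d), %d factor%s, n = %d\n",
    "  criterion prevalence %.2f, liability noise var %.2f\n"),
    x$n_items, length(x$thresholds[[1]]), x$n_factors,
    if (x$n_factors == 1) "" else "s", x$n, x$prevalence, x$crit_noise_var))
  invisible(x)
}

#' Default emulation design
#'
#' The package's reference design: 10 four-point Likert items loading on
#' two correlated factors (r = 0.4), loadings spanning 0.5-0.8 split five
#' items per factor, a binary criterion with equal factor weights, unit
#' liability noise and prevalence 0.25, and n = 242 respondents. This
#' mirrors the mixed (not strictly unidimensional) structure of the
#' bundled depression-item example at the same sample size; it is an
#' emulation, not a replication of any raw data.
#'
#' @param n number of respondents (default 242).
#' @return A [simulation_design()].
#' @export
default_design <- function(n = 242) {
  lam <- seq(0.5, 0.8, length.out = 5)
  loadings <- matrix(0, 10, 2)
  loadings[1:5, 1] <- lam
  loadings[6:10, 2] <- lam
  simulation_design(
    loadings = loadings,
    factor_corr = matrix(c(1, .4, .4, 1), 2, 2),
    crit_weights = c(1, 1),
    crit_noise_var = 1,
    prevalence = 0.25,
    n = n)
}

#' Draw a synthetic respondent sample
#'
#' Simulates item scores and the binary criterion from a
#' [simulation_design()]: factors are drawn multivariate normal, the
#' continuous item responses are formed as loadings times factors plus
#' unique noise scaled to unit total variance, then cut at the thresholds
#' into integer categories; the criterion indicates a liability above its
#' population prevalence quantile. With a given `seed` the output is
#' identical on every call, and the global RNG state is left untouched.
#'
#' @param design a [simulation_design()].
#' @param seed integer seed; `NULL` uses (and advances) the global RNG.
#' @param keep_latent also return the continuous pre-discretization item
#'   responses as attribute `latent`.
#' @return Object of class `item_response_data`: list with `scores`
#'   (n-by-items integer matrix, columns labelled "1", "2", ...) and
#'   `criterion` (0/1 vector).
#' @examples
#' d <- default_design()
#' x <- simulate_sample(d, seed = 1)
#' table(x$criterion)
#' @export
simulate_sample <- function(design, seed = NULL, keep_latent = FALSE) {
  stopifnot(inherits(design, "simulation_design"))
  with_seed(seed, {
    n <- design$n
    p <- design$n_items
    q <- design$n_factors
    Fm <- matrix(stats::rnorm(n * q), n, q) %*% chol(design$factor_corr)
    comm <- vapply(seq_len(p), function(i)
      as.numeric(t(design$loadings[i, ]) %*% design$factor_corr %*%
                   design$loadings[i, ]), numeric(1))
    uniq <- sqrt(pmax(0, 1 - comm))
    latent <- Fm %*% t(design$loadings) +
      matrix(stats::rnorm(n * p), n, p) * rep(uniq, each = n)
    scores <- matrix(0L, n, p)
    for (i in seq_len(p))
      scores[, i] <- findInterval(latent[, i], design$thresholds[[i]])
    colnames(scores) <- as.character(seq_len(p))
    w <- design$crit_weights
    sd_L <- sqrt(as.numeric(t(w) %*% design$factor_corr %*% w) +
                   design$crit_noise_var)
    liab <- as.vector(Fm %*% w) +
      stats::rnorm(n, sd = sqrt(design$crit_noise_var))
    cut <- stats::qnorm(1 - design$prevalence, sd = sd_L)
    out <- structure(list(scores = scores,
                          criterion = as.integer(liab > cut)),
                     class = "item_response_data")
    if (keep_latent) attr(out, "latent") <- latent
    out
  })
}

#' @rdname simulate_sample
#' @param object a [simulation_design()] (for the [stats::simulate()]
#'   generic).
#' @param nsim number of samples to draw.
#' @param ... unused.
#' @return For `simulate()`: a list of `nsim` `item_response_data` objects.
#' @export
simulate.simulation_design <- function(object, nsim = 1, seed = NULL, ...) {
  seeds <- if (is.null(seed)) vector("list", nsim)
           else as.list(seed + seq_len(nsim))
  lapply(seeds, function(s) simulate_sample(object, seed = s))
}

#' @export
print.item_response_data <- function(x, ...) {
  cat(sprintf("Item responses: %d respondents x %d items, %d positives (%.1f%%)\n",
              nrow(x$scores), ncol(x$scores), sum(x$criterion),
              100 * mean(x$criterion)))
  invisible(x)
}

#' Estimate a correlation structure from respondent data
#'
#' Computes the Pearson item-by-item correlation matrix, per-item standard
#' deviations, and Pearson item--criterion correlations (point-biserial,
#' the criterion being binary) from raw scores -- the empirical substrate
#' every published correlation table is built from.
#'
#' @param data an `item_response_data` object (or any list with a numeric
#'   `scores` matrix and optional `criterion` vector).
#' @return A [corr_structure()] with `sd`, `r_crit` (when a criterion is
#'   present) and `n_obs` filled in.
#' @export
estimate_structure <- function(data) {
  scores <- as.matrix(data$scores)
  if (nrow(scores) < 3L)
    stop("at least 3 respondents are required", call. = FALSE)
  sds <- apply(scores, 2, stats::sd)
  labels <- colnames(scores) %||% as.character(seq_len(ncol(scores)))
  if (any(sds == 0))
    stop("constant item column(s): ",
         paste(labels[sds == 0], collapse = ", "), call. = FALSE)
  R <- stats::cor(scores)
  r_crit <- NULL
  if (!is.null(data$criterion)) {
    if (stats::sd(data$criterion) == 0)
      stop("criterion is constant; point-biserial correlations undefined",
           call. = FALSE)
    r_crit <- as.vector(stats::cor(scores, data$criterion))
  }
  corr_structure(R, labels = labels, sd = sds, r_crit = r_crit,
                 n_obs = nrow(scores))
}

# Univariate category probabilities and moments for one item's thresholds
# under a standard-normal latent response.
likert_moments <- function(th) {
  cuts <- c(-Inf, th, Inf)
  pr <- diff(stats::pnorm(cuts))
  cats <- seq_along(pr) - 1
  m <- sum(cats * pr)
  v <- sum(cats^2 * pr) - m^2
  list(pr = pr, cats = cats, mean = m, var = v, cuts = cuts)
}

#' Design-implied population correlation structure
#'
#' The exact population Pearson correlation structure of the *discretized*
#' scores generated by a [simulation_design()]: category cross-probabilities
#' come from bivariate-normal rectangle probabilities at the latent
#' inter-item correlations, and the item--criterion correlations from the
#' joint distribution of each latent item response with the dichotomized
#' liability. Discretization attenuates all correlations relative to their
#' latent counterparts, so this -- not the loading products -- is the
#' correct recovery target for sample statistics.
#'
#' @param design a [simulation_design()].
#' @return A [corr_structure()] with population SDs and criterion
#'   correlations (and `n_obs = NULL`).
#' @export
implied_structure <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  p <- design$n_items
  Phi <- design$factor_corr
  L <- design$loadings
  lat_R <- L %*% Phi %*% t(L)  # latent item correlations (unit variances)
  mom <- lapply(design$thresholds, likert_moments)
  R <- diag(p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    mi <- mom[[i]]; mj <- mom[[j]]
    rho <- min(1, max(-1, lat_R[i, j]))
    e_xy <- 0
    for (a in seq_along(mi$cats)) for (b in seq_along(mj$cats)) {
      ca <- mi$cats[a]; cb <- mj$cats[b]
      if (ca == 0 || cb == 0) next
      rect <- pbinorm(mi$cuts[a + 1], mj$cuts[b + 1], rho) -
        pbinorm(mi$cuts[a], mj$cuts[b + 1], rho) -
        pbinorm(mi$cuts[a + 1], mj$cuts[b], rho) +
        pbinorm(mi$cuts[a], mj$cuts[b], rho)
      e_xy <- e_xy + ca * cb * rect
    }
    R[i, j] <- R[j, i] <-
      (e_xy - mi$mean * mj$mean) / sqrt(mi$var * mj$var)
  }
  w <- design$crit_weights
  sd_L <- sqrt(as.numeric(t(w) %*% Phi %*% w) + design$crit_noise_var)
  rho_iL <- as.vector(L %*% Phi %*% w) / sd_L
  t_std <- stats::qnorm(1 - design$prevalence)
  prev <- design$prevalence
  r_crit <- vapply(seq_len(p), function(i) {
    mi <- mom[[i]]
    rho <- min(1, max(-1, rho_iL[i]))
    # E[score_i * 1(positive)] = sum_a a * P(score = a, liability > cut)
    e_xy <- 0
    for (a in seq_along(mi$cats)) {
      ca <- mi$cats[a]
      if (ca == 0) next
      p_cat <- mi$pr[a]
      p_both_neg <- pbinorm(mi$cuts[a + 1], t_std, rho) -
        pbinorm(mi$cuts[a], t_std, rho)
      e_xy <- e_xy + ca * (p_cat - p_both_neg)
    }
    (e_xy - mi$mean * prev) / sqrt(mi$var * prev * (1 - prev))
  }, numeric(1))
  corr_structure(R, labels = as.character(seq_len(p)),
                 sd = sqrt(vapply(mom, `[[`, numeric(1), "var")),
                 r_crit = r_crit)
}

#' Replicated measurement-versus-prediction trade-off experiment
#'
#' Repeatedly simulates a respondent sample from a design, estimates its
#' correlation structure, and runs [compare_goals()] at scale length `k`,
#' summarizing alpha and validity per objective arm across replications
#' together with the mean overlap of the two selected item sets. This is
#' the package's in-silico version of the scale-construction comparison:
#' under designs with a multi-factor criterion the measurement arm attains
#' the higher mean alpha and the prediction arm the higher mean validity.
#'
#' @param design a [simulation_design()].
#' @param k target scale length.
#' @param reps number of replications (at least 1).
#' @param seed integer seed; replication r uses `seed + r`.
#' @param method search method passed to [compare_goals()].
#' @return Object of class `tradeoff_experiment`: list with `k`, `reps`,
#'   `per_rep` (data frame of per-replication statistics) and `summary`
#'   (means and SDs per arm, mean overlap).
#' @examples
#' tradeoff_experiment(default_design(), k = 5, reps = 3, seed = 1)
#' @export
tradeoff_experiment <- function(design, k, reps, seed = NULL,
                                method = c("backward", "exhaustive")) {
  stopifnot(inherits(design, "simulation_design"))
  method <- match.arg(method)
  assert_scalar(reps, "reps")
  if (reps < 1 || reps != trunc(reps))
    stop("'reps' must be an integer >= 1", call. = FALSE)
  rows <- lapply(seq_len(reps), function(r) {
    s <- if (is.null(seed)) NULL else seed + r
    dat <- simulate_sample(design, seed = s)
    est <- estimate_structure(dat)
    cg <- compare_goals(est, k = k, method = method)
    data.frame(
      rep = r,
      alpha_measurement = cg$measurement$evaluation$alpha,
      validity_measurement = cg$measurement$evaluation$validity,
      alpha_prediction = cg$prediction$evaluation$alpha,
      validity_prediction = cg$prediction$evaluation$validity,
      overlap = length(cg$overlap))
  })
  per_rep <- do.call(rbind, rows)
  summ <- list(
    mean_alpha = c(measurement = mean(per_rep$alpha_measurement),
                   prediction = mean(per_rep$alpha_prediction)),
    sd_alpha = c(measurement = stats::sd(per_rep$alpha_measurement),
                 prediction = stats::sd(per_rep$alpha_prediction)),
    mean_validity = c(measurement = mean(per_rep$validity_measurement),
                      prediction = mean(per_rep$validity_prediction)),
    sd_validity = c(measurement = stats::sd(per_rep$validity_measurement),
                    prediction = stats::sd(per_rep$validity_prediction)),
    mean_overlap = mean(per_rep$overlap))
  structure(list(k = k, reps = reps, method = method,
                 per_rep = per_rep, summary = summ),
            class = "tradeoff_experiment")
}

#' @export
print.tradeoff_experiment <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Trade-off experiment: %d reps, k = %d (%s search)\n",
              x$reps, x$k, x$method))
  cat(sprintf("  mean alpha:    measurement %.3f, prediction %.3f\n",
              s$mean_alpha["measurement"], s$mean_alpha["prediction"]))
  cat(sprintf("  mean validity: measurement %.3f, prediction %.3f\n",
              s$mean_validity["measurement"], s$mean_validity["prediction"]))
  cat(sprintf("  mean overlap of selected sets: %.2f items\n",
              s$mean_overlap))
  invisible(x)
}
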