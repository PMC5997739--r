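# Order labels numerically when they all look numeric, else lexically.
# Used for deterministic tie-breaking ("remove the smallest label").
label_order <- function(labels) {
  num <- suppressWarnings(as.numeric(labels))
  if (!anyNA(num)) order(num) else order(labels)
}

objective_fun <- function(structure, objective) {
  switch(objective,
    measurement = function(items) cronbach_alpha(structure, items),
    prediction = {
      if (is.null(structure$r_crit))
        stop("prediction objective requires item-criterion correlations ('r_crit')",
             call. = FALSE)
      function(items) predictive_validity(structure, items)
    },
    stop("unknown objective", call. = FALSE))
}

#' Number of candidate item subsets
#'
#' The number of nonempty subsets of an `n`-item pool, \eqn{2^n - 1}: the
#' search space a test constructor faces when choosing final items from
#' pretest items. Grows so fast that full enumeration is feasible only for
#' small pools (1023 subsets at n = 10, over a trillion at n = 40), which
#' motivates stepwise selection.
#'
#' @param n pool size (integer, at least 1).
#' @return The count as a double (exact up to n = 53), with attribute
#'   `exact` carrying the exact decimal representation for any `n`.
#' @examples
#' count_subsets(10)  # 1023
#' @export
count_subsets <- function(n) {
  assert_scalar(n, "n")
  if (n < 1 || n != trunc(n))
    stop("'n' must be an integer >= 1", call. = FALSE)
  # exact 2^n as little-endian decimal digits, by repeated doubling
  d <- 1L
  for (i in seq_len(n)) {
    d <- d * 2L
    carry <- 0L
    for (j in seq_along(d)) {
      t <- d[j] + carry
      d[j] <- t %% 10L
      carry <- t %/% 10L
    }
    while (carry > 0L) {
      d <- c(d, carry %% 10L)
      carry <- carry %/% 10L
    }
  }
  d[1L] <- d[1L] - 1L  # 2^n ends in 2,4,6,8 so no borrow
  structure(2^n - 1, exact = paste(rev(d), collapse = ""))
}

#' Stepwise backward item selection
#'
#' Constructs a scale from a pretest pool by repeatedly deleting items.
#' Under the measurement objective the item whose deletion yields the
#' highest alpha-if-deleted is removed at each step; under the prediction
#' objective, the item whose deletion yields the highest
#' validity-if-deleted. Selection stops when the scale has shrunk to the
#' target size `k`, or earlier under `threshold` as soon as the current
#' objective value is at least the threshold ("the minimal value deemed
#' sufficient"). If both are given, `k` takes precedence. A threshold that
#' is never reached terminates at the minimum scale size of 2 with
#' `threshold_unreached = TRUE` recorded in the trace.
#'
#' Ties within 1e-12 are broken by removing the smallest item label, so
#' runs are deterministic. Steps where the best and second-best deletion
#' differ by less than 0.01 are flagged `near_tie`, since with correlations
#' published to two decimals such steps are rounding-sensitive: set
#' membership may flip while the headline statistics barely move.
#'
#' @param structure a [corr_structure()]; the prediction objective requires
#'   `r_crit`.
#' @param objective `"measurement"` (maximize alpha) or `"prediction"`
#'   (maximize sum-score--criterion validity).
#' @param k target number of final items, between 2 and the pool size.
#' @param threshold objective value deemed sufficient; stop as soon as the
#'   current scale attains it.
#' @param items starting pool (default: all items of the structure).
#' @return Object of class `selection_trace`: list with `objective`,
#'   `stop_rule`, `steps` (data frame: `step`, `removed`, `value` of the
#'   surviving scale, `near_tie`), `initial_items`, `final_items`,
#'   `final_evaluation` (a [evaluate_scale()] result),
#'   `threshold_unreached`, and the `structure` (so traces are replayable).
#' @examples
#' tr <- backward_select(depression_items(), "measurement", k = 5)
#' tr$steps
#' @export
backward_select <- function(structure,
                            objective = c("measurement", "prediction"),
                            k = NULL, threshold = NULL, items = NULL) {
  objective <- match.arg(objective)
  pool <- resolve_items(structure, items)
  if (length(pool) < 2L)
    stop("the pool must contain at least 2 items", call. = FALSE)
  if (is.null(k) && is.null(threshold))
    stop("supply a stop rule: target size 'k' or objective 'threshold'",
         call. = FALSE)
  if (!is.null(k)) {
    assert_scalar(k, "k")
    if (k < 2 || k > length(pool) || k != trunc(k))
      stop(sprintf("'k' must be an integer in [2, %d]", length(pool)),
           call. = FALSE)
  }
  if (!is.null(threshold)) assert_scalar(threshold, "threshold")
  f <- objective_fun(structure, objective)

  current <- pool
  steps <- list()
  unreached <- FALSE
  repeat {
    if (!is.null(k)) {
      if (length(current) <= k) break
    } else {
      if (f(current) >= threshold) break
      if (length(current) <= 2L) { unreached <- TRUE; break }
    }
    cand <- vapply(current, function(i) f(setdiff(current, i)), numeric(1))
    best <- max(cand)
    top <- current[cand >= best - 1e-12]
    remove <- top[label_order(top)[1L]]
    near <- length(current) > 1L &&
      sum(cand >= best - 0.01) > 1L
    current <- setdiff(current, remove)
    steps[[length(steps) + 1L]] <-
      data.frame(removed = remove, value = f(current), near_tie = near,
                 stringsAsFactors = FALSE)
  }
  steps <- if (length(steps))
    cbind(step = seq_along(steps), do.call(rbind, steps))
  else
    data.frame(step = integer(), removed = character(), value = numeric(),
               near_tie = logical(), stringsAsFactors = FALSE)
  rownames(steps) <- NULL
  structure(list(
    objective = objective,
    stop_rule = list(k = k, threshold = threshold),
    steps = steps,
    initial_items = pool,
    final_items = current,
    final_evaluation = evaluate_scale(structure, current),
    threshold_unreached = unreached,
    structure = structure), class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("Backward selection (%s objective): %d -> %d items\n",
              x$objective, length(x$initial_items), length(x$final_items)))
  if (nrow(x$steps)) {
    for (i in seq_len(nrow(x$steps)))
      cat(sprintf("  step %d: removed item %s, objective = %.3f%s\n",
                  x$steps$step[i], x$steps$removed[i], x$steps$value[i],
                  if (x$steps$near_tie[i]) "  [near-tie: rounding-sensitive]"
                  else ""))
  } else cat("  (no removals)\n")
  cat("  final: ")
  print(x$final_evaluation)
  if (x$threshold_unreached)
    cat("  NOTE: threshold never reached; stopped at minimum size 2\n")
  invisible(x)
}

#' @export
summary.selection_trace <- function(object, ...) {
  c(objective = object$objective,
    n_initial = length(object$initial_items),
    n_final = length(object$final_items),
    alpha = object$final_evaluation$alpha,
    validity = object$final_evaluation$validity)
}

#' @export
plot.selection_trace <- function(x, ...) {
  if (!nrow(x$steps)) {
    graphics::plot.new()
    graphics::title("No removal steps")
    return(invisible(x))
  }
  ylab <- if (x$objective == "measurement") "coefficient alpha"
          else "predictive validity"
  graphics::plot(x$steps$step, x$steps$value, type = "b", pch = 19,
                 xlab = "removal step", ylab = ylab, ...)
  graphics::text(x$steps$step, x$steps$value, labels = x$steps$removed,
                 pos = 3, cex = 0.8)
  invisible(x)
}

#' Exhaustive best subset of a given size
#'
#' Enumerates all size-`k` subsets of the pool and returns the one
#' maximizing the objective. Feasible only for small pools; enumeration is
#' refused when `choose(pool, k)` exceeds `cap`, reporting the total
#' subset count from [count_subsets()]. Ties are broken toward the
#' lexicographically smallest label set (enumeration order).
#'
#' @inheritParams backward_select
#' @param k subset size.
#' @param cap maximum number of subsets to enumerate (default 1e6).
#' @return Object of class `best_subset`: list with `items`, `value`,
#'   `objective`, `evaluation` and `n_evaluated`.
#' @examples
#' exhaustive_best_subset(depression_items(), "prediction", k = 5)
#' @export
exhaustive_best_subset <- function(structure,
                                   objective = c("measurement", "prediction"),
                                   k, cap = 1e6, items = NULL) {
  objective <- match.arg(objective)
  pool <- resolve_items(structure, items)
  assert_scalar(k, "k")
  if (k < 1 || k > length(pool) || k != trunc(k))
    stop(sprintf("'k' must be an integer in [1, %d]", length(pool)),
         call. = FALSE)
  if (objective == "measurement" && k < 2)
    stop("the measurement objective (alpha) requires k >= 2", call. = FALSE)
  n_comb <- choose(length(pool), k)
  if (n_comb > cap)
    stop(sprintf(paste0(
      "enumeration refused: choose(%d, %d) = %s subsets exceeds the cap ",
      "of %s (the pool has %s nonempty subsets in total)"),
      length(pool), k, format(n_comb, big.mark = ","),
      format(cap, big.mark = ","),
      attr(count_subsets(length(pool)), "exact")), call. = FALSE)
  # order the pool by label so ties resolve to the smallest label set
  pool <- pool[label_order(pool)]
  f <- objective_fun(structure, objective)
  best_val <- -Inf
  best_set <- NULL
  sets <- utils::combn(pool, k, simplify = FALSE)
  for (s in sets) {
    v <- f(s)
    if (v > best_val + 1e-12) {
      best_val <- v
      best_set <- s
    }
  }
  structure(list(items = best_set, value = best_val, objective = objective,
                 evaluation = evaluate_scale(structure, best_set),
                 n_evaluated = length(sets)), class = "best_subset")
}

#' @export
print.best_subset <- function(x, ...) {
  cat(sprintf("Exhaustive best %d-item subset (%s objective, %d evaluated):\n",
              length(x$items), x$objective, x$n_evaluated))
  cat("  ")
  print(x$evaluation)
  invisible(x)
}

#' Compare measurement-based and prediction-based scale construction
#'
#' Runs item selection at the same target size `k` under both objectives
#' and evaluates each resulting scale on *both* metrics (alpha and
#' validity), so the trade-off is visible: the measurement-based scale
#' attains the higher alpha, the prediction-based scale the higher
#' validity, and the two sets may share few items. Optionally reports
#' percent reductions against a reference (e.g. full-length) scale.
#'
#' @inheritParams backward_select
#' @param k target number of final items for both arms.
#' @param reference optional list with `alpha` and/or `validity` of a
#'   reference scale; percent reductions of each arm are reported
#'   against it.
#' @param method `"backward"` (stepwise, the field's standard procedure)
#'   or `"exhaustive"` (full enumeration, small pools only).
#' @return Object of class `goal_comparison`: list with `k`, `method`,
#'   `measurement` and `prediction` (each a [evaluate_scale()] result with
#'   the trace or search attached), `overlap` (common items), and
#'   `reductions` when a reference was supplied.
#' @examples
#' compare_goals(depression_items(), k = 5,
#'               reference = list(alpha = 0.93, validity = 0.40))
#' @export
compare_goals <- function(structure, k, reference = NULL,
                          method = c("backward", "exhaustive"),
                          items = NULL) {
  method <- match.arg(method)
  arms <- lapply(c(measurement = "measurement", prediction = "prediction"),
    function(obj) {
      if (method == "backward") {
        tr <- backward_select(structure, obj, k = k, items = items)
        list(search = tr, evaluation = tr$final_evaluation)
      } else {
        bs <- exhaustive_best_subset(structure, obj, k = k, items = items)
        list(search = bs, evaluation = bs$evaluation)
      }
    })
  overlap <- intersect(arms$measurement$evaluation$items,
                       arms$prediction$evaluation$items)
  reductions <- NULL
  if (!is.null(reference)) {
    reductions <- list()
    for (arm in names(arms)) {
      ev <- arms[[arm]]$evaluation
      reductions[[arm]] <- list(
        alpha = if (!is.null(reference$alpha))
          percent_reduction(ev$alpha, reference$alpha),
        validity = if (!is.null(reference$validity) && !is.na(ev$validity))
          percent_reduction(ev$validity, reference$validity))
    }
  }
  structure(list(k = k, method = method,
                 measurement = arms$measurement,
                 prediction = arms$prediction,
                 overlap = overlap, reference = reference,
                 reductions = reductions), class = "goal_comparison")
}

#' @export
print.goal_comparison <- function(x, ...) {
  cat(sprintf("Goal comparison at k = %d (%s search)\n", x$k, x$method))
  for (arm in c("measurement", "prediction")) {
    cat(sprintf("  %-11s ", paste0(arm, ":")))
    print(x[[arm]]$evaluation)
  }
  cat(sprintf("  overlap: %s (%d item%s)\n",
              if (length(x$overlap)) paste(x$overlap, collapse = ",") else "-",
              length(x$overlap), if (length(x$overlap) == 1) "" else "s"))
  if (!is.null(x$reductions)) {
    for (arm in names(x$reductions)) {
      r <- x$reductions[[arm]]
      cat(sprintf("  %s vs reference:%s%s\n", arm,
        if (!is.null(r$alpha))
          sprintf(" alpha -%d%%", r$alpha$rounded) else "",
        if (!is.null(r$validity))
          sprintf(" validity -%d%%", r$validity$rounded) else ""))
    }
  }
  invisible(x)
}
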