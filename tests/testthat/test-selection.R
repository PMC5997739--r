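fix <- depression_items()

test_that("subset counts are exact, including beyond pocket-calculator range", {
  expect_equal(as.numeric(count_subsets(10)), 1023)
  expect_identical(attr(count_subsets(10), "exact"), "1023")
  expect_equal(as.numeric(count_subsets(20)), 1048575)
  expect_identical(attr(count_subsets(20), "exact"), "1048575")
  expect_gt(as.numeric(count_subsets(40)), 1e12)
  expect_identical(attr(count_subsets(40), "exact"), "1099511627775")
  expect_equal(as.numeric(count_subsets(1)), 1)
  # exact decimal string survives past double precision
  expect_identical(nchar(attr(count_subsets(100), "exact")), 31L)
  expect_identical(attr(count_subsets(100), "exact"),
                   "1267650600228229401496703205375")
  expect_error(count_subsets(0), ">= 1")
  expect_error(count_subsets(2.5), ">= 1")
})

test_that("backward selection stops, records steps, and starts correctly", {
  # stop at k = pool size: no removals
  tr <- backward_select(fix, "measurement", k = 10)
  expect_identical(nrow(tr$steps), 0L)
  expect_setequal(tr$final_items, fixture_labels)

  # first removal under each objective matches exhaustive per-step oracle
  trm <- backward_select(fix, "measurement", k = 5)
  oracle_first <- fixture_labels[which.max(vapply(fixture_labels, function(i)
    oracle_alpha(fix$R, fix$sd, setdiff(fixture_labels, i)), numeric(1)))]
  expect_identical(trm$steps$removed[1], oracle_first)
  expect_identical(trm$steps$removed[1], "9")

  trp <- backward_select(fix, "prediction", k = 5)
  oracle_first_p <- fixture_labels[which.max(vapply(fixture_labels, function(i)
    oracle_validity(fix$R, fix$sd, fix$r_crit, setdiff(fixture_labels, i)),
    numeric(1)))]
  expect_identical(trp$steps$removed[1], oracle_first_p)
  expect_identical(trp$steps$removed[1], "2")

  expect_error(backward_select(fix, "measurement"), "stop rule")
  expect_error(backward_select(fix, "measurement", k = 1), "\\[2, 10\\]")
  s <- corr_structure(diag(3))
  expect_error(backward_select(s, "prediction", k = 2), "r_crit")
})

test_that("selection traces are replayable and structurally nested", {
  for (obj in c("measurement", "prediction")) {
    tr <- backward_select(fix, obj, k = 3)
    expect_identical(nrow(tr$steps), 7L)
    expect_identical(length(tr$final_items),
                     length(tr$initial_items) - nrow(tr$steps))
    current <- tr$initial_items
    for (i in seq_len(nrow(tr$steps))) {
      rm_i <- tr$steps$removed[i]
      expect_true(rm_i %in% current)          # present before its step
      current <- setdiff(current, rm_i)       # absent after
      replayed <- if (obj == "measurement") cronbach_alpha(fix, current)
                  else predictive_validity(fix, current)
      expect_identical(tr$steps$value[i], replayed)
    }
    expect_setequal(current, tr$final_items)
    # each recorded value is the per-step maximum over alternative deletions
    current <- tr$initial_items
    f <- function(set) if (obj == "measurement")
      oracle_alpha(fix$R, fix$sd, set)
    else oracle_validity(fix$R, fix$sd, fix$r_crit, set)
    for (i in seq_len(nrow(tr$steps))) {
      alts <- vapply(current, function(j) f(setdiff(current, j)), numeric(1))
      expect_gte(tr$steps$value[i] + 1e-12, max(alts))
      current <- setdiff(current, tr$steps$removed[i])
    }
  }
})

test_that("threshold stop rule triggers early or flags unreachability", {
  # immediately satisfied: full pool alpha already above a low threshold
  tr0 <- backward_select(fix, "measurement", threshold = 0.5)
  expect_identical(nrow(tr0$steps), 0L)
  expect_false(tr0$threshold_unreached)
  # reachable: removing weak items raises alpha past the full-pool value
  full <- cronbach_alpha(fix)
  tr1 <- backward_select(fix, "measurement", threshold = full + 0.005)
  expect_gt(nrow(tr1$steps), 0L)
  expect_gte(tr1$final_evaluation$alpha, full + 0.005)
  expect_false(tr1$threshold_unreached)
  # unreachable: terminates at minimum size 2 with the flag set
  tr2 <- backward_select(fix, "measurement", threshold = 0.999)
  expect_identical(length(tr2$final_items), 2L)
  expect_true(tr2$threshold_unreached)
  # k takes precedence over threshold when both are given
  tr3 <- backward_select(fix, "measurement", k = 6, threshold = 0.5)
  expect_identical(length(tr3$final_items), 6L)
})

test_that("ties are broken deterministically toward the smallest label", {
  # four exchangeable items: every deletion is equivalent at every step
  s <- corr_structure(matrix(.3, 4, 4) + diag(.7, 4))
  tr <- backward_select(s, "measurement", k = 2)
  expect_identical(tr$steps$removed, c("1", "2"))
  tr_rep <- backward_select(s, "measurement", k = 2)
  expect_identical(tr$steps, tr_rep$steps)
})

test_that("near-ties within 0.01 are flagged as rounding-sensitive", {
  s <- corr_structure(matrix(.3, 3, 3) + diag(.7, 3))
  tr <- backward_select(s, "measurement", k = 2)
  expect_true(all(tr$steps$near_tie))
  # well-separated case: no flags
  R <- diag(3); R[1, 2] <- R[2, 1] <- .6; R[1, 3] <- R[3, 1] <- .1
  s2 <- corr_structure(R)
  tr2 <- backward_select(s2, "measurement", k = 2)
  expect_false(any(tr2$steps$near_tie))
})

test_that("exhaustive search agrees with hand enumeration and dominates greedy", {
  # 4-item toy pool: all six 2-subsets enumerated by hand with the oracle
  set.seed(61)
  s4 <- random_structure(4, with_crit = TRUE)
  pairs <- utils::combn(s4$labels, 2, simplify = FALSE)
  for (obj in c("measurement", "prediction")) {
    f <- function(set) if (obj == "measurement")
      oracle_alpha(s4$R, s4$sd, set)
    else oracle_validity(s4$R, s4$sd, s4$r_crit, set)
    hand_vals <- vapply(pairs, f, numeric(1))
    hand_best <- pairs[[which.max(hand_vals)]]
    bs <- exhaustive_best_subset(s4, obj, k = 2)
    expect_setequal(bs$items, hand_best)
    expect_equal(bs$value, max(hand_vals), tolerance = 1e-12)
    expect_identical(bs$n_evaluated, 6L)
  }

  # k = pool size returns the pool itself
  bs_full <- exhaustive_best_subset(fix, "measurement", k = 10)
  expect_setequal(bs_full$items, fixture_labels)

  # greedy never beats enumeration, and matches it for one-step selection
  for (obj in c("measurement", "prediction")) {
    for (k in c(3, 5, 7, 9)) {
      g <- backward_select(fix, obj, k = k)
      e <- exhaustive_best_subset(fix, obj, k = k)
      gv <- if (obj == "measurement") g$final_evaluation$alpha
            else g$final_evaluation$validity
      expect_lte(gv, e$value + 1e-12)
      if (k == 9) expect_setequal(g$final_items, e$items)
    }
  }
})

test_that("enumeration above the cap is refused with the subset count", {
  expect_error(exhaustive_best_subset(fix, "measurement", k = 5, cap = 100),
               "enumeration refused")
  expect_error(exhaustive_best_subset(fix, "measurement", k = 5, cap = 100),
               "1023")
})

test_that("validity-optimal subsets dominate alpha-optimal subsets in validity", {
  for (k in 2:9) {
    em <- exhaustive_best_subset(fix, "measurement", k = k)
    ep <- exhaustive_best_subset(fix, "prediction", k = k)
    expect_gte(ep$value + 1e-12,
               predictive_validity(fix, em$items))
    expect_gte(em$value + 1e-12, cronbach_alpha(fix, ep$items))
  }
})

test_that("goal comparison shows the measurement-prediction trade-off", {
  cg <- compare_goals(fix, k = 5,
                      reference = list(alpha = 0.93, validity = 0.40))
  expect_gt(cg$measurement$evaluation$alpha, cg$prediction$evaluation$alpha)
  expect_gte(cg$prediction$evaluation$validity + 1e-12,
             cg$measurement$evaluation$validity)
  expect_true(all(cg$overlap %in% fixture_labels))
  # alpha drops more for the prediction-based scale, validity more for the
  # measurement-based scale
  expect_gt(cg$reductions$prediction$alpha$percent,
            cg$reductions$measurement$alpha$percent)
  expect_gt(cg$reductions$measurement$validity$percent,
            cg$reductions$prediction$validity$percent)
  # k = pool size: both arms identical with full overlap
  cg_full <- compare_goals(fix, k = 10)
  expect_setequal(cg_full$measurement$evaluation$items,
                  cg_full$prediction$evaluation$items)
  expect_identical(length(cg_full$overlap), 10L)
})
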