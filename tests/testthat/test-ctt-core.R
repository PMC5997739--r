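fix <- depression_items()

test_that("coefficient alpha matches closed forms and the printed scales", {
  # two uncorrelated items share no variance
  s0 <- corr_structure(diag(2))
  expect_equal(cronbach_alpha(s0), 0)
  # three items, all pairwise r = .5: standardized alpha 3r/(1+2r)
  s3 <- corr_structure(matrix(c(1, .5, .5, .5, 1, .5, .5, .5, 1), 3, 3))
  expect_equal(cronbach_alpha(s3), 3 * .5 / (1 + 2 * .5))
  expect_equal(cronbach_alpha(s3), oracle_alpha(s3$R, s3$sd, c("1", "2", "3")),
               tolerance = 1e-14)
  # the two five-item scales of the worked example, unit SDs
  expect_identical(round(cronbach_alpha(fix, meas_set), 2), 0.80)
  expect_identical(round(cronbach_alpha(fix, pred_set), 2), 0.63)
  # alpha may be negative and is not floored
  sneg <- corr_structure(matrix(c(1, -.5, -.5, 1), 2, 2))
  expect_lt(cronbach_alpha(sneg), 0)
})

test_that("alpha input errors: subset size, unknown label, zero variance", {
  expect_error(cronbach_alpha(fix, "1"), "at least 2")
  expect_error(cronbach_alpha(fix, c("1", "11")), "unknown")
  sdeg <- suppressWarnings(corr_structure(matrix(c(1, -1, -1, 1), 2, 2)))
  expect_error(cronbach_alpha(sdeg), "degenerate")
})

test_that("alpha and validity agree with the brute-force oracle on the fixture", {
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(2:10, 1)
    idx <- sample(fixture_labels, k)
    expect_equal(cronbach_alpha(fix, idx),
                 oracle_alpha(fix$R, fix$sd, idx), tolerance = 1e-12)
    expect_equal(predictive_validity(fix, idx),
                 oracle_validity(fix$R, fix$sd, fix$r_crit, idx),
                 tolerance = 1e-12)
  }
})

test_that("corrected item-total correlation: closed forms and fixture value", {
  # with two items the rest score is the other item
  s2 <- corr_structure(matrix(c(1, .37, .37, 1), 2, 2))
  expect_equal(unname(corrected_item_total(s2, "1")), .37)
  # item uncorrelated with all others
  R <- diag(4); R[2, 3] <- R[3, 2] <- .5
  s4 <- corr_structure(R)
  expect_equal(unname(corrected_item_total(s4, "1")), 0)
  # fixture item 9, all ten items, unit SDs (recomputed; the printed .28
  # used unpublished raw SDs)
  v <- unname(corrected_item_total(fix, "9"))
  expect_equal(round(v, 3), 0.287)
  expect_equal(v, oracle_item_total(fix$R, fix$sd, "9",
                                    setdiff(fixture_labels, "9")),
               tolerance = 1e-12)
  expect_error(corrected_item_total(fix, "3", items = c("1", "2")),
               "not in the scale")
})

test_that("alpha-if-deleted delegates exactly and finds the weakest item", {
  # three parallel items: deleting any leaves the two-item alpha 2r/(1+r)
  r <- .41
  s3 <- corr_structure(matrix(r, 3, 3) + diag(1 - r, 3))
  expect_equal(unname(alpha_if_deleted(s3)), rep(2 * r / (1 + r), 3))
  # exact delegation identity on random structures
  set.seed(21)
  for (rep in 1:10) {
    s <- random_structure(6)
    for (i in s$labels)
      expect_identical(unname(alpha_if_deleted(s, i)),
                       cronbach_alpha(s, setdiff(s$labels, i)))
  }
  # on the fixture, deleting item 9 maximizes alpha (oracle enumeration)
  oracle_best <- fixture_labels[which.max(vapply(fixture_labels, function(i)
    oracle_alpha(fix$R, fix$sd, setdiff(fixture_labels, i)), numeric(1)))]
  expect_identical(oracle_best, "9")
  expect_identical(names(which.max(alpha_if_deleted(fix))), "9")
  expect_error(alpha_if_deleted(s3, "1", items = c("1", "2")), "at least 3")
})

test_that("predictive validity: collapse, fixture values, missing criterion", {
  # singleton scale: validity is the item-criterion correlation itself
  for (i in c("1", "5", "10"))
    expect_equal(predictive_validity(fix, i), unname(fix$r_crit[i]))
  expect_identical(round(predictive_validity(fix, meas_set), 2), 0.33)
  # unit-SD recomputation of the prediction scale (printed .40 used
  # unpublished raw SDs)
  expect_identical(round(predictive_validity(fix, pred_set), 3), 0.392)
  s <- corr_structure(diag(2))
  expect_error(predictive_validity(s), "r_crit")
})

test_that("validity-if-deleted delegates and ranks deletions correctly", {
  set.seed(31)
  for (rep in 1:10) {
    s <- random_structure(5, with_crit = TRUE)
    for (i in s$labels)
      expect_identical(unname(validity_if_deleted(s, i)),
                       predictive_validity(s, setdiff(s$labels, i)))
  }
  # on the fixture, deleting item 2 maximizes validity (oracle enumeration)
  oracle_best <- fixture_labels[which.max(vapply(fixture_labels, function(i)
    oracle_validity(fix$R, fix$sd, fix$r_crit,
                    setdiff(fixture_labels, i)), numeric(1)))]
  expect_identical(oracle_best, "2")
  expect_identical(names(which.max(validity_if_deleted(fix))), "2")
  # two identical items with equal criterion correlation: deleting either
  # leaves validity at rho_iY
  s2 <- corr_structure(matrix(c(1, 1, 1, 1), 2, 2), r_crit = c(.3, .3))
  expect_equal(unname(validity_if_deleted(s2)), c(.3, .3))
  # dropping the only item correlated with the criterion lowers validity
  R <- diag(3); R[1, 2] <- R[2, 1] <- .2
  s3 <- corr_structure(R, r_crit = c(0, 0, .5))
  expect_lt(unname(validity_if_deleted(s3, "3")),
            predictive_validity(s3))
})

test_that("Spearman-Brown prophecy: identity, doubling, halving, monotone", {
  expect_equal(spearman_brown(.44, 1), .44)
  expect_equal(spearman_brown(.5, 2), 2 / 3)
  # any subtest of a split is less reliable than the full test
  for (rho in c(.2, .5, .9))
    expect_lt(spearman_brown(rho, 0.5), rho)
  ks <- seq(0.25, 4, by = .25)
  vals <- vapply(ks, function(k) spearman_brown(.6, k), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(spearman_brown(1, 2), "\\[0, 1\\)")
  expect_error(spearman_brown(.5, 0), "positive")
})

test_that("validity bound report: satisfied, boundary, violation flag", {
  b <- check_validity_bound(0.40, 0.63)
  expect_true(b$satisfied)
  expect_equal(b$slack, sqrt(0.63) - 0.40)
  expect_equal(b$slack, 0.3937, tolerance = 1e-4)

  b0 <- check_validity_bound(1, 1)
  expect_true(b0$satisfied)
  expect_equal(b0$slack, 0)

  bv <- check_validity_bound(0.9, 0.5)
  expect_false(bv$satisfied)
  expect_match(bv$note, "underestimating")
})

test_that("percent reduction reproduces the reported shortening losses", {
  expect_identical(percent_reduction(0.63, 0.93)$rounded, 32)
  expect_identical(percent_reduction(0.80, 0.93)$rounded, 14)
  expect_identical(percent_reduction(0.33, 0.40)$rounded, 18)
  expect_identical(percent_reduction(0.40, 0.40)$rounded, 0)
  expect_equal(percent_reduction(0.63, 0.93)$percent,
               100 * (1 - 0.63 / 0.93))
  expect_error(percent_reduction(.5, 0), "nonzero")
})

test_that("alpha is at most 1 and validity within [-1, 1] on PSD structures", {
  set.seed(41)
  for (rep in 1:200) {
    p <- sample(2:8, 1)
    s <- random_structure(p, with_crit = TRUE)
    expect_lte(cronbach_alpha(s), 1)
    v <- predictive_validity(s)
    expect_gte(v, -1)
    expect_lte(v, 1)
  }
})

test_that("alpha and validity are invariant under item permutation", {
  set.seed(51)
  s <- random_structure(7, with_crit = TRUE)
  for (rep in 1:10) {
    perm <- sample(s$labels)
    expect_equal(cronbach_alpha(s, perm), cronbach_alpha(s),
                 tolerance = 1e-14)
    expect_equal(predictive_validity(s, perm), predictive_validity(s),
                 tolerance = 1e-14)
  }
})

test_that("scale evaluation bundles items, alpha and validity", {
  ev <- evaluate_scale(fix, pred_set)
  expect_s3_class(ev, "scale_evaluation")
  expect_identical(ev$n_items, 5L)
  expect_identical(ev$alpha, cronbach_alpha(fix, pred_set))
  expect_identical(ev$validity, predictive_validity(fix, pred_set))
  ev1 <- evaluate_scale(corr_structure(diag(2)), "1")
  expect_true(is.na(ev1$alpha))
  expect_true(is.na(ev1$validity))
})
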