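# Independent brute-force oracles: every statistic is recomputed by
# assembling the full covariance matrix entry by entry with explicit loops,
# a separate code path from the package's quadratic-form implementation.

oracle_cov <- function(R, sd, idx) {
  k <- length(idx)
  S <- matrix(0, k, k)
  for (a in seq_len(k)) for (b in seq_len(k))
    S[a, b] <- unname(sd[idx[a]] * sd[idx[b]] * R[idx[a], idx[b]])
  S
}

oracle_alpha <- function(R, sd, idx) {
  S <- oracle_cov(R, sd, idx)
  k <- length(idx)
  diag_sum <- 0
  total <- 0
  for (a in seq_len(k)) for (b in seq_len(k)) {
    total <- total + S[a, b]
    if (a == b) diag_sum <- diag_sum + S[a, b]
  }
  unname(k / (k - 1) * (1 - diag_sum / total))
}

oracle_validity <- function(R, sd, r_crit, idx) {
  S <- oracle_cov(R, sd, idx)
  num <- 0
  for (a in seq_along(idx)) num <- num + sd[idx[a]] * r_crit[idx[a]]
  unname(num / sqrt(sum(S)))
}

oracle_item_total <- function(R, sd, item, rest) {
  cov_ir <- 0
  for (j in rest) cov_ir <- cov_ir + sd[item] * sd[j] * R[item, j]
  v_rest <- 0
  for (a in rest) for (b in rest) v_rest <- v_rest + sd[a] * sd[b] * R[a, b]
  unname(cov_ir / (sd[item] * sqrt(v_rest)))
}

# Random correlation matrix, PSD by construction (Gram matrix of random
# vectors), optionally joint with a criterion variable so that the implied
# item-criterion correlations are jointly consistent.
random_corr <- function(p, df = p + 2) {
  A <- matrix(rnorm(p * df), p, df)
  stats::cov2cor(tcrossprod(A))
}

random_structure <- function(p, with_crit = FALSE, sd = NULL) {
  if (with_crit) {
    full <- random_corr(p + 1)
    corr_structure(full[seq_len(p), seq_len(p)],
                   sd = sd, r_crit = full[seq_len(p), p + 1])
  } else {
    corr_structure(random_corr(p), sd = sd)
  }
}

random_true_score_model <- function(p) {
  A <- matrix(rnorm(p * (p + 2)), p, p + 2)
  Sigma_T <- tcrossprod(A) / (p + 2)
  true_score_model(Sigma_T, error_var = runif(p, 0, 2),
                   crit_weights = rnorm(p), crit_noise_var = runif(1, 0, 2))
}

fixture_labels <- as.character(1:10)
meas_set <- c("2", "3", "5", "8", "10")
pred_set <- c("4", "6", "7", "9", "10")
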