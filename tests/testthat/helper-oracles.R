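# Independent oracles and fixture builders shared across tests. These
# deliberately avoid the code paths they check: sums of squares are
# accumulated with explicit loops, epsilon comes from eigenvalues, the
# t-test from its textbook formula.

# A responder that truthfully aims for a fixed target curve: stops the
# ramp at the first amplitude >= target, clicks straight toward the
# target, is satisfied only when the curve matches it exactly.
fixed_target_responder <- function(target_mA) {
  tgt <- round(target_mA * 10)
  subject_responder(
    stop_ramp = function(pad, amplitude_mA) round(amplitude_mA * 10) >= tgt[pad],
    adjust = function(pad, current_mA) {
      cur <- round(current_mA * 10)
      if (cur > tgt[pad]) "down" else if (cur < tgt[pad]) "up" else "accept"
    },
    satisfied = function(curve) all(round(as.numeric(curve) * 10) == tgt))
}

# A responder that never stops the ramp and never accepts a value.
unresponsive_responder <- function(accept_anyway = TRUE) {
  subject_responder(
    stop_ramp = function(pad, amplitude_mA) FALSE,
    adjust = function(pad, current_mA) "accept",
    satisfied = function(curve) TRUE)
}

# Random grid-valid dataset: n_curves curves over n_pads pads drawn
# uniformly from the device grid.
random_grid_dataset <- function(n_curves, n_pads = 16) {
  curves <- lapply(seq_len(n_curves), function(i) {
    sample(seq(0.1, 5.0, by = 0.1), n_pads, replace = TRUE)
  })
  dataset_from_curves(curves,
                      subject_id = paste0("S", seq_len(n_curves)),
                      session_id = rep("1", n_curves))
}

# Paired t-test from the textbook formula, p via the t distribution.
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), df = n - 1))
}

# One-way within-subject ANOVA by explicit sums-of-squares loops, with
# the Greenhouse-Geisser epsilon from the eigenvalues of the double-
# centered condition covariance.
oracle_rm_anova <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  cond_means <- colMeans(Y)
  unit_means <- rowMeans(Y)
  ss_cond <- 0
  for (j in seq_len(k)) ss_cond <- ss_cond + n * (cond_means[j] - grand)^2
  ss_err <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      ss_err <- ss_err + (Y[i, j] - cond_means[j] - unit_means[i] + grand)^2
    }
  }
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  F_stat <- (ss_cond / df1) / (ss_err / df2)
  S <- cov(Y)
  Cc <- diag(k) - matrix(1 / k, k, k)
  lambda <- eigen(Cc %*% S %*% Cc, symmetric = TRUE, only.values = TRUE)$values
  eps <- sum(lambda)^2 / ((k - 1) * sum(lambda^2))
  list(F = unname(F_stat), epsilon = min(max(eps, 1 / (k - 1)), 1),
       df1 = df1, df2 = df2)
}

# Exhaustive-search oracle for the optimal constant: scans every grid
# amplitude in double precision (no integer-tenths shortcut).
oracle_optimal_constant <- function(values_mA) {
  cand <- seq(0.1, 5.0, by = 0.1)
  tot <- sapply(cand, function(cc) sum(abs(values_mA - cc)))
  idx <- which(tot <= min(tot) + 1e-9)[1]
  list(constant_mA = cand[idx], total_distance_mA = tot[idx])
}

# The set of L1 minimizers over the reals is the median interval
# [lower median, upper median]; for odd counts the two coincide.
median_interval <- function(values_mA) {
  s <- sort(values_mA)
  n <- length(s)
  if (n %% 2 == 1) rep(s[(n + 1) / 2], 2) else c(s[n / 2], s[n / 2 + 1])
}
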