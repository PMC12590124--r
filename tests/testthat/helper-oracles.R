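# Independent brute-force oracles used to freeze expected values.

# exact two-sided rank-sum p by enumeration of all group assignments
# (midranks for ties); symmetric-tail definition on the Mann-Whitney U
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  rk <- rank(pooled)
  u_of <- function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2
  obs <- u_of(seq_len(n1))
  mu <- n1 * length(b) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2L, u_of)
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# literal Benjamini-Hochberg step-up: rejections and adjusted p values
oracle_bh <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  rejected <- rep(FALSE, m)
  if (length(k)) rejected[o[seq_len(max(k))]] <- TRUE
  adj <- rev(cummin(rev(pmin(1, m * ps / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  list(p_adjusted = out, rejected = rejected)
}

# AUC as the Mann-Whitney concordance probability over all (pos, neg) pairs
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  mean(outer(sp, sn, function(x, y) (x > y) + 0.5 * (x == y)))
}

# Pearson chi-squared from the definition sum (O - E)^2 / E
oracle_chi2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# OLS coefficients from the normal equations
oracle_ols <- function(X, y) {
  Xi <- cbind(1, X)
  as.numeric(solve(t(Xi) %*% Xi, t(Xi) %*% y))
}

# quick tfr_map constructor for operation-level tests (all pixels valid)
make_map <- function(values, freqs = seq_len(nrow(values)),
                     times = seq(-200, by = 10, length.out = ncol(values)),
                     ...) {
  visoscil:::new_tfr_map(freqs, times, values,
                         valid = matrix(TRUE, nrow(values), ncol(values)), ...)
}
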