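# Independent oracles used to validate the package's own implementations.
# Each is deliberately naive (enumeration, closed form, brute force) and
# shares no code with the functions it checks.

# Breslow log partial likelihood written out directly (single covariate).
breslow_loglik_1d <- function(beta, time, event, x) {
  sum(vapply(which(event), function(i) {
    risk <- time >= time[i]
    beta * x[i] - log(sum(exp(beta * x[risk])))
  }, numeric(1)))
}

# Maximize the written-out partial likelihood on a dense grid.
cox_grid_oracle <- function(time, event, x, lo = -4, hi = 4, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, breslow_loglik_1d, numeric(1), time = time, event = event, x = x)
  grid[which.max(ll)]
}

# Two-group log-rank chi-square computed independently (same formula family,
# written against the 2xk contingency form at each event time).
logrank_chisq_oracle <- function(time, event, grp) {
  et <- sort(unique(time[event]))
  o <- e <- v <- 0
  for (tt in et) {
    at <- time >= tt
    n <- sum(at); n1 <- sum(at & grp == 1)
    d <- sum(event & time == tt); d1 <- sum(event & time == tt & grp == 1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

# Exhaustive label-permutation p-value for the two-group log-rank statistic.
logrank_perm_oracle <- function(time, event, grp) {
  n <- length(time)
  n1 <- sum(grp == 1)
  obs <- logrank_chisq_oracle(time, event, grp)
  combos <- utils::combn(n, n1)
  stats <- apply(combos, 2, function(idx) {
    g <- rep(0L, n); g[idx] <- 1L
    logrank_chisq_oracle(time, event, g)
  })
  mean(stats >= obs - 1e-12)
}

# P(median of k iid Uniform(0,1) <= x), exact for odd k: the median is <= x
# iff at least (k+1)/2 of the uniforms are.
median_uniform_cdf_odd <- function(x, k) {
  stopifnot(k %% 2 == 1)
  stats::pbinom((k + 1) / 2 - 1, k, x, lower.tail = FALSE)
}

# Textbook TMM: doubly trimmed, precision-weighted mean of M-values against
# an explicit reference column.
tmm_oracle <- function(counts, ref = 1, logratio_trim = 0.3, abs_trim = 0.05) {
  lib <- colSums(counts)
  one <- function(j) {
    ok <- counts[, j] > 0 & counts[, ref] > 0
    pj <- counts[ok, j] / lib[j]
    pr <- counts[ok, ref] / lib[ref]
    M <- log2(pj / pr)
    A <- 0.5 * log2(pj * pr)
    w <- 1 / ((lib[j] - counts[ok, j]) / (lib[j] * counts[ok, j]) +
                (lib[ref] - counts[ok, ref]) / (lib[ref] * counts[ok, ref]))
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), one, numeric(1))
  f / exp(mean(log(f)))
}

# tiny hand-checkable survival fixture: 8 subjects, one binary covariate
small_surv_fixture <- function() {
  tibble::tibble(
    time = c(2, 3, 5, 7, 8, 11, 13, 17),
    event = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
    x = c(1, 1, 1, 0, 1, 0, 0, 0)
  )
}
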