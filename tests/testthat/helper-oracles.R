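# Independent oracles, deliberately brute-force and separate from the
# package's code paths.

# Exact two-sided Mann-Whitney p-value by enumerating every assignment
# of the pooled (mid)ranks to group 1. Conditional on the observed ties.
enum_mw <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  combos <- utils::combn(n, n1)
  u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  list(
    u = u_obs,
    p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  )
}

# Upper-tail hypergeometric p by enumerating every n-subset of an
# M-element universe whose first K elements are annotated.
enum_hyper <- function(k, K, n, M) {
  combos <- utils::combn(M, n)
  hits <- colSums(combos <= K)
  mean(hits >= k)
}

# Kaplan-Meier product-limit estimate computed directly from the
# definition, reported at the distinct event times.
hand_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]
  event <- as.logical(event)[ord]
  ts <- sort(unique(time[event]))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_, at_risk = NA_real_, events = NA_real_)
  for (i in seq_along(ts)) {
    n_i <- sum(time >= ts[i])
    d_i <- sum(time == ts[i] & event)
    s <- s * (1 - d_i / n_i)
    out$surv[i] <- s
    out$at_risk[i] <- n_i
    out$events[i] <- d_i
  }
  out
}

# Two-group log-rank chi-square from the O - E and hypergeometric
# variance sums over distinct event times.
hand_logrank <- function(t1, e1, t2, e2) {
  time <- c(t1, t2)
  event <- as.logical(c(e1, e2))
  grp <- rep(1:2, c(length(t1), length(t2)))
  ts <- sort(unique(time[event]))
  o_minus_e <- 0
  v <- 0
  for (tt in ts) {
    n_i <- sum(time >= tt)
    n1_i <- sum(time >= tt & grp == 1)
    d_i <- sum(time == tt & event)
    d1_i <- sum(time == tt & event & grp == 1)
    e1_i <- d_i * n1_i / n_i
    o_minus_e <- o_minus_e + (d1_i - e1_i)
    if (n_i > 1) {
      v <- v + d_i * (n1_i / n_i) * (1 - n1_i / n_i) * (n_i - d_i) / (n_i - 1)
    }
  }
  chi2 <- o_minus_e^2 / v
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}
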