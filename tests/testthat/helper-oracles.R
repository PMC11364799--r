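# Independent brute-force oracles used to pin down the survival primitives.
# These deliberately re-derive each quantity from first principles and stay
# separate from the package implementation.

# Harrell's C by O(n^2) pair enumeration. A pair is usable when the earlier
# time is an event (ties in time: usable only when exactly one is an event,
# the event counting as earlier). Prediction ties score 1/2.
oracle_concordance <- function(lp, time, event) {
  n <- length(lp)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ti <- time[i]; tj <- time[j]; ei <- event[i]; ej <- event[j]
    if (ti == tj) {
      if (ei + ej != 1) next
      first <- if (ei == 1) i else j
      second <- if (ei == 1) j else i
    } else if (ti < tj) {
      if (ei != 1) next
      first <- i; second <- j
    } else {
      if (ej != 1) next
      first <- j; second <- i
    }
    den <- den + 1
    if (lp[first] > lp[second]) num <- num + 1
    else if (lp[first] == lp[second]) num <- num + 0.5
  }
  num / den
}

# Two-group log-rank statistic from the hypergeometric O-E / V sums.
oracle_logrank2 <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  stopifnot(length(unique(g)) == 2L)
  ts <- sort(unique(time[event == 1]))
  u <- 0; v <- 0
  for (tt in ts) {
    at_risk <- time >= tt
    n_t <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d_t <- sum(event == 1 & time == tt)
    d1 <- sum(event == 1 & time == tt & g == 1)
    u <- u + d1 - n1 * d_t / n_t
    if (n_t > 1)
      v <- v + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
  }
  u^2 / v
}

# Product-limit estimate by explicit risk-set bookkeeping.
oracle_km <- function(time, event, t_eval) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  for (tt in ts[ts <= t_eval]) {
    n_t <- sum(time >= tt)
    d_t <- sum(event == 1 & time == tt)
    s <- s * (1 - d_t / n_t)
  }
  s
}

# Breslow partial log-likelihood for one covariate.
oracle_breslow_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Breslow score function (d loglik / d beta) for one covariate.
oracle_breslow_score <- function(beta, x, time, event) {
  u <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    w <- exp(beta * x[risk])
    u <- u + x[i] - sum(x[risk] * w) / sum(w)
  }
  u
}

# Literal transcription of the truncated-power restricted-cubic-spline
# nonlinear terms.
oracle_rcs_term <- function(x, knots, j) {
  k <- length(knots)
  p3 <- function(u) ifelse(u > 0, u^3, 0)
  (p3(x - knots[j]) -
     p3(x - knots[k - 1]) * (knots[k] - knots[j]) /
       (knots[k] - knots[k - 1]) +
     p3(x - knots[k]) * (knots[k - 1] - knots[j]) /
       (knots[k] - knots[k - 1])) / (knots[k] - knots[1])^2
}

# Toy survival data used across modules: hand product-limit gives
# S(1)=4/5, S(3)=4/5*2/3, S(4)=4/5*2/3*1/2.
toy_surv <- function() {
  data.frame(time = c(1, 2, 3, 4, 5), event = c(1, 0, 1, 1, 0))
}
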