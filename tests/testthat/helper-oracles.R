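# Independent oracles used to cross-check the implementation. These stay
# deliberately naive and share no code with the package internals.

# Brute-force multiset classification of one predicted allele pair against
# a two-slot truth: counts right/wrong/uncalled and returns the unmatched
# truth alleles.
oracle_classify <- function(pred, truth) {
  pred <- pred[!is.na(pred)]
  remaining <- truth
  right <- 0L
  for (p in pred) {
    j <- match(p, remaining)
    if (!is.na(j)) {
      right <- right + 1L
      remaining <- remaining[-j]
    }
  }
  list(right = right,
       wrong = length(pred) - right,
       uncalled = 2L - length(pred),
       miscall = if (length(pred) >= 1) remaining else character(0))
}

# Breslow log partial likelihood for a single numeric covariate,
# vectorized over the coefficient grid.
oracle_breslow_logpl <- function(beta, time, event, x) {
  out <- numeric(length(beta))
  for (t in unique(time[event == 1])) {
    d <- which(time == t & event == 1)
    risk <- which(time >= t)
    out <- out + sum(x[d]) * beta -
      length(d) * log(colSums(exp(outer(x[risk], beta))))
  }
  out
}

# Grid-search maximizer of the Breslow partial likelihood.
oracle_grid_cox <- function(time, event, x, lo = -4, hi = 4, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  grid[which.max(oracle_breslow_logpl(grid, time, event, x))]
}

# Hand product-limit estimator (no censoring support needed beyond
# removing censored subjects from later risk sets).
oracle_km <- function(time, event) {
  times <- sort(unique(time[event == 1]))
  surv <- numeric(length(times))
  s <- 1
  for (i in seq_along(times)) {
    at_risk <- sum(time >= times[i])
    d <- sum(time == times[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = times, surv = surv)
}
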