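# Independent oracles used by both the unit and the acceptance suites.

# exhaustive search of the adaptive-threshold cutoff: evaluate the
# (count >= v) * v objective at every candidate value directly
threshold_oracle <- function(q) {
  surv <- q[q > 0.8]
  if (length(surv) == 0L) {
    return(list(kept = rep(FALSE, length(q)), cutoff = NA_real_))
  }
  best <- -Inf; cut <- NA_real_
  for (v in sort(unique(surv))) {
    p <- sum(surv >= v) * v
    if (p > best) { best <- p; cut <- v }     # ties -> smaller cutoff
  }
  list(kept = q > 0.8 & q >= cut, cutoff = cut)
}

# independently written transcription of the interval-length outlier
# rules: window statistics first, then each rule applied wholesale
outlier_oracle <- function(rr) {
  n <- length(rr)
  if (n < 2L) return(rep(FALSE, n))
  stats <- t(sapply(seq_len(n), function(i) {
    quantile(rr[max(1, i - 13):min(n, i + 13)], c(0.1, 0.5, 0.9), names = FALSE)
  }))
  p10 <- stats[, 1]; m <- stats[, 2]; p90 <- stats[, 3]
  amp <- p90 - p10
  flag <- rep(FALSE, n)
  i <- seq_len(n - 1L)
  hi <- pmax(rr[i], rr[i + 1]); lo <- pmin(rr[i], rr[i + 1])
  mid <- (hi + lo) / 2
  pair1 <- lo < pmin(m[i] - 50, p10[i] - 0.2 * amp[i]) &
    hi > pmax(m[i] + 50, p90[i] + 0.2 * amp[i]) &
    p10[i] < mid & mid < p90[i]
  pair2 <- rr[i] < 0.7 * m[i] & rr[i + 1] < 0.7 * m[i] &
    p10[i] < rr[i] + rr[i + 1] & rr[i] + rr[i + 1] < p90[i]
  flag[i] <- flag[i] | pair1 | pair2
  flag[i + 1] <- flag[i + 1] | pair1 | pair2
  flag <- flag | rr > 1.6 * m
  flag <- flag | rr < pmin(0.7 * m, p10)
  flag
}

# random RR sequence with occasional anomalies, for oracle-agreement trials
random_rr <- function(n) {
  rr <- rnorm(n, 800, 120)
  k <- sample(0:min(3, n - 1), 1)
  if (k > 0) {
    at <- sample(n, k)
    rr[at] <- rr[at] * sample(c(0.4, 0.6, 1.7, 2.2), k, replace = TRUE)
  }
  pmax(rr, 250)
}
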