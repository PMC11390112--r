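# Independent reference implementations used as oracles.

# Naive event detection: literal sample-by-sample scan of the stated
# contract (downward crossing -> trough within the following window,
# dead time after each event, snippet window must fit).
naiveDetect <- function(x, thr, pre = 16L, post = 32L, dead = 48L) {
  n <- length(x)
  events <- integer()
  lastEvent <- -Inf
  for (i in seq_len(n)) {
    crossed <- x[i] < thr && (i == 1L || x[i - 1L] >= thr)
    if (!crossed) next
    if (i <= lastEvent + dead) next
    windowEnd <- min(i + post, n)
    trough <- i
    for (j in i:windowEnd) if (x[j] < x[trough]) trough <- j
    lastEvent <- trough
    if (trough - pre >= 1L && trough + post - 1L <= n) {
      events <- c(events, trough)
    }
  }
  events
}

# Brute-force Mood's median test: explicit cell counts + textbook
# 2x2 chi-square formula (no continuity correction).
bruteMedianTest <- function(x, y) {
  g <- stats::median(c(x, y))
  a <- sum(x > g); b <- sum(x <= g)
  cc <- sum(y > g); d <- sum(y <= g)
  n <- a + b + cc + d
  denom <- (a + b) * (cc + d) * (a + cc) * (b + d)
  if (denom == 0) return(list(statistic = 0, p = 1))
  stat <- n * (a * d - b * cc)^2 / denom
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# Analytic squared-magnitude response of an order-n Butterworth
# high-pass applied forward and backward (zero-phase).
butterHighpassGain2 <- function(f, cutoff, order) {
  single <- 1 / (1 + (cutoff / f)^(2 * order))
  single^2
}
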