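# Independent brute-force oracles used to cross-check the package
# implementations. These deliberately share no code with R/.

# five-number summary: sort, interpolate between order statistics, scan
# the Tukey fences
oracle_boxplot <- function(values, coef = 1.5) {
  v <- sort(values[!is.na(values)])
  n <- length(v)
  qt <- function(p) {
    h <- (n - 1) * p
    lo <- floor(h)
    if (lo + 2 > n) return(v[n])
    v[lo + 1] + (h - lo) * (v[lo + 2] - v[lo + 1])
  }
  q1 <- qt(0.25); q2 <- qt(0.5); q3 <- qt(0.75)
  iqr <- q3 - q1
  lo_f <- q1 - coef * iqr
  hi_f <- q3 + coef * iqr
  inside <- v[v >= lo_f & v <= hi_f]
  # whiskers never cross the hinges inward: in degenerate samples they
  # collapse onto the (interpolated) hinge
  list(n = n, median = q2, q1 = q1, q3 = q3,
       whisker_low = min(c(inside, q1)), whisker_high = max(c(inside, q3)),
       outliers = sort(v[v < lo_f | v > hi_f]))
}

# pointwise tricube-weighted degree-1 least squares through stats::lm.wfit
oracle_loess <- function(times, values, bandwidth, grid_times = times) {
  keep <- !is.na(values)
  t <- as.numeric(as.POSIXct(times, tz = "UTC"))[keep] / 86400
  y <- values[keep]
  n <- length(y)
  g <- as.numeric(as.POSIXct(grid_times, tz = "UTC")) / 86400
  q <- max(2L, ceiling(bandwidth * n))
  vapply(g, function(t0) {
    d <- abs(t - t0)
    dq <- sort(d)[q]
    if (dq == 0) return(mean(y[d == 0]))
    w <- (1 - pmin(d / dq, 1)^3)^3
    if (sum(w) == 0) w <- as.numeric(d <= dq)
    X <- cbind(1, t - t0)
    if (sum(w * (t - t0 - sum(w * (t - t0)) / sum(w))^2) < 1e-12) {
      return(sum(w * y) / sum(w))
    }
    unname(stats::lm.wfit(X, y, w)$coefficients[1])
  }, numeric(1))
}

# nearest scheduled daily time, first wins on ties, by explicit scan
oracle_slot <- function(minute_of_day, daily_times) {
  d <- abs(daily_times - minute_of_day)
  which(d == min(d))[1]
}
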