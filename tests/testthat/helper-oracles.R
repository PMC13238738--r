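# Independent reference implementations used as oracles. These deliberately
# avoid the code paths of the package: the NB/Poisson pmf is built by the
# multiplicative recurrence, BH by the literal step-up procedure, and
# counting by a double loop.

# pmf of NB(mu, size = theta) at 0..k_max via the recurrence
# f(0) = (theta/(theta+mu))^theta, f(k+1) = f(k) * (k+theta)/(k+1) * mu/(mu+theta);
# theta = Inf gives the Poisson recurrence f(k+1) = f(k) * mu/(k+1).
oracle_count_pmf <- function(k_max, mu, theta) {
  f <- numeric(k_max + 1)
  if (is.infinite(theta)) {
    f[1] <- exp(-mu)
    for (k in seq_len(k_max)) f[k + 1] <- f[k] * mu / k
  } else {
    f[1] <- (theta / (theta + mu))^theta
    r <- mu / (mu + theta)
    for (k in seq_len(k_max)) f[k + 1] <- f[k] * (k - 1 + theta) / k * r
  }
  f
}

# P(Y >= y) by explicit pmf summation
oracle_tail <- function(y, mu, theta) {
  if (y == 0) return(1)
  if (mu == 0) return(0)
  1 - sum(oracle_count_pmf(y - 1, mu, theta))
}

# literal BH step-up: sort, p_(i) * m / i, cumulative min from the largest,
# clamp, return in input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# double loop over (midpoint, interval)
oracle_count_midpoints <- function(intervals, track) {
  counts <- integer(nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    for (j in seq_len(nrow(track))) {
      if (track$chrom[j] == intervals$chrom[i] &&
          track$pos[j] >= intervals$start[i] &&
          track$pos[j] < intervals$end[i]) {
        counts[i] <- counts[i] + 1L
      }
    }
  }
  counts
}
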