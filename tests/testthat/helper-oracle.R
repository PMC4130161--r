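# Independent change-point oracle: exhaustive least-squares segmentation.
# For a trace with at most two change points, enumerate all ordered
# change-point positions (each the first index of a new segment) and pick
# the split minimizing the residual sum of squares around segment means.
# O(n^2) via cumulative sums; independent of the package's detector.

seg_rss_fun <- function(x) {
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  function(i, j) {
    n <- j - i + 1
    s <- cs[j + 1] - cs[i]
    (cs2[j + 1] - cs2[i]) - s^2 / n
  }
}

oracle_changepoints <- function(x, n_changes) {
  n <- length(x)
  rss <- seg_rss_fun(x)
  if (n_changes == 0) return(integer(0))
  if (n_changes == 1) {
    best <- NULL; best_rss <- Inf
    for (c1 in 2:n) {
      r <- rss(1, c1 - 1) + rss(c1, n)
      if (r < best_rss) { best_rss <- r; best <- c1 }
    }
    return(best)
  }
  if (n_changes == 2) {
    best <- NULL; best_rss <- Inf
    for (c1 in 2:(n - 1)) {
      r1 <- rss(1, c1 - 1)
      for (c2 in (c1 + 1):n) {
        r <- r1 + rss(c1, c2 - 1) + rss(c2, n)
        if (r < best_rss) { best_rss <- r; best <- c(c1, c2) }
      }
    }
    return(best)
  }
  stop("oracle supports at most 2 change points")
}
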