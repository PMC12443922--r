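# Brute-force oracles, deliberately independent of the package internals.

# signed-rank: enumerate all 2^n sign assignments on the observed midranks
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(m) {
    s <- as.integer(intToBits(m))[1:n]
    sum(r[s == 1])
  }, numeric(1))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# rank-sum: enumerate all choose(m+n, m) assignments of the pooled values
oracle_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  m <- length(x)
  w_obs <- sum(r[seq_len(m)])
  sets <- utils::combn(length(pooled), m)
  ws <- colSums(matrix(r[sets], nrow = m))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# direct O(n*w) truncated centered moving average
oracle_running_mean <- function(x, window) {
  h <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

# full re-implementation of the smoothing contract for one query AOI:
# log-ratio vs reference mean, clip, median-center, per-chromosome moving
# average, re-center
oracle_cnv_track <- function(q, ref_mat, chrom, window, clip) {
  lr <- q - rowMeans(ref_mat)
  lr <- lr - stats::median(lr)
  lr <- pmin(pmax(lr, -clip), clip)
  out <- numeric(length(lr))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    out[idx] <- oracle_running_mean(lr[idx], window)
  }
  out - stats::median(out)
}
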