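# independent oracles, kept free of the package's code paths

# brute-force Pearson chi-square: sum over cells of (O - E)^2 / E
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# exact two-sided signed-rank p-value by enumerating the null distribution of
# W+ (sum of ranks of positive differences) over all 2^N sign assignments;
# assumes no zero differences and no tied absolute values
signrank_p_oracle <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  n <- length(d)
  # distribution of W+ via polynomial expansion (exact enumeration)
  counts <- c(1, rep(0, sum(r)))
  for (ri in r) {
    shifted <- c(rep(0, ri), counts[seq_len(length(counts) - ri)])
    counts <- counts + shifted
  }
  probs <- counts / 2^n
  w_vals <- 0:(length(counts) - 1)
  p_le <- sum(probs[w_vals <= w_obs])
  p_ge <- sum(probs[w_vals >= w_obs])
  min(1, 2 * min(p_le, p_ge))
}
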