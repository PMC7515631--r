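# Shared fixture builders: everything is generated in code at test time.

# A trace data.frame with explicit positions/values.
make_trace <- function(pos, val, image = "img1", channel = "DNA") {
  data.frame(image_id = image, channel = channel,
             rel_pos = pos, intensity = val)
}

# Brute-force binning oracle: assigns each sample by explicit edge tests.
brute_force_bin <- function(pos, val, n_bins) {
  means <- rep(NA_real_, n_bins)
  counts <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    lo <- (b - 1) / n_bins
    hi <- b / n_bins
    inb <- if (b == n_bins) pos >= lo & pos <= hi else pos >= lo & pos < hi
    counts[b] <- sum(inb)
    if (counts[b] > 0) means[b] <- mean(val[inb])
  }
  list(means = means, counts = counts)
}

# Brute-force two-sample KS statistic: sup |ECDF_a - ECDF_b| over all
# observed points.
brute_force_ks_D <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(x) {
    abs(mean(a <= x) - mean(b <= x))
  }, numeric(1)))
}

# Uniformly tiled loop array with jittered loop sizes summing near n * L.
planted_loop_array <- function(n_loops, mean_size, seed) {
  set.seed(seed)
  sizes <- stats::rgamma(n_loops, shape = 20, rate = 20 / mean_size)
  sizes <- sizes / sum(sizes) * (n_loops * mean_size)
  b <- cumsum(c(0, sizes))
  hetloop:::new_loop_array(b[-length(b)], b[-1], Inf, n_loops * mean_size)
}

# Contacts drawn from P(s) proportional to 1/s on one contig, by inverse
# CDF: s = s_min * (s_max/s_min)^U has density proportional to 1/s.
power_law_contacts <- function(n, contig_len, s_min = 1e3, seed = 1) {
  set.seed(seed)
  s <- s_min * (contig_len / 2 / s_min)^stats::runif(n)
  pos_a <- stats::runif(n, 0, contig_len - s)
  data.frame(contig_a = "c1", pos_a = floor(pos_a),
             contig_b = "c1", pos_b = floor(pos_a + s))
}
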