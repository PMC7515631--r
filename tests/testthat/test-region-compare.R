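# Brute-force application of the signal-region rule: every contiguous
# window that (a) contains the argmax, (b) has all bins >= 70% of max,
# (c) has 1..max_bins bins; the rule's symmetric growth must return a
# maximal such window given per-side stopping.
rule_windows <- function(v, thr_frac, max_bins) {
  m <- which.max(v)
  thr <- thr_frac * v[m]
  wins <- list()
  for (lo in 1:m) for (hi in m:length(v)) {
    w <- hi - lo + 1
    if (w > max_bins) next
    if (all(v[lo:hi] >= thr)) wins[[length(wins) + 1]] <- c(lo, hi)
  }
  wins
}

test_that("the 70%-of-max rule recovers the documented example window", {
  v <- c(rep(10, 12), 65, 80, 100, 75, 60, rep(10, 3))  # bins 12-16 raised
  sig <- select_signal_region(mean_profile(v, channel = "FISH"))
  expect_equal(sig$bin_indices, c(13, 14, 15))
  # oracle: the returned window must satisfy the rule and be maximal per side
  wins <- rule_windows(v, 0.70, 5)
  lohi <- c(min(sig$bin_indices) + 1, max(sig$bin_indices) + 1)
  expect_true(any(vapply(wins, function(w) all(w == lohi), logical(1))))
  expect_false(v[lohi[1] - 1] >= 70)  # cannot grow left
  expect_false(v[lohi[2] + 1] >= 70)  # cannot grow right
})

test_that("signal-region growth stops at max_bins and ties go left", {
  v <- rep(100, 20)  # everything qualifies; argmax ties -> bin 0
  sig <- select_signal_region(mean_profile(v, channel = "FISH"))
  expect_equal(min(sig$bin_indices), 0)
  expect_equal(length(sig$bin_indices), 5)
  # interior argmax grows symmetrically, final odd slot taken on the left
  v2 <- rep(80, 20); v2[11] <- 100
  sig2 <- select_signal_region(mean_profile(v2, channel = "FISH"))
  expect_equal(length(sig2$bin_indices), 5)
  expect_equal(sig2$bin_indices, 8:12)
})

test_that("a delta profile yields a one-bin region with undersize warning", {
  v <- rep(0, 20); v[8] <- 50
  expect_warning(sig <- select_signal_region(mean_profile(v,
                                                          channel = "FISH")),
                 "min_bins")
  expect_equal(sig$bin_indices, 7)
  expect_true(sig$undersized)
  expect_error(select_signal_region(mean_profile(rep(0, 20))), "positive")
})

test_that("control regions satisfy the SD rule and maximise separation", {
  v <- rep(100, 20)
  sig <- select_signal_region(mean_profile(c(rep(1, 13),
                                                        rep(100, 3),
                                                        rep(1, 4)),
                                                      channel = "FISH"))
  expect_equal(sig$bin_indices, 13:15)
  ctrls <- select_control_regions(mean_profile(v), sig)
  expect_length(ctrls, 2)
  w <- 3
  for (ctrl in ctrls) {
    expect_length(ctrl$bin_indices, w)
    expect_length(intersect(ctrl$bin_indices, sig$bin_indices), 0)
  }
  expect_length(intersect(ctrls[[1]]$bin_indices, ctrls[[2]]$bin_indices), 0)
  # oracle: enumerate all admissible window pairs and verify the chosen
  # pair attains the maximal min-gap score
  starts <- 0:(20 - w)
  ok <- starts[vapply(starts, function(s)
    !any((s:(s + w - 1)) %in% sig$bin_indices), logical(1))]
  gap <- function(s1, s2) max(abs(s2 - s1) - w, 0)
  score <- function(s1, s2)
    min(gap(s1, s2), gap(s1, 13), gap(s2, 13))
  best <- max(apply(utils::combn(ok, 2), 2, function(p) {
    if (abs(p[2] - p[1]) < w) -1 else score(p[1], p[2])
  }))
  got <- score(min(ctrls[[1]]$bin_indices), min(ctrls[[2]]$bin_indices))
  expect_equal(got, best)
})

test_that("an elevated centromere bin is excluded from controls", {
  v <- rep(100, 20); v[1] <- 300  # bin 0 extreme
  sig <- structure(
    list(bin_indices = 13:15, label = "signal", undersized = FALSE),
    class = "region")
  ctrls <- select_control_regions(mean_profile(v), sig)
  for (ctrl in ctrls) expect_false(0 %in% ctrl$bin_indices)
})

test_that("impossible control constraints give an advisory error", {
  v <- c(100, rep(1000, 3), rep(-0, 0), rep(1, 16))
  # dataset so dispersed that only a few bins are admissible; demand more
  sig <- structure(list(bin_indices = 4:19, label = "signal",
                        undersized = FALSE), class = "region")
  expect_error(select_control_regions(mean_profile(v), sig,
                                      region_config(max_bins = 16)),
               "control")
})

test_that("pooled measurements are the per-image bin means, image-major", {
  set.seed(7)
  bs <- lapply(1:10, function(i)
    bin_trace(make_trace(sort(runif(60)), runif(60),
                         image = sprintf("i%02d", i)), 20))
  reg <- structure(list(bin_indices = 4:6, label = "signal",
                        undersized = FALSE), class = "region")
  vals <- pooled_measurements(bs, reg)
  expect_length(vals, 30)
  m <- hetloop:::binned_matrix(bs)
  expect_equal(vals, as.numeric(t(m$means[, 5:7])))
})

test_that("ks_compare reproduces hand-computed D values", {
  same <- ks_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic_D, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$star_label, "n.s.")
  expect_equal(ks_compare(c(1, 2, 3), c(4, 5, 6))$statistic_D, 1)
  expect_equal(ks_compare(c(1, 3, 5, 7), c(2, 4, 6, 8))$statistic_D, 0.25)
  expect_error(ks_compare(numeric(0), 1), "non-empty")
})

test_that("ks_compare is symmetric and matches the ECDF oracle", {
  for (s in 1:50) {
    set.seed(s)
    a <- rnorm(sample(5:50, 1))
    b <- rnorm(sample(5:50, 1), mean = runif(1, -1, 1))
    r1 <- ks_compare(a, b)
    r2 <- ks_compare(b, a)
    expect_equal(r1$statistic_D, r2$statistic_D)
    expect_equal(r1$p_value, r2$p_value)
    expect_equal(r1$statistic_D, brute_force_ks_D(a, b), tolerance = 1e-12)
  }
})

test_that("the asymptotic p-value uses the effective sample size", {
  a <- rnorm(30); b <- rnorm(40, 0.5)
  set.seed(2)
  r <- ks_compare(a, b)
  n_eff <- 30 * 40 / 70
  # Kolmogorov tail evaluated directly
  x <- sqrt(n_eff) * r$statistic_D
  k <- 1:100
  p_ref <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
  expect_equal(r$p_value, min(max(p_ref, 0), 1), tolerance = 1e-6)
})

test_that("region KS testing drops undefined slots symmetrically", {
  # image 2 has no samples in bin 5, so that slot must vanish from both
  b1 <- bin_trace(make_trace(c(0.05, 0.15, 0.55, 0.65), c(1, 2, 3, 4),
                             image = "a"), 10)
  b2 <- bin_trace(make_trace(c(0.05, 0.15, 0.65), c(5, 6, 7),
                             image = "b"), 10)
  ra <- structure(list(bin_indices = 0:1, label = "signal",
                       undersized = FALSE), class = "region")
  rb <- structure(list(bin_indices = 5:6, label = "control",
                       undersized = FALSE), class = "region")
  res <- region_ks_test(list(b1, b2), ra, rb)
  expect_equal(res$n_a, 3)  # image b contributes only one defined slot pair
  expect_equal(res$n_a, res$n_b)
})
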