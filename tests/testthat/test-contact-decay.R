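test_that("loci map to containing loops and gaps to the nearest loop", {
  arr <- hetloop:::new_loop_array(c(0, 500, 900), c(400, 800, 1000),
                                  Inf, 1000)
  expect_equal(hetloop:::loop_index_of(arr, c(100, 600, 950)), c(1, 2, 3))
  # gap 400-500: nearest anchor decides
  expect_equal(hetloop:::loop_index_of(arr, c(410, 490)), c(1, 2))
  # gap 800-900
  expect_equal(hetloop:::loop_index_of(arr, c(810, 890)), c(2, 3))
})

test_that("same-loop pairs carry the maximal contact weight", {
  arr <- planted_loop_array(50, 5e4, seed = 1)
  mdl <- contact_model(n_contacts = 2e4, seed = 2)
  cl <- sample_contacts(arr, mdl)
  expect_equal(nrow(cl), 2e4)
  s <- abs(cl$pos_b - cl$pos_a)
  # short-range pairs must dominate: median separation far below fiber scale
  expect_lt(median(s), arr$fiber_length / 10)
  expect_true(all(cl$pos_a >= 0 & cl$pos_a < arr$fiber_length))
})

test_that("contact sampling is seed-reproducible", {
  arr <- planted_loop_array(20, 5e4, seed = 3)
  mdl <- contact_model(n_contacts = 5e3, seed = 42)
  expect_identical(sample_contacts(arr, mdl), sample_contacts(arr, mdl))
})

test_that("a delta separation distribution lands in a single P(s) bin", {
  s0 <- 5e4
  cl <- data.frame(contig_a = "c1", pos_a = seq(0, 9e5, by = 1e4),
                   contig_b = "c1", pos_b = seq(0, 9e5, by = 1e4) + s0)
  cs <- contig_set(c(c1 = 1e6))
  pc <- ps_curve(cl, cs)
  expect_equal(sum(pc$probability > 0), 1)
  hit <- which(pc$probability > 0)
  expect_true(pc$s_lo[hit] <= s0 && s0 <= pc$s_hi[hit])
  expect_equal(sum(pc$probability), 1)
})

test_that("N50 truncation drops distal bins and renormalises a prefix", {
  set.seed(5)
  lens <- c(a = 8e5, b = 5e5, c = 4e5, d = 3e5)
  cs <- contig_set(lens)
  rows <- lapply(names(lens), function(nm) {
    n <- 400
    s <- 10^runif(n, 3.2, log10(lens[[nm]] * 0.9))
    pa <- runif(n, 0, lens[[nm]] - s)
    data.frame(contig_a = nm, pos_a = floor(pa), contig_b = nm,
               pos_b = floor(pa + s))
  })
  cl <- do.call(rbind, rows)
  full <- ps_curve(cl, cs, truncation = "none")
  trunc <- ps_curve(cl, cs, truncation = "n50")
  expect_true(all(trunc$s_hi <= cs$n50))
  expect_equal(attr(trunc, "truncation_s"), cs$n50)
  # prefix property: truncated bins are the leading bins of the full curve
  # with identical values after renormalisation
  k <- nrow(trunc)
  expect_equal(trunc$mean_s, full$mean_s[1:k])
  expect_equal(trunc$probability,
               full$probability[1:k] / sum(full$probability[1:k]),
               tolerance = 1e-12)
  expect_equal(sum(trunc$probability), 1)
  expect_true(all(trunc$probability >= 0))
})

test_that("trans contacts are excluded from P(s)", {
  cs <- contig_set(c(a = 1e5, b = 1e5))
  cl <- data.frame(contig_a = c("a", "a"), pos_a = c(0, 0),
                   contig_b = c("a", "b"), pos_b = c(5e4, 5e4))
  pc <- ps_curve(cl, cs, s_min = 1e3)
  expect_equal(sum(pc$count), 1)
  expect_error(ps_curve(data.frame(contig_a = "z", pos_a = 0,
                                   contig_b = "z", pos_b = 10),
                        cs), "absent")
})

test_that("a 1/s contact ensemble recovers a log-log slope near -1", {
  cl <- power_law_contacts(1e5, 2e6, seed = 8)
  cs <- contig_set(c(c1 = 2e6))
  pc <- ps_curve(cl, cs)
  keep <- pc$probability > 0 & pc$mean_s < 5e5
  fit <- stats::lm(log10(probability) ~ log10(mean_s),
                   data = as.data.frame(pc)[keep, ])
  slope <- unname(coef(fit)[2])
  expect_gt(slope, -1.15)
  expect_lt(slope, -0.85)
})

test_that("drop-off detection finds a planted breakpoint near 150 kb", {
  # piecewise P(s): flat to s0 = 150 kb, then steeply declining
  s <- 10^seq(3, 6, by = 1 / 8)
  p <- ifelse(s <= 1.5e5, 1, (s / 1.5e5)^-4)
  curve <- structure(
    data.frame(s_lo = s / 10^(1 / 16), s_hi = s * 10^(1 / 16),
               mean_s = s, count = NA_real_, probability = p / sum(p)),
    class = c("ps_curve", "data.frame"), truncation_s = NA_real_)
  d <- dropoff_distance(curve)
  # within one bin width (a factor of 10^(1/8)) of the planted 150 kb
  expect_gt(d, 1.5e5 / 10^(1 / 8))
  expect_lt(d, 1.5e5 * 10^(2 / 8))
})

test_that("a shallow pure power law has no drop-off", {
  s <- 10^seq(3, 6, by = 1 / 8)
  p <- s^-0.5
  curve <- structure(
    data.frame(s_lo = s / 10^(1 / 16), s_hi = s * 10^(1 / 16),
               mean_s = s, count = NA_real_, probability = p / sum(p)),
    class = c("ps_curve", "data.frame"), truncation_s = NA_real_)
  expect_true(is.na(dropoff_distance(curve)))
  expect_error(dropoff_distance(curve[1:3, ]), "4 bins")
})

test_that("fragmented-assembly projection preserves coordinates", {
  cs <- contig_set(c(a = 3e5, b = 2e5, c = 5e5))
  cl <- data.frame(contig_a = "fiber", pos_a = c(1e5, 3.5e5, 6e5),
                   contig_b = "fiber", pos_b = c(2e5, 9e5, 6.5e5))
  m <- map_contacts_to_contigs(cl, cs)
  expect_equal(m$contig_a, c("a", "b", "c"))
  expect_equal(m$contig_b, c("a", "c", "c"))
  expect_equal(m$pos_a, c(1e5, 0.5e5, 1e5))
  expect_equal(m$pos_b, c(2e5, 4e5, 1.5e5))
  # cross-contig pairs are trans and excluded from P(s) automatically
  expect_equal(sum(m$contig_a == m$contig_b), 2)
})

test_that("region subsetting shifts coordinates to the region origin", {
  cl <- data.frame(contig_a = "f", pos_a = c(10, 150, 300),
                   contig_b = "f", pos_b = c(50, 180, 90))
  sub <- subset_contacts(cl, 100, 200, "het")
  expect_equal(nrow(sub), 1)
  expect_equal(sub$pos_a, 50)
  expect_equal(sub$pos_b, 80)
})
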