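test_that("no loading and no preload gives an empty loop array", {
  fib <- fiber_spec(1e6, loading_rate = 0, duration = 100, seed = 1)
  arr <- simulate_extrusion(fib)
  expect_equal(nrow(arr$loops), 0)
})

test_that("a lone condensin extrudes to both fiber ends", {
  fib <- fiber_spec(1e6, loading_rate = 0, duration = 1e4, seed = 1)
  arr <- simulate_extrusion(fib, preload = 3e5, check_invariants = TRUE)
  expect_equal(nrow(arr$loops), 1)
  expect_equal(arr$loops$left, 0)
  expect_equal(arr$loops$right, 1e6)
})

test_that("preloaded condensins tile the fiber and match the geometry oracle", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(2:12, 1)
    L <- runif(1, 1e5, 1e6)
    pre <- sort(runif(n, 0, L))
    fib <- fiber_spec(L, loading_rate = 0, duration = 1e5, seed = s)
    arr <- simulate_extrusion(fib, preload = pre, check_invariants = TRUE)
    oracle <- collision_geometry_loops(pre, L)
    expect_equal(arr$loops$left, oracle$loops$left, tolerance = 1e-9)
    expect_equal(arr$loops$right, oracle$loops$right, tolerance = 1e-9)
    # tiling: loop sizes sum to the fiber length, mean size = L / n
    sizes <- arr$loops$right - arr$loops$left
    expect_equal(sum(sizes), L, tolerance = 1e-6)
    expect_equal(mean(sizes), L / n, tolerance = 1e-6)
  }
})

test_that("anchor intervals stay disjoint through loading and unloading", {
  # check_invariants stops inside the simulator on any violation
  fib <- fiber_spec(5e5, loading_rate = 2e-6, off_rate = 0.01,
                    duration = 500, seed = 3)
  arr <- simulate_extrusion(fib, check_invariants = TRUE)
  lt <- arr$loops$left
  rt <- arr$loops$right
  expect_true(all(rt >= lt))
  if (nrow(arr$loops) > 1)
    expect_true(all(lt[-1] >= rt[-length(rt)] - 1e-3))
  expect_true(all(lt >= 0) && all(rt <= 5e5))
})

test_that("a stalled anchor resumes when its blocker unloads", {
  # two condensins collide mid-fiber; under this seed exactly one unloads
  # and the survivor must extrude past the old contact point to both ends
  fib <- fiber_spec(1e6, loading_rate = 0, off_rate = 2e-4,
                    duration = 5000, seed = 3)
  arr <- simulate_extrusion(fib, preload = c(4e5, 6e5),
                            check_invariants = TRUE)
  expect_equal(nrow(arr$loops), 1)
  expect_equal(arr$loops$left, 0)
  expect_equal(arr$loops$right, 1e6)
})

test_that("loop statistics assign by midpoint and audit conservation", {
  arr <- hetloop:::new_loop_array(c(0, 400, 700), c(400, 700, 1000),
                                  Inf, 1000)
  regions <- data.frame(start = c(0, 500), end = c(500, 1000),
                        label = c("left", "right"))
  st <- loop_statistics(arr, regions = regions)
  expect_equal(st$n_condensins, c(1, 2))  # midpoints 200 | 550, 850
  expect_equal(st$mean_loop_size, c(400, 300))
  expect_equal(st$condensin_per_bp, c(1 / 500, 2 / 500))
  expect_equal(st$bp_per_scaffold_unit, c(500, 250))
  # conservation: looped + gap bp equals fiber length
  sizes <- arr$loops$right - arr$loops$left
  expect_equal(sum(sizes), arr$fiber_length)
  # a region with no loops is flagged undefined, not an error
  st0 <- loop_statistics(hetloop:::new_loop_array(100, 200, Inf, 1000),
                         regions = data.frame(start = 500, end = 1000,
                                              label = "empty"))
  expect_true(is.na(st0$mean_loop_size))
  expect_equal(st0$n_condensins, 0)
})

test_that("quiescent tiled states obey the density-size reciprocal law", {
  fib <- fiber_spec(3e6, seed = 11)
  arr <- simulate_extrusion(fib)
  st <- loop_statistics(arr, fib)
  prod <- st$condensin_per_bp * st$mean_loop_size
  expect_true(all(abs(prod - 1) < 0.05))
})

test_that("higher heterochromatin loading yields smaller, denser loops", {
  res <- lapply(1:5, function(s) {
    fib <- fiber_spec(3e6, het_intervals = list(c(1e6, 2e6)),
                      het_multiplier = 3, seed = 100 + s)
    pool_loop_stats(loop_statistics(simulate_extrusion(fib), fib))
  })
  het <- vapply(res, function(x) x$mean_loop_size[x$label == "het"],
                numeric(1))
  eu <- vapply(res, function(x) x$mean_loop_size[x$label == "eu"],
               numeric(1))
  expect_gt(mean(eu > het), 0.5)
  dens_het <- vapply(res, function(x)
    x$condensin_per_bp[x$label == "het"], numeric(1))
  dens_eu <- vapply(res, function(x)
    x$condensin_per_bp[x$label == "eu"], numeric(1))
  expect_gt(mean(dens_het > dens_eu), 0.5)
})

test_that("fiber validation rejects malformed heterochromatin intervals", {
  expect_error(fiber_spec(1e6, het_intervals = list(c(5e5, 4e5))),
               "start < end")
  expect_error(fiber_spec(1e6, het_intervals = list(c(0, 6e5),
                                                    c(5e5, 9e5))),
               "overlap")
  expect_error(fiber_spec(1e6, speed = 0), "speed")
})
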