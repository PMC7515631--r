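#' Specify a chromatin fiber for loop-extrusion simulation
#'
#' A 1D fiber of `length` bp, optionally carrying heterochromatin intervals
#' over which the condensin loading rate is multiplied by `het_multiplier`.
#' Defaults are chosen so that a euchromatic region reaches a mean loop size
#' near 100 kb (for loading rate lambda and per-side speed v the collision
#' spacing scales as sqrt(2 v / lambda)), inside the 80-120 kb range
#' reported for mitotic chromatin loops.
#'
#' @param length fiber length in bp.
#' @param het_intervals heterochromatin intervals: a list of `c(start, end)`
#'   pairs or a 2-column matrix, half-open, in bp, non-overlapping.
#' @param loading_rate condensin loading rate outside heterochromatin,
#'   events per bp per unit time.
#' @param het_multiplier loading-rate multiplier inside `het_intervals`
#'   (>= 0; 1 means no regional difference).
#' @param speed extrusion speed per anchor side, bp per unit time (> 0).
#' @param off_rate condensin unloading rate, events per condensin per unit
#'   time (0 = stable binding).
#' @param duration simulated time, in the same time units.
#' @param seed integer seed or `NULL`.
#' @return an object of class `fiber`.
#' @export
fiber_spec <- function(length, het_intervals = NULL,
                       loading_rate = 1.25e-7, het_multiplier = 1,
                       speed = 1000, off_rate = 0, duration = 1000,
                       seed = NULL) {
  stop_if_not_scalar_number(length, "length", min = 1)
  stop_if_not_scalar_number(loading_rate, "loading_rate", min = 0)
  stop_if_not_scalar_number(het_multiplier, "het_multiplier", min = 0)
  stop_if_not_scalar_number(speed, "speed", min = 0, strict_min = TRUE)
  stop_if_not_scalar_number(off_rate, "off_rate", min = 0)
  stop_if_not_scalar_number(duration, "duration", min = 0)
  het <- NULL
  if (!is.null(het_intervals)) {
    if (is.list(het_intervals)) het_intervals <- do.call(rbind, het_intervals)
    het <- matrix(as.numeric(het_intervals), ncol = 2)
    het <- het[order(het[, 1]), , drop = FALSE]
    if (any(het[, 1] >= het[, 2]) || any(het[, 1] < 0) ||
        any(het[, 2] > length))
      stop("het intervals must satisfy 0 <= start < end <= length",
           call. = FALSE)
    if (nrow(het) > 1 && any(het[-1, 1] < het[-nrow(het), 2]))
      stop("het intervals must not overlap", call. = FALSE)
  }
  structure(list(length = length, het_intervals = het,
                 loading_rate = loading_rate,
                 het_multiplier = het_multiplier,
                 speed = speed, off_rate = off_rate,
                 duration = duration, seed = seed),
            class = "fiber")
}

in_het <- function(fiber, x) {
  if (is.null(fiber$het_intervals)) return(rep(FALSE, length(x)))
  res <- rep(FALSE, length(x))
  for (i in seq_len(nrow(fiber$het_intervals)))
    res <- res | (x >= fiber$het_intervals[i, 1] &
                    x < fiber$het_intervals[i, 2])
  res
}

new_loop_array <- function(left, right, time, fiber_length) {
  structure(list(loops = data.frame(left = as.numeric(left),
                                    right = as.numeric(right)),
                 time = time, fiber_length = fiber_length),
            class = "loop_array")
}

#' @export
print.loop_array <- function(x, ...) {
  sizes <- x$loops$right - x$loops$left
  cat(sprintf(
    "<loop_array> %d loops at t = %.1f on a %.0f bp fiber; mean loop %.0f bp, looped fraction %.2f\n",
    nrow(x$loops), x$time, x$fiber_length,
    if (length(sizes)) mean(sizes) else NA_real_,
    sum(sizes) / x$fiber_length))
  invisible(x)
}

#' Simulate condensin loop extrusion on a fiber
#'
#' Event-driven stochastic simulation. Condensins load as point loops at
#' rate `loading_rate` per bp (times `het_multiplier` inside
#' heterochromatin; loading inside an existing loop's anchor span is
#' forbidden, the chromatin there being already extruded). Each condensin's
#' two anchors move apart at `speed` bp per unit time per side; an anchor
#' stalls while it touches a neighbouring condensin's anchor or a fiber end,
#' and resumes if the obstacle unloads. Condensins unload at `off_rate`,
#' releasing their loop. Loading times come from exact thinning of a
#' homogeneous proposal process, and anchor motion is continuous between
#' events, so stalls carry no time-step artefacts. The state at
#' `fiber$duration` is returned; the same seed reproduces it exactly.
#'
#' @param fiber a [fiber_spec()].
#' @param preload optional numeric vector of positions at which condensins
#'   are already bound (as point loops) at time 0.
#' @param check_invariants if `TRUE`, verify anchor-interval disjointness
#'   and chromatin conservation (looped + gap bp = fiber length) after every
#'   event, stopping on violation. For tests; adds overhead.
#' @return a `loop_array`: loops as `(left, right)` anchor pairs (disjoint,
#'   non-nested), plus the simulation time reached.
#' @export
simulate_extrusion <- function(fiber, preload = NULL,
                               check_invariants = FALSE) {
  stopifnot(inherits(fiber, "fiber"))
  L <- fiber$length
  v <- fiber$speed
  snap_tol <- 1e-3  # bp; collapses floating-point slack at contacts
  with_seed(fiber$seed, {
    left <- right <- numeric(0)
    if (!is.null(preload)) {
      if (any(preload < 0) || any(preload > L))
        stop("preload positions outside fiber", call. = FALSE)
      p <- sort(as.numeric(preload))
      left <- right <- p
    }
    lambda_max <- fiber$loading_rate * L * max(1, fiber$het_multiplier)
    t <- 0
    n_events <- 0L
    check <- function() {
      n <- length(left)
      if (any(right < left - snap_tol))
        stop("invariant violation: right anchor left of left anchor")
      if (n > 1 && any(left[-1] < right[-n] - snap_tol))
        stop("invariant violation: overlapping anchor intervals")
      if (any(left < -snap_tol) || any(right > L + snap_tol))
        stop("invariant violation: anchor outside fiber")
      looped <- sum(right - left)
      gaps <- L - looped
      if (abs(looped + gaps - L) > 1e-6)
        stop("invariant violation: chromatin not conserved")
    }
    repeat {
      n <- length(left)
      # moving status: stalled at fiber ends or when touching a neighbour
      if (n > 0) {
        l_bound <- c(0, right[-n])[seq_len(n)]
        r_bound <- c(left[-1], L)
        l_move <- (left - l_bound) > snap_tol
        r_move <- (r_bound - right) > snap_tol
      } else {
        l_move <- r_move <- logical(0)
      }
      # earliest collision/boundary time under current motion
      dt_coll <- Inf
      if (n > 0) {
        if (l_move[1]) dt_coll <- min(dt_coll, left[1] / v)
        if (r_move[n]) dt_coll <- min(dt_coll, (L - right[n]) / v)
        if (n > 1) {
          gap <- left[-1] - right[-n]
          closing <- v * (r_move[-n] + l_move[-1])
          pos <- closing > 0
          if (any(pos)) dt_coll <- min(dt_coll, min(gap[pos] / closing[pos]))
        }
      }
      dt_load <- if (lambda_max > 0) stats::rexp(1, lambda_max) else Inf
      dt_off <- if (fiber$off_rate > 0 && n > 0)
        stats::rexp(1, fiber$off_rate * n) else Inf
      dt_end <- fiber$duration - t
      dt <- min(dt_coll, dt_load, dt_off, dt_end)
      if (!is.finite(dt)) break  # quiescent: nothing can ever happen
      # advance continuous anchor motion
      if (n > 0) {
        left[l_move] <- left[l_move] - v * dt
        right[r_move] <- right[r_move] + v * dt
        left <- pmax(left, 0)
        right <- pmin(right, L)
        # snap contacts exactly
        if (n > 1) {
          g <- left[-1] - right[-n]
          hit <- which(g <= snap_tol)
          for (i in hit) {
            m <- (right[i] + left[i + 1]) / 2
            right[i] <- m
            left[i + 1] <- m
          }
        }
      }
      t <- t + dt
      if (dt == dt_end && dt_end <= min(dt_coll, dt_load, dt_off)) {
        if (check_invariants) check()
        break
      }
      if (dt == dt_load && dt_load <= min(dt_coll, dt_off)) {
        # thinning: accept proposal with prob lambda(x) / lambda_max
        x <- stats::runif(1, 0, L)
        rate <- fiber$loading_rate *
          (if (in_het(fiber, x)) fiber$het_multiplier else 1)
        accept <- stats::runif(1) < rate * L / lambda_max
        inside <- n > 0 && any(x >= left & x <= right)
        if (accept && !inside) {
          k <- findInterval(x, left)
          left <- append(left, x, after = k)
          right <- append(right, x, after = k)
        }
      } else if (dt == dt_off && dt_off <= dt_coll) {
        j <- sample.int(n, 1)
        left <- left[-j]
        right <- right[-j]
      }
      # collisions need no explicit handling: statuses recompute next pass
      n_events <- n_events + 1L
      if (check_invariants) check()
      if (n_events > 5e6L)
        stop("event budget exceeded; check fiber parameters", call. = FALSE)
    }
    new_loop_array(left, right, t, L)
  })
}

#' Final loop array for fixed load positions, by collision geometry
#'
#' Independent closed-form solver for the quiescent state reached from
#' condensins pre-loaded at fixed positions with no further loading or
#' unloading: neighbouring anchors moving at equal speed meet at the
#' midpoint between adjacent load positions, and the outer anchors reach the
#' fiber ends, so the final loops tile the fiber with boundaries at
#' `(x[i] + x[i+1]) / 2`. Used as the cross-check oracle for
#' [simulate_extrusion()].
#'
#' @param positions numeric vector of load positions (bp).
#' @param fiber_length fiber length (bp).
#' @return a `loop_array` at `time = Inf`.
#' @export
collision_geometry_loops <- function(positions, fiber_length) {
  x <- sort(as.numeric(positions))
  if (length(x) == 0L) return(new_loop_array(numeric(0), numeric(0), Inf,
                                             fiber_length))
  bounds <- c(0, (x[-length(x)] + x[-1]) / 2, fiber_length)
  new_loop_array(bounds[-length(bounds)], bounds[-1], Inf, fiber_length)
}

#' Per-region loop and condensin statistics
#'
#' Assigns each loop to the region containing its midpoint and reports, per
#' region: loop count (= condensin count), mean loop size, condensins per
#' bp, and bp of region chromatin per scaffold unit (region length /
#' condensin count). Regions with no loops are reported with NA statistics,
#' not an error.
#'
#' @param array a `loop_array`.
#' @param fiber the `fiber` the array was simulated on; used to derive
#'   default regions (its het intervals, labelled `"het"`, and their
#'   complement, labelled `"eu"`).
#' @param regions optional `data.frame` with columns `start`, `end`,
#'   `label` (bp, half-open) overriding the fiber-derived regions.
#' @return a `data.frame` of class `loop_stats` with columns `label`,
#'   `start`, `end`, `n_condensins`, `mean_loop_size`, `condensin_per_bp`,
#'   `bp_per_scaffold_unit`.
#' @export
loop_statistics <- function(array, fiber = NULL, regions = NULL) {
  stopifnot(inherits(array, "loop_array"))
  if (is.null(regions)) {
    if (is.null(fiber))
      stop("either 'fiber' or 'regions' is required", call. = FALSE)
    regions <- fiber_regions(fiber)
  }
  stopifnot(is.data.frame(regions),
            all(c("start", "end", "label") %in% names(regions)))
  if (any(regions$start < 0) || any(regions$end > array$fiber_length) ||
      any(regions$start >= regions$end))
    stop("regions must lie within the fiber", call. = FALSE)
  mid <- (array$loops$left + array$loops$right) / 2
  size <- array$loops$right - array$loops$left
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    inside <- mid >= regions$start[i] & mid < regions$end[i]
    n <- sum(inside)
    rl <- regions$end[i] - regions$start[i]
    data.frame(label = regions$label[i],
               start = regions$start[i], end = regions$end[i],
               n_condensins = n,
               mean_loop_size = if (n > 0) mean(size[inside]) else NA_real_,
               condensin_per_bp = n / rl,
               bp_per_scaffold_unit = if (n > 0) rl / n else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("loop_stats", "data.frame")
  out
}

#' Regions implied by a fiber
#'
#' The fiber's het intervals (labelled `"het"`) plus their euchromatic
#' complement (labelled `"eu"`), as a regions table for [loop_statistics()].
#'
#' @param fiber a [fiber_spec()].
#' @return a `data.frame` with columns `start`, `end`, `label`.
#' @export
fiber_regions <- function(fiber) {
  stopifnot(inherits(fiber, "fiber"))
  if (is.null(fiber$het_intervals))
    return(data.frame(start = 0, end = fiber$length, label = "eu"))
  het <- fiber$het_intervals
  rows <- list()
  cursor <- 0
  for (i in seq_len(nrow(het))) {
    if (het[i, 1] > cursor)
      rows[[length(rows) + 1L]] <- data.frame(start = cursor,
                                              end = het[i, 1], label = "eu")
    rows[[length(rows) + 1L]] <- data.frame(start = het[i, 1],
                                            end = het[i, 2], label = "het")
    cursor <- het[i, 2]
  }
  if (cursor < fiber$length)
    rows[[length(rows) + 1L]] <- data.frame(start = cursor,
                                            end = fiber$length, label = "eu")
  do.call(rbind, rows)
}

#' Pool loop statistics by region label
#'
#' Collapses a [loop_statistics()] table to one row per label (e.g. the two
#' `"eu"` flanks of a het interval), with counts summed and mean loop size
#' weighted by loop count.
#'
#' @param stats a `loop_stats` table.
#' @return a `data.frame` with one row per label.
#' @export
pool_loop_stats <- function(stats) {
  labs <- unique(stats$label)
  rows <- lapply(labs, function(lb) {
    s <- stats[stats$label == lb, , drop = FALSE]
    n <- sum(s$n_condensins)
    len <- sum(s$end - s$start)
    msize <- if (n > 0)
      sum(ifelse(s$n_condensins > 0,
                 s$mean_loop_size * s$n_condensins, 0)) / n else NA_real_
    data.frame(label = lb, length = len, n_condensins = n,
               mean_loop_size = msize, condensin_per_bp = n / len,
               bp_per_scaffold_unit = if (n > 0) len / n else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
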