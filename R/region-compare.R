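#' Configuration for signal/control region selection
#'
#' Encodes the rule used to pick the insert ("signal") region from a FISH
#' profile — 2 to 5 contiguous bins centred on the FISH maximum, keeping
#' only bins at or above 70% of that maximum — and the rule for control
#' regions, whose bins must lie within one SD of the dataset mean (thereby
#' excluding extreme regions such as the centromere).
#'
#' @param fish_threshold_fraction fraction of the FISH maximum a bin must
#'   reach to join the signal region (default 0.70).
#' @param min_bins minimum signal-region size in bins (default 2); a smaller
#'   result is returned with an undersize warning flag rather than an error.
#' @param max_bins maximum signal-region size in bins (default 5).
#' @param control_sd_multiplier how many dataset SDs from the dataset mean a
#'   control bin may lie (default 1).
#' @param n_controls number of control regions sought (default 2).
#' @return an object of class `region_config`.
#' @export
region_config <- function(fish_threshold_fraction = 0.70,
                          min_bins = 2, max_bins = 5,
                          control_sd_multiplier = 1, n_controls = 2) {
  stop_if_not_scalar_number(fish_threshold_fraction,
                            "fish_threshold_fraction", min = 0,
                            strict_min = TRUE)
  if (fish_threshold_fraction > 1)
    stop("'fish_threshold_fraction' must be in (0, 1]", call. = FALSE)
  stop_if_not_scalar_number(min_bins, "min_bins", min = 1)
  stop_if_not_scalar_number(max_bins, "max_bins", min = min_bins)
  stop_if_not_scalar_number(control_sd_multiplier, "control_sd_multiplier",
                            min = 0)
  stop_if_not_scalar_number(n_controls, "n_controls", min = 1)
  structure(list(fish_threshold_fraction = fish_threshold_fraction,
                 min_bins = as.integer(min_bins),
                 max_bins = as.integer(max_bins),
                 control_sd_multiplier = control_sd_multiplier,
                 n_controls = as.integer(n_controls)),
            class = "region_config")
}

new_region <- function(bins, label, undersized = FALSE) {
  bins <- as.integer(bins)
  if (length(bins) == 0L) stop("empty region", call. = FALSE)
  if (any(diff(bins) != 1L)) stop("region bins must be contiguous",
                                  call. = FALSE)
  structure(list(bin_indices = bins, label = label,
                 undersized = undersized),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region> %s: bins %d-%d (%d bins)%s\n", x$label,
              min(x$bin_indices), max(x$bin_indices), length(x$bin_indices),
              if (isTRUE(x$undersized)) " [undersized]" else ""))
  invisible(x)
}

#' Select the insert (signal) region from a FISH profile
#'
#' Finds the bin with the highest FISH intensity (ties broken toward the
#' lower index) and grows the region symmetrically outward, one bin per side
#' per step, admitting a bin only while its FISH intensity is at least
#' `fish_threshold_fraction` of the maximum. Each side stops independently
#' at its first failing bin; growth stops at `max_bins`. When one final slot
#' remains and both sides qualify, the lower-index side is taken. A result
#' smaller than `min_bins` is returned with `undersized = TRUE` and a
#' warning.
#'
#' @param fish a `mean_profile` for the FISH channel.
#' @param cfg a [region_config()].
#' @return a `region` with label `"signal"` (bin indices are 0-based).
#' @export
select_signal_region <- function(fish, cfg = region_config()) {
  stopifnot(inherits(fish, "mean_profile"), inherits(cfg, "region_config"))
  v <- fish$bin_mean
  if (fish$n_bins < cfg$max_bins)
    stop("profile has fewer bins than 'max_bins'", call. = FALSE)
  if (all(is.na(v)) || max(v, na.rm = TRUE) <= 0)
    stop("FISH profile has no positive signal", call. = FALSE)
  m <- which.max(ifelse(is.na(v), -Inf, v))  # ties -> lowest index
  thr <- cfg$fish_threshold_fraction * v[m]
  ok <- !is.na(v) & v >= thr
  lo <- hi <- m
  left_open <- right_open <- TRUE
  while ((left_open || right_open) && (hi - lo + 1L) < cfg$max_bins) {
    grew <- FALSE
    if (left_open) {
      if (lo > 1L && ok[lo - 1L]) {
        lo <- lo - 1L
        grew <- TRUE
      } else left_open <- FALSE
    }
    if (right_open && (hi - lo + 1L) < cfg$max_bins) {
      if (hi < length(v) && ok[hi + 1L]) {
        hi <- hi + 1L
        grew <- TRUE
      } else right_open <- FALSE
    }
    if (!grew && !left_open && !right_open) break
  }
  undersized <- (hi - lo + 1L) < cfg$min_bins
  if (undersized)
    warning(sprintf("signal region has %d bin(s), below min_bins = %d",
                    hi - lo + 1L, cfg$min_bins), call. = FALSE)
  new_region(seq(lo, hi) - 1L, "signal", undersized)
}

# All length-w windows of 0-based bins valid as controls for `values`:
# disjoint from `exclude` windows and with every member bin within
# mean +/- k*SD of the whole profile.
control_candidates <- function(values, w, exclude_bins, k) {
  n <- length(values)
  mu <- mean(values, na.rm = TRUE)
  sdv <- stats::sd(values, na.rm = TRUE)
  if (is.na(sdv)) sdv <- 0
  admissible <- !is.na(values) & abs(values - mu) <= k * sdv + 1e-12
  starts <- integer(0)
  for (s in 0:(n - w)) {
    bins <- s:(s + w - 1L)
    if (any(bins %in% exclude_bins)) next
    if (all(admissible[bins + 1L])) starts <- c(starts, s)
  }
  starts
}

#' Select control regions matched in size to the signal region
#'
#' Enumerates every contiguous window of the signal region's size whose
#' member bins all lie within `control_sd_multiplier` SDs of the profile's
#' overall mean (excluding extreme bins such as the boosted centromere) and
#' which does not overlap the signal region. Among admissible windows it
#' returns the `n_controls` windows (default two) maximising the minimum
#' pairwise gap between all chosen windows and the signal window — the
#' "two distant, non-overlapping controls" rule. If only fewer windows
#' exist, that many are returned with a warning.
#'
#' @param channel a `mean_profile` of the channel under test (IF or DNA).
#' @param signal the signal `region` from [select_signal_region()].
#' @param cfg a [region_config()].
#' @return a list of `region` objects labelled `"control1"`, `"control2"`, ...
#' @export
select_control_regions <- function(channel, signal, cfg = region_config()) {
  stopifnot(inherits(channel, "mean_profile"), inherits(signal, "region"),
            inherits(cfg, "region_config"))
  w <- length(signal$bin_indices)
  starts <- control_candidates(channel$bin_mean, w, signal$bin_indices,
                               cfg$control_sd_multiplier)
  if (length(starts) == 0L)
    stop(paste("no admissible control window: consider a smaller signal",
               "region or a looser control_sd_multiplier"), call. = FALSE)
  gap <- function(s1, s2) {  # gap in bins between two windows of width w
    if (s1 > s2) { tmp <- s1; s1 <- s2; s2 <- tmp }
    max(s2 - (s1 + w), 0L)
  }
  sig_start <- min(signal$bin_indices)
  n_want <- min(cfg$n_controls, length(starts))
  if (n_want < cfg$n_controls)
    warning(sprintf("only %d admissible control window(s) found", n_want),
            call. = FALSE)
  chosen <- NULL
  if (n_want == 1L) {
    d <- vapply(starts, function(s) gap(s, sig_start), numeric(1))
    chosen <- starts[which.max(d)]
  } else {
    combs <- utils::combn(starts, n_want)
    best <- -1
    for (j in seq_len(ncol(combs))) {
      sel <- combs[, j]
      # windows must be mutually disjoint
      ss <- sort(sel)
      if (any(diff(ss) < w)) next
      gaps <- c(vapply(sel, function(s) gap(s, sig_start), numeric(1)),
                utils::combn(sel, 2, function(p) gap(p[1], p[2])))
      score <- min(gaps)
      if (score > best) {
        best <- score
        chosen <- sel
      }
    }
    if (is.null(chosen)) {  # fewer mutually disjoint windows than wanted
      d <- vapply(starts, function(s) gap(s, sig_start), numeric(1))
      chosen <- starts[which.max(d)]
      warning("could not place disjoint controls; returning one",
              call. = FALSE)
    }
  }
  chosen <- sort(chosen)
  lapply(seq_along(chosen), function(i)
    new_region(chosen[i]:(chosen[i] + w - 1L), sprintf("control%d", i)))
}

#' Pool per-image per-bin measurements over a region
#'
#' Returns the per-image bin means at the region's bins across all images —
#' the "equal numbers of measurements" samples fed to the KS test. Values
#' are ordered image-major (all bins of image 1, then image 2, ...); bins
#' undefined in an image yield NA, so that two equally sized regions can be
#' filtered symmetrically before testing.
#'
#' @param binned list of `binned_trace` objects (one per image).
#' @param region a `region`.
#' @return numeric vector of length `n_images * length(region)`.
#' @export
pooled_measurements <- function(binned, region) {
  stopifnot(inherits(region, "region"))
  m <- binned_matrix(binned)
  cols <- region$bin_indices + 1L
  if (any(cols < 1L) || any(cols > m$n_bins))
    stop("region bins outside the binned traces", call. = FALSE)
  as.numeric(t(m$means[, cols, drop = FALSE]))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample KS test: D is the supremum difference of the two
#' empirical CDFs; the p-value uses the asymptotic Kolmogorov distribution
#' with effective sample size `n_a * n_b / (n_a + n_b)` (the pipeline's
#' region comparisons always supply equal n). Identical samples give D = 0
#' and p = 1.
#'
#' @param a,b numeric sample vectors (non-empty; NAs removed).
#' @param star_thresholds threshold table passed to [star_label()].
#' @return an object of class `ks_result`: list with `statistic_D`,
#'   `p_value`, `n_a`, `n_b`, `star_label`.
#' @export
#' @examples
#' ks_compare(c(1, 3, 5, 7), c(2, 4, 6, 8))$statistic_D  # 0.25
ks_compare <- function(a, b, star_thresholds = c("**" = 0.001, "*" = 0.05)) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  D <- unname(kt$statistic)
  p <- min(max(unname(kt$p.value), 0), 1)
  structure(list(statistic_D = D, p_value = p,
                 n_a = length(a), n_b = length(b),
                 star_label = star_label(p, star_thresholds)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> D = %.4f, p = %.4g (n = %d vs %d) %s\n",
              x$statistic_D, x$p_value, x$n_a, x$n_b, x$star_label))
  invisible(x)
}

#' Region-vs-region KS test on pooled per-image measurements
#'
#' Pools equal-size measurement sets for two regions with
#' [pooled_measurements()], drops slots that are undefined in either region
#' (symmetrically, preserving equal n) and runs [ks_compare()].
#'
#' @param binned list of `binned_trace` objects for the channel under test.
#' @param region_a,region_b `region` objects of equal size.
#' @param star_thresholds threshold table passed to [star_label()].
#' @return a `ks_result`.
#' @export
region_ks_test <- function(binned, region_a, region_b,
                           star_thresholds = c("**" = 0.001, "*" = 0.05)) {
  if (length(region_a$bin_indices) != length(region_b$bin_indices))
    stop("regions must contain equal numbers of bins", call. = FALSE)
  a <- pooled_measurements(binned, region_a)
  b <- pooled_measurements(binned, region_b)
  keep <- !is.na(a) & !is.na(b)
  ks_compare(a[keep], b[keep], star_thresholds)
}
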