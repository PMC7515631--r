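#' Bin one intensity trace along the relative chromosome axis
#'
#' Assigns each sample at relative position p to bin `floor(p * n_bins)`
#' (p = 1 is clamped into the last bin), i.e. half-open bins
#' \[i/n, (i+1)/n) with the final bin closed, and records the arithmetic
#' mean and sample count per bin. With the default 20 bins this reproduces
#' the 5% binning used for metaphase chromosome profiles, bin 0 being the
#' centromere end (0-5%) and bin 19 the telomere end (95-100%).
#'
#' @param trace a `data.frame` with columns `rel_pos` (in \[0, 1\], strictly
#'   increasing) and `intensity` (finite, >= 0), plus optional `image_id`
#'   and `channel` columns carried through.
#' @param n_bins number of bins (default 20).
#' @return an object of class `binned_trace`: list with `image_id`,
#'   `channel`, `bin_means` (NA where a bin received no samples),
#'   `bin_counts`, `n_bins`.
#' @export
bin_trace <- function(trace, n_bins = 20) {
  stop_if_not_scalar_number(n_bins, "n_bins", min = 1)
  n_bins <- as.integer(n_bins)
  if (!is.data.frame(trace) ||
      !all(c("rel_pos", "intensity") %in% names(trace)))
    stop("'trace' needs columns rel_pos and intensity", call. = FALSE)
  if (nrow(trace) == 0L) stop("empty trace", call. = FALSE)
  p <- trace$rel_pos
  v <- trace$intensity
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("rel_pos must be finite and in [0, 1]", call. = FALSE)
  if (is.unsorted(p, strictly = TRUE))
    stop("rel_pos must be strictly increasing", call. = FALSE)
  if (any(!is.finite(v)) || any(v < 0))
    stop("intensities must be finite and >= 0", call. = FALSE)
  idx <- pmin(floor(p * n_bins), n_bins - 1L) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  rs <- rowsum(v, idx)
  sums <- numeric(n_bins)
  sums[as.integer(rownames(rs))] <- rs[, 1]
  means <- ifelse(counts > 0, sums / counts, NA_real_)
  structure(
    list(image_id = if ("image_id" %in% names(trace))
           as.character(trace$image_id[1]) else NA_character_,
         channel = if ("channel" %in% names(trace))
           as.character(trace$channel[1]) else NA_character_,
         bin_means = means, bin_counts = counts, n_bins = n_bins),
    class = "binned_trace")
}

#' Bin every trace of one channel in a trace set
#'
#' Convenience wrapper around [bin_trace()]: splits a `trace_set` by image
#' for one channel and bins each image's trace.
#'
#' @param traces a `trace_set` `data.frame` (columns `image_id`, `channel`,
#'   `rel_pos`, `intensity`).
#' @param channel the channel to extract.
#' @param n_bins number of bins (default 20).
#' @return a list of `binned_trace` objects, one per image.
#' @export
bin_traces <- function(traces, channel, n_bins = 20) {
  stopifnot(is.data.frame(traces))
  sub <- traces[traces$channel == channel, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop(sprintf("no traces for channel '%s'", channel), call. = FALSE)
  lapply(split(sub, sub$image_id), bin_trace, n_bins = n_bins)
}

# Stack a list of binned_trace objects (same channel / n_bins) into
# n_images x n_bins matrices of means and counts.
binned_matrix <- function(binned) {
  if (!is.list(binned) || length(binned) == 0L)
    stop("need a non-empty list of binned traces", call. = FALSE)
  if (!all(vapply(binned, inherits, logical(1), "binned_trace")))
    stop("all inputs must be binned_trace objects", call. = FALSE)
  nb <- vapply(binned, function(b) b$n_bins, integer(1))
  ch <- vapply(binned, function(b) b$channel, character(1))
  if (length(unique(nb)) != 1L)
    stop("mixed bin counts across binned traces", call. = FALSE)
  if (length(unique(ch)) != 1L)
    stop("mixed channels across binned traces", call. = FALSE)
  ids <- vapply(binned, function(b) b$image_id, character(1))
  if (anyDuplicated(ids[!is.na(ids)]))
    stop("each image may contribute at most one binned trace", call. = FALSE)
  list(channel = ch[1], n_bins = nb[1], image_ids = ids,
       means = do.call(rbind, lapply(binned, function(b) b$bin_means)),
       counts = do.call(rbind, lapply(binned, function(b) b$bin_counts)))
}

#' Average binned traces into a mean chromosome profile
#'
#' The independent replicates are images: the profile's per-bin mean is the
#' mean over images of the per-image bin means, and the per-bin SEM is the
#' sample SD over images divided by sqrt(n_images). With a single image the
#' SEM is reported as 0 by convention. Bins undefined (no samples) in some
#' image are averaged over the images that do define them.
#'
#' @param binned list of `binned_trace` objects sharing channel and
#'   `n_bins`, at most one per image.
#' @return an object of class `mean_profile`: list with `channel`, `n_bins`,
#'   `bin_mean`, `bin_sem`, `n_images`.
#' @export
average_binned <- function(binned) {
  m <- binned_matrix(binned)
  n_img <- nrow(m$means)
  bin_mean <- colMeans(m$means, na.rm = TRUE)
  bin_mean[is.nan(bin_mean)] <- NA_real_
  if (n_img == 1L) {
    bin_sem <- ifelse(is.na(bin_mean), NA_real_, 0)
  } else {
    bin_sd <- apply(m$means, 2, stats::sd, na.rm = TRUE)
    n_def <- colSums(!is.na(m$means))
    bin_sem <- ifelse(n_def > 1, bin_sd / sqrt(n_def),
                      ifelse(n_def == 1, 0, NA_real_))
  }
  structure(list(channel = m$channel, n_bins = m$n_bins,
                 bin_mean = as.numeric(bin_mean),
                 bin_sem = as.numeric(bin_sem),
                 n_images = n_img),
            class = "mean_profile")
}

#' Construct a mean profile from explicit per-bin values
#'
#' @param bin_mean numeric vector of per-bin means.
#' @param bin_sem numeric vector of per-bin SEMs (default 0).
#' @param channel channel label.
#' @param n_images number of images the profile summarises.
#' @return a `mean_profile` object.
#' @export
mean_profile <- function(bin_mean, bin_sem = rep(0, length(bin_mean)),
                         channel = "DNA", n_images = 1L) {
  stopifnot(is.numeric(bin_mean), is.numeric(bin_sem),
            length(bin_mean) == length(bin_sem))
  if (any(bin_sem < 0, na.rm = TRUE))
    stop("bin_sem must be >= 0", call. = FALSE)
  structure(list(channel = channel, n_bins = length(bin_mean),
                 bin_mean = as.numeric(bin_mean),
                 bin_sem = as.numeric(bin_sem),
                 n_images = as.integer(n_images)),
            class = "mean_profile")
}

#' @export
print.mean_profile <- function(x, ...) {
  cat(sprintf("<mean_profile> channel %s, %d bins, n = %d images\n",
              x$channel, x$n_bins, x$n_images))
  print(data.frame(bin = seq_len(x$n_bins) - 1L,
                   mean = round(x$bin_mean, 4),
                   sem = round(x$bin_sem, 4)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.mean_profile <- function(x, ...) {
  mid <- (seq_len(x$n_bins) - 0.5) / x$n_bins * 100
  graphics::plot(mid, x$bin_mean, type = "b", pch = 16,
                 xlab = "position along chromosome (%)",
                 ylab = sprintf("%s intensity (a.u.)", x$channel), ...)
  graphics::arrows(mid, x$bin_mean - x$bin_sem, mid, x$bin_mean + x$bin_sem,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Normalise a profile to a reference bin
#'
#' Divides every bin mean and SEM by the original mean of `ref_bin`
#' (0-based; default bin 0, the centromeric 0-5% region), so the reference
#' bin maps to 1. This is the normalisation used when comparing
#' immunofluorescence levels between cell lines.
#'
#' @param profile a `mean_profile`.
#' @param ref_bin 0-based index of the reference bin (default 0).
#' @return the normalised `mean_profile`.
#' @export
normalize_to_reference_bin <- function(profile, ref_bin = 0) {
  stopifnot(inherits(profile, "mean_profile"))
  stop_if_not_scalar_number(ref_bin, "ref_bin", min = 0)
  i <- as.integer(ref_bin) + 1L
  if (i > profile$n_bins)
    stop(sprintf("reference bin %d outside profile (%d bins)",
                 as.integer(ref_bin), profile$n_bins), call. = FALSE)
  ref <- profile$bin_mean[i]
  if (is.na(ref) || ref <= 0)
    stop(sprintf("reference bin %d mean is undefined or <= 0",
                 as.integer(ref_bin)), call. = FALSE)
  profile$bin_mean <- profile$bin_mean / ref
  profile$bin_sem <- profile$bin_sem / ref
  profile
}

#' Per-bin ratio of two mean profiles
#'
#' Computes `numerator / denominator` bin by bin — e.g. a condensin profile
#' normalised to DNA, the condensin:chromatin ratio. Bins where the
#' denominator is missing or non-positive are flagged undefined (NA) rather
#' than erroring. SEMs are propagated to first order by adding relative
#' errors in quadrature:
#' `sem_ratio = |ratio| * sqrt((sem_num/num)^2 + (sem_den/den)^2)`.
#'
#' @param numerator,denominator `mean_profile` objects with equal `n_bins`.
#' @return a `mean_profile` whose channel is `"num/den"`.
#' @export
ratio_profile <- function(numerator, denominator) {
  stopifnot(inherits(numerator, "mean_profile"),
            inherits(denominator, "mean_profile"))
  if (numerator$n_bins != denominator$n_bins)
    stop("profiles have different bin counts", call. = FALSE)
  num <- numerator$bin_mean
  den <- denominator$bin_mean
  ok <- !is.na(num) & !is.na(den) & den > 0
  r <- ifelse(ok, num / den, NA_real_)
  rel2 <- ifelse(ok & num != 0,
                 (numerator$bin_sem / num)^2 + (denominator$bin_sem / den)^2,
                 ifelse(ok, (denominator$bin_sem / den)^2, NA_real_))
  sem <- ifelse(ok, abs(r) * sqrt(rel2), NA_real_)
  structure(list(channel = paste0(numerator$channel, "/",
                                  denominator$channel),
                 n_bins = numerator$n_bins,
                 bin_mean = as.numeric(r), bin_sem = as.numeric(sem),
                 n_images = min(numerator$n_images, denominator$n_images)),
            class = "mean_profile")
}

#' Full profile for one channel of a trace set
#'
#' Bins every image's trace and averages across images; optionally
#' normalises to a reference bin.
#'
#' @inheritParams bin_traces
#' @param normalize_ref_bin 0-based reference bin for normalisation, or
#'   `NULL` (default) for no normalisation.
#' @return a `mean_profile`.
#' @export
channel_profile <- function(traces, channel, n_bins = 20,
                            normalize_ref_bin = NULL) {
  prof <- average_binned(bin_traces(traces, channel, n_bins))
  if (!is.null(normalize_ref_bin))
    prof <- normalize_to_reference_bin(prof, normalize_ref_bin)
  prof
}
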