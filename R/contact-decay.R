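#' Layer model for contact generation from a loop array
#'
#' Maps each genomic position to an axial coordinate on the mitotic
#' chromosome — the index of its containing loop divided by
#' `loops_per_layer` — so consecutive loops stack into axial layers. Contact
#' weight between two loci decays exponentially in their axial separation
#' (contacts within one layer are very likely, contacts across layers
#' strongly restricted), with an additive bonus for loci in the same loop.
#'
#' The default `layer_decay_scale` of 2/3 layer makes the log-log slope of
#' the resulting P(s) curve cross -1.5 at a genomic separation of
#' `loops_per_layer * mean loop size`, so the drop-off detector reads out
#' the chromatin-per-layer scale directly.
#'
#' @param loops_per_layer number of consecutive loops per axial layer
#'   (>= 1, default 3).
#' @param layer_decay_scale axial decay scale in layers (> 0, default 2/3).
#' @param intra_loop_weight additive weight bonus for same-loop pairs
#'   (default 1).
#' @param n_contacts number of contact pairs to draw (default 1e5).
#' @param seed integer seed or `NULL`.
#' @return an object of class `contact_model`.
#' @export
contact_model <- function(loops_per_layer = 3, layer_decay_scale = 2 / 3,
                          intra_loop_weight = 1, n_contacts = 1e5,
                          seed = NULL) {
  stop_if_not_scalar_number(loops_per_layer, "loops_per_layer", min = 1)
  stop_if_not_scalar_number(layer_decay_scale, "layer_decay_scale",
                            min = 0, strict_min = TRUE)
  stop_if_not_scalar_number(intra_loop_weight, "intra_loop_weight", min = 0)
  stop_if_not_scalar_number(n_contacts, "n_contacts", min = 1)
  structure(list(loops_per_layer = loops_per_layer,
                 layer_decay_scale = layer_decay_scale,
                 intra_loop_weight = intra_loop_weight,
                 n_contacts = as.integer(n_contacts), seed = seed),
            class = "contact_model")
}

# Loop index for positions x given a loop_array; loci in gaps between loops
# take the nearest loop's index.
loop_index_of <- function(array, x) {
  lt <- array$loops$left
  rt <- array$loops$right
  nl <- length(lt)
  if (nl == 0L) stop("empty loop array", call. = FALSE)
  idx <- findInterval(x, lt)
  idx[idx < 1L] <- 1L
  # in gap beyond loop idx's right anchor: nearest of idx / idx + 1
  gap <- idx < nl & x > rt[idx]
  if (any(gap)) {
    d_prev <- x[gap] - rt[idx[gap]]
    d_next <- lt[idx[gap] + 1L] - x[gap]
    idx[gap] <- idx[gap] + as.integer(d_next < d_prev)
  }
  idx
}

#' Sample a contact list from a loop array under the layer model
#'
#' Draws `n_contacts` locus pairs uniformly on the fiber, accepting each
#' pair with probability proportional to
#' `exp(-|a(x) - a(y)| / layer_decay_scale) + intra_loop_weight * same_loop`,
#' where `a(x)` is the axial (layer) coordinate of `x`. Rejection sampling
#' against the maximal weight keeps the draw exact; the same seed
#' reproduces the same list.
#'
#' @param array a `loop_array` (non-empty).
#' @param model a [contact_model()].
#' @param contig_name name given to the fiber in the contact list.
#' @return a `data.frame` of class `contact_list` with columns `contig_a`,
#'   `pos_a`, `contig_b`, `pos_b` (bp).
#' @export
sample_contacts <- function(array, model, contig_name = "fiber") {
  stopifnot(inherits(array, "loop_array"), inherits(model, "contact_model"))
  if (nrow(array$loops) == 0L) stop("empty loop array", call. = FALSE)
  L <- array$fiber_length
  k <- model$loops_per_layer
  sigma <- model$layer_decay_scale
  wmax <- 1 + model$intra_loop_weight
  with_seed(model$seed, {
    need <- model$n_contacts
    xs <- numeric(0)
    ys <- numeric(0)
    guard <- 0L
    while (length(xs) < need) {
      m <- max(4L * (need - length(xs)), 20000L)
      x <- stats::runif(m, 0, L)
      y <- stats::runif(m, 0, L)
      ix <- loop_index_of(array, x)
      iy <- loop_index_of(array, y)
      da <- abs(ix - iy) / k
      w <- exp(-da / sigma) + model$intra_loop_weight * (ix == iy)
      keep <- stats::runif(m) < w / wmax
      xs <- c(xs, x[keep])
      ys <- c(ys, y[keep])
      guard <- guard + 1L
      if (guard > 10000L)
        stop("contact sampling acceptance rate too low", call. = FALSE)
    }
    res <- data.frame(contig_a = contig_name, pos_a = floor(xs[seq_len(need)]),
                      contig_b = contig_name, pos_b = floor(ys[seq_len(need)]))
    class(res) <- c("contact_list", "data.frame")
    res
  })
}

#' Restrict a contact list to pairs inside an interval
#'
#' Keeps cis pairs with both loci in `[start, end)` and shifts coordinates
#' to the interval start, so region-specific P(s) curves can be computed
#' against the region's own length.
#'
#' @param contacts a `contact_list`.
#' @param start,end interval bounds in bp (half-open).
#' @param contig_name name for the extracted region.
#' @return a `contact_list` on a single contig of length `end - start`.
#' @export
subset_contacts <- function(contacts, start, end, contig_name = "region") {
  stopifnot(is.data.frame(contacts))
  keep <- contacts$contig_a == contacts$contig_b &
    contacts$pos_a >= start & contacts$pos_a < end &
    contacts$pos_b >= start & contacts$pos_b < end
  res <- data.frame(contig_a = contig_name,
                    pos_a = contacts$pos_a[keep] - start,
                    contig_b = contig_name,
                    pos_b = contacts$pos_b[keep] - start)
  class(res) <- c("contact_list", "data.frame")
  res
}

#' Project single-fiber contacts onto a fragmented contig set
#'
#' Lays the contigs end to end along the fiber and renames each locus by its
#' containing contig (positions become contig-relative). Pairs falling on
#' different contigs become trans records; they are retained in the list but
#' excluded from P(s). Emulates mapping against a fragmented de novo
#' assembly.
#'
#' @param contacts a `contact_list` on a single contig.
#' @param contigs a `contig_set` whose total length is at least the largest
#'   coordinate in `contacts`.
#' @return a `contact_list` referencing the contig names.
#' @export
map_contacts_to_contigs <- function(contacts, contigs) {
  stopifnot(inherits(contigs, "contig_set"), is.data.frame(contacts))
  len <- contigs$contigs
  offs <- cumsum(c(0, unname(len)))
  total <- offs[length(offs)]
  if (any(c(contacts$pos_a, contacts$pos_b) >= total))
    stop("contacts extend beyond the contig set", call. = FALSE)
  place <- function(p) {
    i <- findInterval(p, offs, rightmost.closed = FALSE)
    i[i > length(len)] <- length(len)
    list(contig = names(len)[i], pos = p - offs[i])
  }
  a <- place(contacts$pos_a)
  b <- place(contacts$pos_b)
  res <- data.frame(contig_a = a$contig, pos_a = a$pos,
                    contig_b = b$contig, pos_b = b$pos)
  class(res) <- c("contact_list", "data.frame")
  res
}

#' Contact probability versus genomic separation, P(s)
#'
#' Uses cis contacts only (`contig_a == contig_b`). Separations
#' `s = |pos_a - pos_b|` are accumulated into log-spaced bins; each bin's
#' count is divided by the number of locus pairs available at that
#' separation given the contig lengths (`sum over contigs of the integral of
#' max(L - s, 0)` across the bin), correcting the contig-length bias of a
#' fragmented assembly, and the curve is normalised to unit sum over the
#' reported bins. With `truncation = "n50"` no bin extending beyond the
#' contig set's N50 is reported: past that separation too few contigs remain
#' and the curve becomes erratic.
#'
#' @param contacts a `contact_list`.
#' @param contigs a `contig_set` naming every contig the contacts reference.
#' @param bins_per_decade log-spaced bins per decade of separation
#'   (default 8).
#' @param truncation `"none"`, `"n50"`, or a numeric separation in bp.
#' @param s_min smallest separation binned (bp, default 1000).
#' @return a `data.frame` of class `ps_curve` with columns `s_lo`, `s_hi`,
#'   `mean_s`, `count`, `probability`; attribute `truncation_s`.
#' @export
ps_curve <- function(contacts, contigs, bins_per_decade = 8,
                     truncation = "none", s_min = 1000) {
  stopifnot(is.data.frame(contacts), inherits(contigs, "contig_set"))
  stop_if_not_scalar_number(bins_per_decade, "bins_per_decade", min = 1)
  stop_if_not_scalar_number(s_min, "s_min", min = 0, strict_min = TRUE)
  used <- unique(c(contacts$contig_a, contacts$contig_b))
  missing <- setdiff(used, names(contigs$contigs))
  if (length(missing) > 0)
    stop("contigs absent from contig set: ",
         paste(missing, collapse = ", "), call. = FALSE)
  cis <- contacts$contig_a == contacts$contig_b
  s <- abs(contacts$pos_b - contacts$pos_a)[cis]
  s <- s[s >= s_min]
  if (length(s) == 0L)
    stop("no cis contacts at separations >= s_min", call. = FALSE)
  trunc_s <- switch(as.character(truncation[1]),
                    none = Inf,
                    n50 = contigs$n50,
                    {
                      tv <- suppressWarnings(as.numeric(truncation[1]))
                      if (is.na(tv) || tv <= 0)
                        stop("'truncation' must be 'none', 'n50' or bp",
                             call. = FALSE)
                      tv
                    })
  s_max <- max(s)
  n_edges <- ceiling((log10(s_max) - log10(s_min)) * bins_per_decade) + 1L
  edges <- 10^(log10(s_min) + (0:n_edges) / bins_per_decade)
  idx <- findInterval(s, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_edges)
  lens <- unname(contigs$contigs)
  # pairs available at separation in [a, b): sum_contigs int_a^min(b, L)
  # (L - u) du, evaluated in closed form per contig
  avail <- vapply(seq_len(n_edges), function(i) {
    a <- edges[i]
    b <- edges[i + 1]
    hi <- pmin(b, lens)
    seg <- pmax(hi - a, 0)
    sum(ifelse(seg > 0, lens * seg - (hi^2 - a^2) / 2, 0))
  }, numeric(1))
  mean_s <- vapply(seq_len(n_edges), function(i) {
    inb <- s[idx == i]
    if (length(inb) > 0) exp(mean(log(pmax(inb, 1))))
    else sqrt(edges[i] * edges[i + 1])
  }, numeric(1))
  keep <- avail > 0
  df <- data.frame(s_lo = edges[seq_len(n_edges)][keep],
                   s_hi = edges[-1][keep],
                   mean_s = mean_s[keep], count = counts[keep],
                   probability = ifelse(avail[keep] > 0,
                                        counts[keep] / avail[keep], 0))
  df <- df[df$s_hi <= trunc_s, , drop = FALSE]
  if (nrow(df) == 0L)
    stop("no bins survive truncation", call. = FALSE)
  tot <- sum(df$probability)
  if (tot > 0) df$probability <- df$probability / tot
  rownames(df) <- NULL
  structure(df, class = c("ps_curve", "data.frame"),
            truncation_s = if (is.finite(trunc_s)) trunc_s else NA_real_)
}

#' @export
plot.ps_curve <- function(x, ...) {
  keep <- x$probability > 0
  graphics::plot(x$mean_s[keep], x$probability[keep], log = "xy",
                 type = "b", pch = 16, xlab = "genomic separation s (bp)",
                 ylab = "contact probability P(s)", ...)
  invisible(x)
}

#' Drop-off distance of a P(s) curve
#'
#' Finds the separation at which contact probability falls off abruptly —
#' the proxy for the amount of chromatin per axial layer. The log10
#' probabilities are lightly smoothed (centred running mean over
#' `smooth_window` bins), the discrete log-log derivative is taken between
#' consecutive bins, and the geometric mean separation of the first bin pair
#' whose derivative falls below `slope_threshold` is returned. Mitotic P(s)
#' curves plateau near slope 0 before the drop, hence the default threshold
#' of -1.5. Returns `NA` when no bin pair qualifies (e.g. a shallow pure
#' power law).
#'
#' @param curve a `ps_curve` with at least 4 bins.
#' @param slope_threshold slope cutoff in d log10 P / d log10 s
#'   (default -1.5).
#' @param smooth_window odd window width for the running mean (default 3;
#'   1 disables smoothing).
#' @return drop-off separation in bp, or `NA_real_`.
#' @export
dropoff_distance <- function(curve, slope_threshold = -1.5,
                             smooth_window = 3) {
  stopifnot(inherits(curve, "ps_curve"))
  stop_if_not_scalar_number(slope_threshold, "slope_threshold")
  keep <- curve$probability > 0
  s <- curve$mean_s[keep]
  p <- curve$probability[keep]
  if (length(s) < 4L)
    stop("need at least 4 bins with positive probability", call. = FALSE)
  lp <- log10(p)
  ls <- log10(s)
  if (smooth_window > 1) {
    half <- floor(smooth_window / 2)
    lp <- vapply(seq_along(lp), function(i) {
      j <- max(1, i - half):min(length(lp), i + half)
      mean(lp[j])
    }, numeric(1))
  }
  slope <- diff(lp) / diff(ls)
  hit <- which(slope < slope_threshold)
  if (length(hit) == 0L) return(NA_real_)
  i <- hit[1]
  sqrt(s[i] * s[i + 1])
}
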