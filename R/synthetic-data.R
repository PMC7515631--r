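#' Configuration for synthetic metaphase-chromosome intensity traces
#'
#' Describes the piecewise-constant ground truth behind a set of simulated
#' chromosome line scans: a DNA/IF baseline with a fractional intensity dip
#' over an insert interval, a FISH channel that lights up over the same
#' interval, a brighter centromeric region at the start of the axis, and
#' i.i.d. Gaussian sampling noise (clipped at zero, intensities being
#' non-negative).
#'
#' Positions are on a dimensionless relative axis: 0 is the centromere end,
#' 1 the telomere end. Channels named `"FISH"` follow the FISH model
#' (`fish_gain` inside the insert, a small constant background outside);
#' every other channel follows the DNA/IF model (`baseline`, reduced by
#' `dip_fraction` inside the insert, multiplied by `centromere_boost` over
#' the first `centromere_extent` of the axis).
#'
#' @param n_images number of simulated chromosome images.
#' @param samples_per_trace intensity samples per trace, at evenly spaced
#'   midpoints in \[0, 1).
#' @param channels character vector of channel names; `"FISH"` is special.
#' @param baseline DNA/IF intensity outside the insert (arbitrary units).
#' @param insert_interval length-2 vector, relative start/end of the insert.
#' @param dip_fraction fractional DNA/IF intensity reduction over the insert,
#'   in \[0, 1\].
#' @param fish_gain FISH intensity over the insert (a.u.).
#' @param fish_background FISH level outside the insert, as a fraction of
#'   `fish_gain`; kept small but positive so a maximum-bin search is always
#'   well defined.
#' @param centromere_boost multiplier applied to DNA/IF signal over the
#'   centromeric start of the axis.
#' @param centromere_extent relative length of the boosted centromeric
#'   region (default 0.05, i.e. the first 5% bin of a 20-bin profile).
#' @param noise_sd standard deviation of the additive Gaussian noise (a.u.).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return an object of class `profile_sim_config`.
#' @export
profile_sim_config <- function(n_images = 16,
                               samples_per_trace = 200,
                               channels = c("DNA", "FISH"),
                               baseline = 100,
                               insert_interval = c(0.65, 0.80),
                               dip_fraction = 0.3,
                               fish_gain = 100,
                               fish_background = 0.02,
                               centromere_boost = 2,
                               centromere_extent = 0.05,
                               noise_sd = 5,
                               seed = NULL) {
  stop_if_not_scalar_number(n_images, "n_images", min = 1)
  stop_if_not_scalar_number(samples_per_trace, "samples_per_trace", min = 1)
  if (!is.character(channels) || length(channels) == 0L)
    stop("'channels' must be a non-empty character vector", call. = FALSE)
  stop_if_not_scalar_number(baseline, "baseline", min = 0)
  if (!is.numeric(insert_interval) || length(insert_interval) != 2L ||
      any(!is.finite(insert_interval)))
    stop("'insert_interval' must be two finite numbers", call. = FALSE)
  if (insert_interval[1] >= insert_interval[2] ||
      insert_interval[1] < 0 || insert_interval[2] > 1)
    stop("'insert_interval' must satisfy 0 <= start < end <= 1",
         call. = FALSE)
  stop_if_not_scalar_number(dip_fraction, "dip_fraction", min = 0)
  if (dip_fraction > 1) stop("'dip_fraction' must be in [0, 1]", call. = FALSE)
  stop_if_not_scalar_number(fish_gain, "fish_gain", min = 0)
  stop_if_not_scalar_number(fish_background, "fish_background", min = 0)
  stop_if_not_scalar_number(centromere_boost, "centromere_boost", min = 0)
  stop_if_not_scalar_number(centromere_extent, "centromere_extent", min = 0)
  stop_if_not_scalar_number(noise_sd, "noise_sd", min = 0)
  structure(
    list(n_images = as.integer(n_images),
         samples_per_trace = as.integer(samples_per_trace),
         channels = channels,
         baseline = baseline,
         insert_interval = as.numeric(insert_interval),
         dip_fraction = dip_fraction,
         fish_gain = fish_gain,
         fish_background = fish_background,
         centromere_boost = centromere_boost,
         centromere_extent = centromere_extent,
         noise_sd = noise_sd,
         seed = seed),
    class = "profile_sim_config")
}

# Noiseless expected intensity at relative positions `pos` for one channel.
expected_trace_value <- function(cfg, channel, pos) {
  inside <- pos >= cfg$insert_interval[1] & pos < cfg$insert_interval[2]
  if (identical(channel, "FISH")) {
    bg <- cfg$fish_background * cfg$fish_gain
    ifelse(inside, cfg$fish_gain, bg)
  } else {
    v <- ifelse(inside, cfg$baseline * (1 - cfg$dip_fraction), cfg$baseline)
    v[pos < cfg$centromere_extent] <-
      v[pos < cfg$centromere_extent] * cfg$centromere_boost
    v
  }
}

#' Simulate a set of chromosome intensity line scans
#'
#' Generates `n_images` traces per channel. Each trace samples the
#' configuration's piecewise-constant ground truth at evenly spaced midpoint
#' positions in \[0, 1), adds independent Gaussian noise of sd `noise_sd`,
#' and clips negative intensities to zero. The same seed reproduces the same
#' traces exactly.
#'
#' @param cfg a [profile_sim_config()].
#' @return a `data.frame` of class `trace_set` with columns `image_id`,
#'   `channel`, `rel_pos`, `intensity`, ordered by image then channel then
#'   position.
#' @export
#' @examples
#' ts <- simulate_trace_set(profile_sim_config(n_images = 2, seed = 1))
#' head(ts)
simulate_trace_set <- function(cfg) {
  stopifnot(inherits(cfg, "profile_sim_config"))
  with_seed(cfg$seed, {
    pos <- (seq_len(cfg$samples_per_trace) - 0.5) / cfg$samples_per_trace
    out <- vector("list", cfg$n_images * length(cfg$channels))
    k <- 0L
    for (img in seq_len(cfg$n_images)) {
      for (ch in cfg$channels) {
        mu <- expected_trace_value(cfg, ch, pos)
        val <- mu + stats::rnorm(length(pos), sd = cfg$noise_sd)
        k <- k + 1L
        out[[k]] <- data.frame(
          image_id = sprintf("img%03d", img),
          channel = ch,
          rel_pos = pos,
          intensity = pmax(val, 0))
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    class(res) <- c("trace_set", "data.frame")
    res
  })
}

#' Configuration for synthetic ChIP-qPCR Ct tables
#'
#' Plants a known fractional pulldown per locus and generates cycle-threshold
#' pairs whose noiseless percent-input recovers exactly 100 x the planted
#' enrichment under the standard dilution-adjusted delta-Ct formula
#' (see [percent_input()]).
#'
#' @param loci character vector of locus names.
#' @param true_enrichment named numeric vector (names = loci) of fractional
#'   pulldowns in (0, 1\].
#' @param input_dilution fold-dilution of the input before qPCR (>= 1);
#'   default 20 (a 1:20 input dilution).
#' @param ct_noise_sd Gaussian noise sd, in cycles, added independently to
#'   both the IP and input Ct of every record.
#' @param n_replicates independent replicates per locus (default 3).
#' @param antibody antibody label carried in the output table.
#' @param base_ct mean undiluted input Ct about which input Cts are drawn.
#' @param seed integer seed or `NULL`.
#' @return an object of class `chip_sim_config`.
#' @export
chip_sim_config <- function(loci = c("act", "maSat", "sp1", "sp2"),
                            true_enrichment = c(act = 0.02, maSat = 0.20,
                                                sp1 = 0.15, sp2 = 0.12),
                            input_dilution = 20,
                            ct_noise_sd = 0.2,
                            n_replicates = 3,
                            antibody = "H3K9me3",
                            base_ct = 25,
                            seed = NULL) {
  if (!is.character(loci) || length(loci) == 0L)
    stop("'loci' must be a non-empty character vector", call. = FALSE)
  if (!all(loci %in% names(true_enrichment)))
    stop("every locus needs a 'true_enrichment' entry", call. = FALSE)
  te <- true_enrichment[loci]
  if (any(!is.finite(te)) || any(te <= 0))
    stop("all 'true_enrichment' values must be finite and > 0", call. = FALSE)
  stop_if_not_scalar_number(input_dilution, "input_dilution", min = 1)
  stop_if_not_scalar_number(ct_noise_sd, "ct_noise_sd", min = 0)
  stop_if_not_scalar_number(n_replicates, "n_replicates", min = 1)
  stop_if_not_scalar_number(base_ct, "base_ct", min = 0, strict_min = TRUE)
  structure(
    list(loci = loci, true_enrichment = te,
         input_dilution = input_dilution, ct_noise_sd = ct_noise_sd,
         n_replicates = as.integer(n_replicates), antibody = antibody,
         base_ct = base_ct, seed = seed),
    class = "chip_sim_config")
}

#' Simulate a ChIP-qPCR Ct table
#'
#' One record per locus x replicate. The diluted-input Ct is drawn near
#' `base_ct` (replicate-level spread of 0.5 cycles), and the IP Ct is set so
#' that the noiseless percent-input equals `100 * true_enrichment`:
#' `ct_ip = (ct_input - log2(input_dilution)) - log2(true_enrichment)`.
#' Gaussian noise of sd `ct_noise_sd` is then added to both Cts.
#'
#' @param cfg a [chip_sim_config()].
#' @return a `data.frame` of class `chip_table` with columns `locus`,
#'   `antibody`, `replicate`, `ct_ip`, `ct_input`, `input_dilution`.
#' @export
simulate_chip_table <- function(cfg) {
  stopifnot(inherits(cfg, "chip_sim_config"))
  with_seed(cfg$seed, {
    recs <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        locus = cfg$loci,
                        KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    n <- nrow(recs)
    ct_input <- cfg$base_ct + stats::rnorm(n, sd = 0.5)
    e <- cfg$true_enrichment[recs$locus]
    ct_ip <- (ct_input - log2(cfg$input_dilution)) - log2(e)
    ct_input <- ct_input + stats::rnorm(n, sd = cfg$ct_noise_sd)
    ct_ip <- ct_ip + stats::rnorm(n, sd = cfg$ct_noise_sd)
    res <- data.frame(locus = recs$locus,
                      antibody = cfg$antibody,
                      replicate = recs$replicate,
                      ct_ip = as.numeric(ct_ip),
                      ct_input = as.numeric(ct_input),
                      input_dilution = cfg$input_dilution)
    res <- res[order(res$locus, res$replicate), ]
    rownames(res) <- NULL
    class(res) <- c("chip_table", "data.frame")
    res
  })
}

#' N50 of a set of contig lengths
#'
#' The length L such that contigs of length >= L together contain at least
#' half of the total assembly length.
#'
#' @param lengths numeric vector of contig lengths (bp), all > 0.
#' @return the N50 length (bp).
#' @export
#' @examples
#' n50(c(1000, 600, 400, 200))  # 600
n50 <- function(lengths) {
  if (length(lengths) == 0L || any(!is.finite(lengths)) || any(lengths <= 0))
    stop("'lengths' must be positive finite values", call. = FALSE)
  s <- sort(unname(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Fragment a genome into a synthetic contig set
#'
#' Splits `total_length` bp into `n_fragments` contigs whose lengths are a
#' symmetric Dirichlet(1) split of the total (heavy length variation, as in
#' a fragmented long-read assembly), each at least 1 bp. The defaults give a
#' ~12.5 Mb assembly in 42 contigs with a median N50 near 500 kb.
#'
#' @param total_length total assembly length in bp.
#' @param n_fragments number of contigs (>= 1, <= `total_length`).
#' @param seed integer seed or `NULL`.
#' @return an object of class `contig_set`: a list with `contigs` (named
#'   numeric vector of lengths, bp) and `n50` (bp).
#' @export
fragment_genome <- function(total_length = 12.5e6, n_fragments = 42,
                            seed = NULL) {
  stop_if_not_scalar_number(total_length, "total_length", min = 1)
  stop_if_not_scalar_number(n_fragments, "n_fragments", min = 1)
  if (n_fragments > total_length)
    stop("'n_fragments' may not exceed 'total_length'", call. = FALSE)
  n_fragments <- as.integer(n_fragments)
  with_seed(seed, {
    # Dirichlet(1, ..., 1) via normalised Exp(1) draws.
    w <- stats::rexp(n_fragments)
    len <- floor(w / sum(w) * total_length)
    len <- pmax(len, 1)
    # Repair rounding so the lengths sum exactly to total_length.
    excess <- sum(len) - total_length
    i <- 1L
    ord <- order(len, decreasing = TRUE)
    while (excess != 0) {
      j <- ord[((i - 1L) %% n_fragments) + 1L]
      step <- sign(excess)
      if (len[j] - step >= 1) {
        len[j] <- len[j] - step
        excess <- excess - step
      }
      i <- i + 1L
    }
    names(len) <- sprintf("contig%03d", seq_len(n_fragments))
    contig_set(len)
  })
}

#' Construct a contig set from named lengths
#'
#' @param lengths named numeric vector of contig lengths (bp).
#' @return an object of class `contig_set` with the computed N50.
#' @export
contig_set <- function(lengths) {
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)))
    stop("'lengths' must have unique names", call. = FALSE)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("contig lengths must be positive and finite", call. = FALSE)
  structure(list(contigs = lengths, n50 = n50(lengths)),
            class = "contig_set")
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("<contig_set> %d contigs, total %.0f bp, N50 %.0f bp\n",
              length(x$contigs), sum(x$contigs), x$n50))
  invisible(x)
}
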