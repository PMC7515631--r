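# Readers/writers for the pipeline's plain-text formats. All are strict:
# wrong column counts or non-numeric fields error with the offending line
# number. Coordinates in BED/pairs files are 0-based half-open.

read_tsv_checked <- function(path, columns, numeric_cols, header = TRUE) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  offset <- 0L
  if (header) {
    if (length(lines) == 0L)
      stop(sprintf("%s: empty file, expected a header", path), call. = FALSE)
    hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (!identical(hdr, columns))
      stop(sprintf("%s: line 1: expected header '%s'", path,
                   paste(columns, collapse = "\t")), call. = FALSE)
    lines <- lines[-1]
    offset <- 1L
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- as.data.frame(setNames(
      lapply(seq_along(columns), function(i)
        if (i %in% numeric_cols) numeric(0) else character(0)), columns))
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield != length(columns))
  if (length(bad) > 0)
    stop(sprintf("%s: line %d: expected %d tab-separated fields, found %d",
                 path, bad[1] + offset, length(columns), nfield[bad[1]]),
         call. = FALSE)
  m <- matrix(unlist(parts), ncol = length(columns), byrow = TRUE)
  out <- vector("list", length(columns))
  for (i in seq_along(columns)) {
    if (i %in% numeric_cols) {
      v <- suppressWarnings(as.numeric(m[, i]))
      bad <- which(is.na(v) & !is.na(m[, i]))
      if (length(bad) > 0)
        stop(sprintf("%s: line %d: non-numeric value '%s' in column '%s'",
                     path, bad[1] + offset, m[bad[1], i], columns[i]),
             call. = FALSE)
      out[[i]] <- v
    } else out[[i]] <- m[, i]
  }
  names(out) <- columns
  as.data.frame(out)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read / write intensity trace sets
#'
#' Traces travel as TSV with header `image_id, channel, rel_pos, intensity`.
#' A header-only file yields an empty trace set, not an error.
#'
#' @param path file path.
#' @return `read_traces()` returns a `trace_set` `data.frame`.
#' @export
read_traces <- function(path) {
  df <- read_tsv_checked(path, c("image_id", "channel", "rel_pos",
                                 "intensity"), numeric_cols = 3:4)
  class(df) <- c("trace_set", "data.frame")
  df
}

#' @rdname read_traces
#' @param traces a `trace_set` `data.frame`.
#' @export
write_traces <- function(traces, path) write_tsv(traces, path)

#' Read / write ChIP-qPCR Ct tables
#'
#' TSV with header
#' `locus, antibody, replicate, ct_ip, ct_input, input_dilution`.
#'
#' @param path file path.
#' @return `read_chip_table()` returns a `chip_table` `data.frame`.
#' @export
read_chip_table <- function(path) {
  df <- read_tsv_checked(path, c("locus", "antibody", "replicate", "ct_ip",
                                 "ct_input", "input_dilution"),
                         numeric_cols = 3:6)
  class(df) <- c("chip_table", "data.frame")
  df
}

#' @rdname read_chip_table
#' @param table a `chip_table` `data.frame`.
#' @export
write_chip_table <- function(table, path) write_tsv(table, path)

#' Read / write contig length tables (chrom.sizes dialect)
#'
#' Two tab-separated columns, contig name and length in bp, no header.
#'
#' @param path file path.
#' @return `read_chrom_sizes()` returns a `contig_set`.
#' @export
read_chrom_sizes <- function(path) {
  df <- read_tsv_checked(path, c("contig", "length"), numeric_cols = 2,
                         header = FALSE)
  if (nrow(df) == 0L) stop(sprintf("%s: no contigs", path), call. = FALSE)
  contig_set(stats::setNames(df$length, df$contig))
}

#' @rdname read_chrom_sizes
#' @param contigs a `contig_set`.
#' @export
write_chrom_sizes <- function(contigs, path) {
  stopifnot(inherits(contigs, "contig_set"))
  utils::write.table(
    data.frame(contig = names(contigs$contigs),
               length = unname(contigs$contigs)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read profile regions as BED on the nominal 100-unit axis
#'
#' Each region becomes one BED line `chrom_label, 5*first_bin,
#' 5*(last_bin+1), label` (0-based half-open, 5 units per bin for the
#' default 20-bin profile).
#'
#' @param regions a list of `region` objects.
#' @param path file path.
#' @param chrom_label chromosome label for column 1.
#' @param n_bins bin count of the profile the regions index.
#' @export
write_regions_bed <- function(regions, path, chrom_label = "chrom",
                              n_bins = 20) {
  if (inherits(regions, "region")) regions <- list(regions)
  unit <- 100 / n_bins
  rows <- lapply(regions, function(r)
    data.frame(chrom = chrom_label,
               start = unit * min(r$bin_indices),
               end = unit * (max(r$bin_indices) + 1),
               name = r$label))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_regions_bed
#' @return `read_regions_bed()` returns a list of `region` objects.
#' @export
read_regions_bed <- function(path, n_bins = 20) {
  df <- read_bed(path)
  unit <- 100 / n_bins
  lapply(seq_len(nrow(df)), function(i) {
    first <- df$start[i] / unit
    last <- df$end[i] / unit - 1
    if (abs(first - round(first)) > 1e-9 || abs(last - round(last)) > 1e-9)
      stop(sprintf("%s: line %d: coordinates not on the %g-unit bin grid",
                   path, i, unit), call. = FALSE)
    new_region(round(first):round(last), df$name[i])
  })
}

#' Read a 4-column BED file
#'
#' Columns `chrom, start, end, name`, 0-based half-open; `start < end` is
#' enforced per line.
#'
#' @param path file path.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "name"),
                         numeric_cols = 2:3, header = FALSE)
  bad <- which(df$start < 0 | df$start >= df$end)
  if (length(bad) > 0)
    stop(sprintf("%s: line %d: BED interval violates 0 <= start < end",
                 path, bad[1]), call. = FALSE)
  df
}

#' Write / read a mean profile as bedGraph-like TSV
#'
#' The profile is laid on a nominal 100-unit axis (bin i covering
#' `[5*i, 5*i + 5)` for 20 bins): columns `chrom_label, start, end, value`,
#' no header. A companion file (`<path>.stats`) carries per-bin `sem` and
#' the image count `n`.
#'
#' @param profile a `mean_profile`.
#' @param path file path for the bedGraph-like file.
#' @param chrom_label chromosome label.
#' @export
write_profile_bedgraph <- function(profile, path, chrom_label = "chrom") {
  stopifnot(inherits(profile, "mean_profile"))
  unit <- 100 / profile$n_bins
  i <- seq_len(profile$n_bins) - 1L
  utils::write.table(
    data.frame(chrom = chrom_label, start = unit * i, end = unit * (i + 1),
               value = profile$bin_mean),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_tsv(data.frame(bin = i, sem = profile$bin_sem,
                       n = profile$n_images),
            paste0(path, ".stats"))
  invisible(path)
}

#' @rdname write_profile_bedgraph
#' @return `read_profile_bedgraph()` returns a `mean_profile`.
#' @export
read_profile_bedgraph <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "value"),
                         numeric_cols = 2:4, header = FALSE)
  stats_path <- paste0(path, ".stats")
  sem <- rep(0, nrow(df))
  n_images <- 1L
  if (file.exists(stats_path)) {
    st <- read_tsv_checked(stats_path, c("bin", "sem", "n"),
                           numeric_cols = 1:3)
    sem <- st$sem
    n_images <- as.integer(st$n[1])
  }
  mean_profile(df$value, sem, channel = df$chrom[1], n_images = n_images)
}

#' Read / write contact lists (pairs-style TSV)
#'
#' Four tab-separated columns `contig_a, pos_a, contig_b, pos_b` with a
#' header line; positions in bp.
#'
#' @param path file path.
#' @return `read_pairs()` returns a `contact_list` `data.frame`.
#' @export
read_pairs <- function(path) {
  df <- read_tsv_checked(path, c("contig_a", "pos_a", "contig_b", "pos_b"),
                         numeric_cols = c(2, 4))
  bad <- which(df$pos_a < 0 | df$pos_b < 0)
  if (length(bad) > 0)
    stop(sprintf("%s: line %d: negative coordinate", path, bad[1] + 1L),
         call. = FALSE)
  class(df) <- c("contact_list", "data.frame")
  df
}

#' @rdname read_pairs
#' @param contacts a `contact_list`.
#' @export
write_pairs <- function(contacts, path) write_tsv(contacts, path)

#' Write a loop array as BED
#'
#' One line per loop: `fiber_id, left_anchor, right_anchor, loop_id`.
#'
#' @param array a `loop_array`.
#' @param path file path.
#' @param fiber_id label for column 1.
#' @export
write_loops_bed <- function(array, path, fiber_id = "fiber") {
  stopifnot(inherits(array, "loop_array"))
  utils::write.table(
    data.frame(chrom = fiber_id,
               start = round(array$loops$left),
               end = round(array$loops$right),
               name = sprintf("loop%04d", seq_len(nrow(array$loops)))),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a P(s) curve as TSV
#'
#' Columns `s_lo, s_hi, mean_s, probability` with header.
#'
#' @param curve a `ps_curve`.
#' @param path file path.
#' @export
write_ps_curve <- function(curve, path) {
  stopifnot(inherits(curve, "ps_curve"))
  write_tsv(data.frame(s_lo = curve$s_lo, s_hi = curve$s_hi,
                       mean_s = curve$mean_s,
                       probability = curve$probability), path)
}

#' @rdname write_ps_curve
#' @return `read_ps_curve()` returns a `ps_curve` (truncation unknown,
#'   recorded as NA).
#' @export
read_ps_curve <- function(path) {
  df <- read_tsv_checked(path, c("s_lo", "s_hi", "mean_s", "probability"),
                         numeric_cols = 1:4)
  df$count <- NA_real_
  structure(df[, c("s_lo", "s_hi", "mean_s", "count", "probability")],
            class = c("ps_curve", "data.frame"), truncation_s = NA_real_)
}
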