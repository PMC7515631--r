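#' Percent input from a ChIP-qPCR Ct pair
#'
#' The enrichment at a locus as the percentage of input chromatin recovered
#' by immunoprecipitation, from the standard dilution-adjusted delta-Ct
#' formula with an amplification efficiency of 2 per cycle:
#' `100 * 2^((ct_input - log2(input_dilution)) - ct_ip)`.
#' The `log2(input_dilution)` term converts the Ct of the diluted input
#' (1:20 by default) back to the undiluted input.
#'
#' @param ct_ip Ct of the immunoprecipitated sample (cycles).
#' @param ct_input Ct of the diluted input (cycles).
#' @param input_dilution fold-dilution of the input before qPCR (default 20).
#' @return percent of input (always > 0); vectorised over the Ct arguments.
#' @export
#' @examples
#' percent_input(24, 25, 20)  # 10%
percent_input <- function(ct_ip, ct_input, input_dilution = 20) {
  if (any(!is.finite(ct_ip)) || any(!is.finite(ct_input)))
    stop("Ct values must be finite", call. = FALSE)
  if (any(ct_ip <= 0) || any(ct_input <= 0))
    stop("Ct values must be > 0", call. = FALSE)
  if (any(!is.finite(input_dilution)) || any(input_dilution < 1))
    stop("'input_dilution' must be >= 1", call. = FALSE)
  100 * 2^((ct_input - log2(input_dilution)) - ct_ip)
}

#' Percent-input and positive-control normalisation for a ChIP table
#'
#' Computes [percent_input()] for every record and, within each antibody x
#' replicate set, divides every locus's percent-input by that replicate's
#' positive-control percent-input, so the positive control maps to 1 in
#' every replicate. Records whose antibody contains "no antibody"/"noAb"
#' (mock controls) are carried through but flagged and excluded from
#' downstream statistics.
#'
#' @param table a `chip_table` `data.frame` (columns `locus`, `antibody`,
#'   `replicate`, `ct_ip`, `ct_input`, `input_dilution`).
#' @param positive_control locus used as the normaliser (e.g. the mouse
#'   major-satellite locus "maSat").
#' @param negative_control locus recorded as the comparison baseline
#'   (e.g. "act"); optional.
#' @return a `data.frame` of class `enrichment_table` with added columns
#'   `percent_input`, `normalized`, `is_mock`; attributes
#'   `positive_control` and `negative_control`.
#' @export
normalize_to_positive <- function(table, positive_control,
                                  negative_control = NULL) {
  stopifnot(is.data.frame(table))
  need <- c("locus", "antibody", "replicate", "ct_ip", "ct_input",
            "input_dilution")
  if (!all(need %in% names(table)))
    stop("chip table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!positive_control %in% table$locus)
    stop(sprintf("positive control locus '%s' absent from table",
                 positive_control), call. = FALSE)
  tbl <- as.data.frame(table)
  tbl$percent_input <- percent_input(tbl$ct_ip, tbl$ct_input,
                                     tbl$input_dilution)
  tbl$is_mock <- grepl("no[ _]?antibody|noab|mock", tbl$antibody,
                       ignore.case = TRUE)
  key <- interaction(tbl$antibody, tbl$replicate, drop = TRUE)
  tbl$normalized <- NA_real_
  for (k in levels(key)) {
    rows <- which(key == k)
    pos <- rows[tbl$locus[rows] == positive_control]
    if (length(pos) == 0L)
      stop(sprintf("positive control missing in replicate group '%s'", k),
           call. = FALSE)
    ref <- mean(tbl$percent_input[pos])
    if (!is.finite(ref) || ref <= 0)
      stop(sprintf("positive control percent-input is <= 0 in group '%s'",
                   k), call. = FALSE)
    tbl$normalized[rows] <- tbl$percent_input[rows] / ref
  }
  structure(tbl,
            class = c("enrichment_table", "data.frame"),
            positive_control = positive_control,
            negative_control = negative_control)
}

#' Compare normalised enrichment at a locus against the negative control
#'
#' Two-sample two-sided Student's t-test (equal variance) of the normalised
#' enrichments at `test_locus` versus `control_locus` across replicates.
#' Mock (no-antibody) records are excluded. The default star mapping is the
#' ChIP-figure convention (* for p < 0.05).
#'
#' @param table an `enrichment_table` from [normalize_to_positive()].
#' @param test_locus locus under test.
#' @param control_locus comparison locus; defaults to the table's recorded
#'   negative control.
#' @param star_thresholds threshold table passed to [star_label()].
#' @return list with `t`, `df`, `p_value`, `star_label`, `mean_test`,
#'   `mean_control`, `n_test`, `n_control`.
#' @export
compare_to_control <- function(table, test_locus, control_locus = NULL,
                               star_thresholds = c("**" = 0.001,
                                                   "*" = 0.05)) {
  stopifnot(inherits(table, "enrichment_table"))
  if (is.null(control_locus))
    control_locus <- attr(table, "negative_control")
  if (is.null(control_locus))
    stop("no control locus given and none recorded in the table",
         call. = FALSE)
  keep <- !table$is_mock
  x <- table$normalized[keep & table$locus == test_locus]
  y <- table$normalized[keep & table$locus == control_locus]
  if (length(x) < 2L || length(y) < 2L)
    stop("need >= 2 replicates at both loci", call. = FALSE)
  df0 <- length(x) + length(y) - 2
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    # degenerate noiseless case: identical means are a non-result,
    # different means an infinitely sharp one
    same <- isTRUE(all.equal(mean(x), mean(y)))
    tt <- list(statistic = c(t = if (same) 0 else
                               sign(mean(x) - mean(y)) * Inf),
               parameter = c(df = df0),
               p.value = if (same) 1 else 0)
  } else {
    tt <- stats::t.test(x, y, var.equal = TRUE)
  }
  p <- unname(tt$p.value)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p_value = p,
       star_label = star_label(p, star_thresholds),
       mean_test = mean(x), mean_control = mean(y),
       n_test = length(x), n_control = length(y))
}

#' Summarise an enrichment table per locus
#'
#' Mean and SEM of normalised enrichment per locus (mock records excluded),
#' with the t-test of each locus against the negative control when one is
#' recorded.
#'
#' @param table an `enrichment_table`.
#' @param star_thresholds threshold table passed to [star_label()].
#' @return a `data.frame` with columns `locus`, `mean_normalized`, `sem`,
#'   `n`, `t`, `p`, `star`.
#' @export
summarize_enrichment <- function(table,
                                 star_thresholds = c("**" = 0.001,
                                                     "*" = 0.05)) {
  stopifnot(inherits(table, "enrichment_table"))
  neg <- attr(table, "negative_control")
  tbl <- table[!table$is_mock, , drop = FALSE]
  loci <- unique(tbl$locus)
  rows <- lapply(loci, function(lc) {
    v <- tbl$normalized[tbl$locus == lc]
    sem <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
    t <- p <- NA_real_
    star <- NA_character_
    if (!is.null(neg) && lc != neg && length(v) >= 2L) {
      res <- compare_to_control(table, lc, neg, star_thresholds)
      t <- res$t; p <- res$p_value; star <- res$star_label
    }
    data.frame(locus = lc, mean_normalized = mean(v), sem = sem,
               n = length(v), t = t, p = p, star = star)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
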