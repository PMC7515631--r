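#' Map a p-value to a significance star label
#'
#' Figure legends in this field label comparisons with stars whose meaning
#' varies between panels; the threshold table is therefore configurable.
#' The default maps `**` to p < 0.001 and `*` to p < 0.05.
#'
#' @param p p-value in \[0, 1\].
#' @param thresholds named numeric vector, names are labels, values are the
#'   p-value cutoffs; evaluated from smallest cutoff upward.
#' @return a single character label; `"n.s."` if no cutoff is met.
#' @export
#' @examples
#' star_label(2e-4)   # "**"
#' star_label(0.03)   # "*"
#' star_label(0.2)    # "n.s."
star_label <- function(p, thresholds = c("**" = 0.001, "*" = 0.05)) {
  stopifnot(is.numeric(p), length(p) == 1L, is.finite(p), p >= 0, p <= 1)
  stopifnot(is.numeric(thresholds), !is.null(names(thresholds)))
  thresholds <- sort(thresholds)
  for (i in seq_along(thresholds)) {
    if (p < thresholds[[i]]) return(names(thresholds)[[i]])
  }
  "n.s."
}

# Derive a reproducible sub-seed from a global seed and a stage label.
# Keeps results < 2^31 so they are valid R integer seeds.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Run `expr` under a temporary RNG seed (NULL leaves the RNG stream alone),
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}

stop_if_not_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict_min && x <= min)
    stop(sprintf("'%s' must be > %g", name, min), call. = FALSE)
  if (!strict_min && x < min)
    stop(sprintf("'%s' must be >= %g", name, min), call. = FALSE)
  invisible(x)
}
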