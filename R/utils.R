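#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control. `NA` p-values are kept `NA` and do not
#' count toward the number of tests.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of BH-adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  p.adjust(p, method = "BH")
}

#' Jaccard similarity of two sets
#'
#' @param a,b character vectors treated as sets.
#' @return |a intersect b| / |a union b|; 0 when both sets are empty.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Render a count ratio as a percentage
#'
#' Percentages in study reports are always `100 * k / n` of two integers; this
#' keeps the rendering in one place so report text and statistics agree.
#'
#' @param k integer numerator.
#' @param n integer denominator.
#' @param digits decimal places (`1` by default); use `0` for integer-percent
#'   rendering.
#' @return numeric percentage rounded to `digits`; `NA` when `n` is zero.
#' @export
format_pct <- function(k, n, digits = 1) {
  if (length(n) != 1L || is.na(n) || n == 0L) return(NA_real_)
  round(100 * k / n, digits = digits)
}

# shared input checks -----------------------------------------------------

check_count_matrix <- function(counts, arg = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`", arg, "` must be a numeric matrix (genes x samples)", call. = FALSE)
  if (any(counts < 0, na.rm = TRUE))
    stop("`", arg, "` contains negative entries", call. = FALSE)
  invisible(counts)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

`%||%` <- function(x, y) if (is.null(x)) y else x
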