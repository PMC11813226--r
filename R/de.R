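#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over genes with
#' all-positive counts, of the ratio of each sample's count to the per-gene
#' geometric mean across samples.
#'
#' @param counts nonnegative numeric matrix, genes x samples.
#' @return positive numeric vector of length `ncol(counts)`, named by sample.
#' @examples
#' m <- cbind(s1 = c(10, 20, 5), s2 = c(20, 40, 10))
#' size_factors(m)  # c(1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(counts) {
  check_count_matrix(counts)
  all_pos <- rowSums(counts <= 0) == 0L
  if (!any(all_pos))
    stop("no gene has positive counts in every sample; ",
         "filter samples or use a pseudo-reference fallback", call. = FALSE)
  sub <- counts[all_pos, , drop = FALSE]
  ref <- exp(rowMeans(log(sub)))           # per-gene geometric mean
  sf <- apply(sub, 2, function(x) median(x / ref))
  if (any(!is.finite(sf) | sf <= 0))
    stop("size factors are not all positive and finite", call. = FALSE)
  sf
}

#' Transcripts per million
#'
#' Length-normalized expression: per-kilobase rates scaled so every column
#' sums to 1e6.
#'
#' @param counts nonnegative matrix, genes x samples.
#' @param gene_lengths positive lengths in bp, one per gene (recycled from a
#'   named vector by rowname when available).
#' @return matrix of TPM values with the dimensions of `counts`.
#' @export
tpm <- function(counts, gene_lengths) {
  check_count_matrix(counts)
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts)))
    gene_lengths <- gene_lengths[rownames(counts)]
  if (length(gene_lengths) != nrow(counts))
    stop("`gene_lengths` must supply one length per gene", call. = FALSE)
  if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0))
    stop("gene lengths must be positive", call. = FALSE)
  rate <- counts / (gene_lengths / 1000)
  cs <- colSums(rate)
  cs[cs == 0] <- 1  # all-zero sample stays all-zero
  sweep(rate, 2, cs, "/") * 1e6
}

#' Variance-stabilizing transform surrogate
#'
#' `log2(count / size_factor + 1)`: a shifted log of normalized counts used
#' where a parametric variance-stabilizing fit is not needed (sample PCA,
#' co-expression input).
#'
#' @param counts nonnegative matrix, genes x samples.
#' @param sf positive size factors, one per sample (default [size_factors()]).
#' @return transformed matrix.
#' @export
vst_surrogate <- function(counts, sf = size_factors(counts)) {
  check_count_matrix(counts)
  if (length(sf) != ncol(counts) || any(sf <= 0))
    stop("`sf` must hold one positive factor per sample", call. = FALSE)
  log2(sweep(counts, 2, sf, "/") + 1)
}

#' Sample coordinates on principal components
#'
#' PCA of the gene-centered expression matrix; samples are projected on the
#' top components.
#'
#' @param mat numeric matrix, features (genes) x samples.
#' @param n_components number of components to return.
#' @return list with `coords` (samples x components) and `var_fraction`
#'   (non-increasing variance fractions, one per returned component).
#' @export
pca_coords <- function(mat, n_components = 2) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (ncol(mat) < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  centered <- mat - rowMeans(mat)
  sv <- svd(centered)
  pos <- sv$d > max(sv$d) * 1e-12
  rank <- sum(pos)
  k <- min(n_components, rank)
  if (k < n_components)
    warning("requested ", n_components, " components but rank is ", rank,
            "; returning ", k)
  coords <- sv$v[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(coords) <- list(colnames(mat), paste0("PC", seq_len(k)))
  list(coords = coords,
       var_fraction = (sv$d[seq_len(k)]^2) / sum(sv$d^2))
}

#' Negative-binomial Wald test for a pairwise group contrast
#'
#' A simplified DESeq2-style test: counts are normalized by median-of-ratios
#' size factors; per gene, a shared NB dispersion is estimated by method of
#' moments on the normalized counts (floored at 1e-8); the log2 fold change is
#' the log ratio of group means (a 0.5-count pseudo offset replaces an
#' all-zero group); the Wald statistic divides the natural-log fold change by
#' a delta-method standard error carrying a first-order small-sample
#' correction `SE^2 x (1 + 2/df)` for the plug-in dispersion; p-values are
#' two-sided normal and BH-adjusted. No dispersion shrinkage, outlier
#' filtering or independent filtering is applied, so counts of significant
#' genes will differ from a full DESeq2 analysis on real data.
#'
#' @param ds a `count_dataset` (or a list with `counts` and `group`).
#' @param contrast a [contrast_spec()] or `c(numerator, denominator)` group
#'   labels; fold changes are numerator over denominator.
#' @param alpha adjusted-p threshold for DEG calling (default 0.01).
#' @return list with `result` (a `contrast_result` data frame: gene_id,
#'   log2fc, se, wald_z, p, padj, mean_norm_count; attribute
#'   `excluded_genes` lists all-zero genes) and `degs` (a `deg_sets` object:
#'   `up`, `down`, `alpha`, `background_n`).
#' @export
nb_wald_contrast <- function(ds, contrast, alpha = 0.01) {
  spec <- as_contrast_spec(contrast)
  counts <- ds$counts
  group <- as.character(ds$group)
  for (g in c(spec$numerator, spec$denominator))
    if (sum(group == g) < 2L)
      stop("contrast group '", g, "' needs at least 2 samples", call. = FALSE)
  sel <- group %in% c(spec$numerator, spec$denominator)
  counts <- counts[, sel, drop = FALSE]
  group <- group[sel]

  excluded <- rownames(counts)[rowSums(counts) == 0]
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  norm <- sweep(counts, 2, size_factors(counts), "/")

  i1 <- group == spec$numerator
  i2 <- group == spec$denominator
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(norm[, i1, drop = FALSE])
  m2 <- rowMeans(norm[, i2, drop = FALSE])
  v1 <- apply(norm[, i1, drop = FALSE], 1, var)
  v2 <- apply(norm[, i2, drop = FALSE], 1, var)
  # 0.5-count pseudo offset keeps all-zero groups estimable
  m1[m1 == 0] <- 0.5 / n1
  m2[m2 == 0] <- 0.5 / n2

  vpool <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mbar <- (m1 + m2) / 2
  phi <- pmax((vpool - mbar) / mbar^2, 1e-8)
  df <- n1 + n2 - 2
  se <- sqrt(((1 / m1 + phi) / n1 + (1 / m2 + phi) / n2) * (1 + 2 / df))
  log2fc <- log2(m1 / m2)
  z <- log2fc * log(2) / se
  p <- 2 * pnorm(-abs(z))
  res <- data.frame(gene_id = rownames(counts), log2fc = log2fc, se = se,
                    wald_z = z, p = p, padj = bh_adjust(p),
                    mean_norm_count = rowMeans(norm), row.names = NULL)
  attr(res, "excluded_genes") <- excluded
  attr(res, "contrast") <- spec
  class(res) <- c("contrast_result", "data.frame")
  degs <- deg_sets(up = res$gene_id[res$padj < alpha & res$log2fc > 0],
                   down = res$gene_id[res$padj < alpha & res$log2fc < 0],
                   alpha = alpha, background_n = nrow(res))
  list(result = res, degs = degs)
}

#' Specify a pairwise contrast
#'
#' @param numerator,denominator distinct group labels; fold change is
#'   numerator over denominator.
#' @param name optional label (default "numerator_vs_denominator").
#' @return a `contrast_spec` list.
#' @export
contrast_spec <- function(numerator, denominator, name = NULL) {
  stopifnot(is_string(numerator), is_string(denominator))
  if (numerator == denominator)
    stop("contrast groups must be distinct", call. = FALSE)
  structure(list(name = name %||% paste0(numerator, "_vs_", denominator),
                 numerator = numerator, denominator = denominator),
            class = "contrast_spec")
}

as_contrast_spec <- function(x) {
  if (inherits(x, "contrast_spec")) return(x)
  if (is.character(x) && length(x) == 2L) return(contrast_spec(x[1], x[2]))
  stop("`contrast` must be a contrast_spec or c(numerator, denominator)",
       call. = FALSE)
}

#' Construct a DEG set pair
#'
#' @param up,down character vectors of up-/down-regulated gene ids (disjoint).
#' @param alpha the adjusted-p threshold used to call them.
#' @param background_n number of genes tested.
#' @return a `deg_sets` object.
#' @export
deg_sets <- function(up, down, alpha = 0.01, background_n) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(intersect(up, down)))
    stop("up and down DEG sets must be disjoint", call. = FALSE)
  stopifnot(background_n >= length(up) + length(down))
  structure(list(up = up, down = down, alpha = alpha,
                 background_n = as.integer(background_n)),
            class = "deg_sets")
}

#' @export
print.deg_sets <- function(x, ...) {
  cat(sprintf("deg_sets: %d up, %d down (padj < %g, %d genes tested)\n",
              length(x$up), length(x$down), x$alpha, x$background_n))
  invisible(x)
}

#' @export
print.contrast_result <- function(x, ...) {
  sp <- attr(x, "contrast")
  cat("contrast_result:", sp$name, "-", nrow(x), "genes tested\n")
  print(head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
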