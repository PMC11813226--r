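#' Upper-tail hypergeometric overlap probability
#'
#' Probability of observing an overlap at least as large as `k` between a
#' category of size `K` and a draw of size `n` from a population of `N`
#' exchangeable items: `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`. The
#' upper tail is computed directly (no complement of a near-unit sum), so tiny
#' p-values retain full relative accuracy.
#'
#' @param k observed overlap.
#' @param K category (e.g. gene-set or DEG-set) size.
#' @param n draw (e.g. query-set) size.
#' @param N population (gene-universe) size.
#' @return the upper-tail p-value.
#' @examples
#' hypergeom_overlap(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeom_overlap <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("impossible hypergeometric configuration: k=", k, ", K=", K,
         ", n=", n, ", N=", N, call. = FALSE)
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Direction-aware treatment-reversal report
#'
#' Accounts for how a treatment reverses intervention-induced differential
#' expression: "suppressed" genes are intervention-up and treatment-down,
#' "restored" genes are intervention-down and treatment-up. Each overlap gets
#' an upper-tail hypergeometric p-value (category = the intervention set, draw
#' = the opposite-sign treatment set, population = `background_n`) and a
#' Jaccard similarity of the same two sets.
#'
#' @param sucrose `deg_sets` for the intervention contrast (e.g. sucrose vs
#'   control).
#' @param treatment `deg_sets` for the treatment contrast (e.g. treated vs
#'   sucrose).
#' @param background_n gene universe size; defaults to the intervention
#'   contrast's tested-gene count. The full protein-coding universe can be
#'   supplied instead.
#' @param digits decimal places for percentage fields (default 1).
#' @return a `reversal_report` list: set sizes, overlap counts, percentages
#'   (`NA` when an intervention set is empty, never 0), hypergeometric
#'   p-values and Jaccard indices.
#' @export
reversal_report <- function(sucrose, treatment,
                            background_n = sucrose$background_n, digits = 1) {
  stopifnot(inherits(sucrose, "deg_sets"), inherits(treatment, "deg_sets"))
  suppressed <- intersect(sucrose$up, treatment$down)
  restored <- intersect(sucrose$down, treatment$up)
  n_up <- length(sucrose$up); n_down <- length(sucrose$down)
  rep <- list(
    n_sucrose_up = n_up,
    n_sucrose_down = n_down,
    n_suppressed = length(suppressed),
    n_restored = length(restored),
    pct_suppressed = format_pct(length(suppressed), n_up, digits),
    pct_restored = format_pct(length(restored), n_down, digits),
    p_hyper_suppressed = if (n_up == 0) NA_real_ else
      hypergeom_overlap(length(suppressed), n_up, length(treatment$down),
                        background_n),
    p_hyper_restored = if (n_down == 0) NA_real_ else
      hypergeom_overlap(length(restored), n_down, length(treatment$up),
                        background_n),
    jaccard_up = jaccard_index(sucrose$up, treatment$down),
    jaccard_down = jaccard_index(sucrose$down, treatment$up),
    suppressed = suppressed,
    restored = restored,
    background_n = as.integer(background_n))
  class(rep) <- "reversal_report"
  rep
}

#' @export
print.reversal_report <- function(x, ...) {
  cat("reversal_report (background n =", x$background_n, ")\n")
  cat(sprintf("  suppressed: %d of %d intervention-up (%s%%), hypergeometric p = %.3g\n",
              x$n_suppressed, x$n_sucrose_up,
              format(x$pct_suppressed), x$p_hyper_suppressed))
  cat(sprintf("  restored:   %d of %d intervention-down (%s%%), hypergeometric p = %.3g\n",
              x$n_restored, x$n_sucrose_down,
              format(x$pct_restored), x$p_hyper_restored))
  invisible(x)
}

#' Cross-tissue fold-change concordance of shared DEGs
#'
#' For genes called differentially expressed in the same contrast in two
#' tissues, measures agreement of their log2 fold changes: the fraction with
#' the same sign and the Spearman correlation of the paired values.
#'
#' @param res_a,res_b `contrast_result` objects from the two tissues (shared
#'   gene-id space).
#' @param deg_a,deg_b matching `deg_sets`.
#' @return a `concordance_report` list: `n_shared`, `pct_same_sign` (over
#'   shared DEGs with nonzero fold change in both tissues), `spearman_rho` and
#'   its p-value (`NA` when fewer than 3 shared genes), and the shared gene
#'   ids.
#' @export
cross_tissue_concordance <- function(res_a, res_b, deg_a, deg_b) {
  stopifnot(inherits(deg_a, "deg_sets"), inherits(deg_b, "deg_sets"))
  shared <- intersect(union(deg_a$up, deg_a$down),
                      union(deg_b$up, deg_b$down))
  fa <- setNames(res_a$log2fc, res_a$gene_id)[shared]
  fb <- setNames(res_b$log2fc, res_b$gene_id)[shared]
  ok <- !is.na(fa) & !is.na(fb)
  fa <- fa[ok]; fb <- fb[ok]
  nz <- fa != 0 & fb != 0
  out <- list(
    n_shared = length(fa),
    pct_same_sign = format_pct(sum(fa[nz] * fb[nz] > 0), sum(nz)),
    spearman_rho = NA_real_, p = NA_real_, shared = names(fa))
  if (length(fa) >= 3L) {
    ct <- suppressWarnings(stats::cor.test(fa, fb, method = "spearman",
                                           exact = FALSE))
    out$spearman_rho <- unname(ct$estimate)
    out$p <- ct$p.value
  }
  class(out) <- "concordance_report"
  out
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance_report: %d shared DEGs, %s%% same sign, Spearman rho = %s (p = %.3g)\n",
              x$n_shared, format(x$pct_same_sign),
              format(round(x$spearman_rho, 3)), x$p))
  invisible(x)
}
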