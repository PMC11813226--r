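#' Filter lowly-expressed genes
#'
#' Retains genes whose mean TPM across all samples of a tissue is at or above
#' the threshold (genes with mean TPM below 1 are removed by default; the
#' boundary value is kept).
#'
#' @param tpm_matrix TPM matrix, genes x samples, with rownames.
#' @param threshold mean-TPM cutoff (default 1).
#' @return character vector of retained gene ids.
#' @export
filter_low_expression <- function(tpm_matrix, threshold = 1) {
  stopifnot(is.matrix(tpm_matrix), !is.null(rownames(tpm_matrix)))
  keep <- rowMeans(tpm_matrix) >= threshold
  if (!any(keep))
    stop("all genes fall below the expression threshold", call. = FALSE)
  rownames(tpm_matrix)[keep]
}

#' Build a tissue co-expression network
#'
#' All gene pairs are scored by Spearman rank correlation (t approximation for
#' the p-value); p-values are BH-adjusted across every tested pair; candidate
#' edges are the positively correlated pairs passing the FDR cut, and the top
#' `top_frac` fraction of candidates by descending correlation is retained
#' (ties broken by canonical gene-pair order). Pairs involving constant genes
#' have undefined correlation and are excluded (counted in the result).
#'
#' @param expr expression matrix, genes x samples (at least 4 samples);
#'   typically [vst_surrogate()] or [tpm()] values of filtered genes.
#' @param fdr BH threshold for candidate edges (default 0.05).
#' @param top_frac fraction of candidate edges retained (default 0.10).
#' @param tissue optional tissue label carried into module ids.
#' @return a `coexpr_network`: `nodes` (all input genes), `edges` (data frame
#'   gene_i, gene_j, rho, p, q with gene_i < gene_j), and counts of tested,
#'   candidate and constant-excluded pairs.
#' @export
build_network <- function(expr, fdr = 0.05, top_frac = 0.10, tissue = NULL) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  n <- ncol(expr)
  if (n < 4L) stop("co-expression needs at least 4 samples", call. = FALSE)
  genes <- rownames(expr)
  ranked <- apply(expr, 1, rank)           # samples x genes
  constant <- apply(expr, 1, function(x) length(unique(x)) == 1L)
  r <- suppressWarnings(cor(ranked))
  ut <- which(upper.tri(r))
  rho <- r[ut]
  G <- length(genes)
  ii <- ((ut - 1L) %% G) + 1L              # row index of upper-tri entry
  jj <- ((ut - 1L) %/% G) + 1L
  bad <- constant[ii] | constant[jj] | is.na(rho)
  n_constant <- sum(bad)
  ii <- ii[!bad]; jj <- jj[!bad]; rho <- rho[!bad]
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  q <- bh_adjust(p)
  n_tested <- length(rho)
  cand <- rho > 0 & q < fdr
  n_cand <- sum(cand)
  edges <- data.frame(gene_i = character(0), gene_j = character(0),
                      rho = numeric(0), p = numeric(0), q = numeric(0))
  if (n_cand > 0) {
    ci <- ii[cand]; cj <- jj[cand]
    crho <- rho[cand]; cp <- p[cand]; cq <- q[cand]
    ord <- order(-crho, ci, cj)
    keep <- ord[seq_len(ceiling(top_frac * n_cand))]
    keep <- keep[order(ci[keep], cj[keep])]
    edges <- data.frame(gene_i = genes[ci[keep]], gene_j = genes[cj[keep]],
                        rho = crho[keep], p = cp[keep], q = cq[keep])
  }
  structure(list(nodes = genes, edges = edges, tissue = tissue,
                 n_tested_pairs = n_tested, n_candidates = n_cand,
                 n_constant_excluded = n_constant,
                 fdr = fdr, top_frac = top_frac),
            class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat(sprintf("coexpr_network%s: %d nodes, %d retained edges (of %d candidates, %d pairs tested)\n",
              if (!is.null(x$tissue)) paste0(" [", x$tissue, "]") else "",
              length(x$nodes), nrow(x$edges), x$n_candidates, x$n_tested_pairs))
  invisible(x)
}

#' Detect co-expression modules with the Leiden algorithm
#'
#' Runs Leiden community detection (modularity objective, correlation-weighted
#' edges) on a co-expression network. Communities smaller than `min_size` are
#' discarded to the unassigned set, as are genes without retained edges.
#' Retained modules are labelled by decreasing size (`M0` largest, prefixed by
#' the tissue label when known) and each receives a module eigengene.
#'
#' @param net a [build_network()] result.
#' @param expr the expression matrix the network was built from (used for
#'   eigengenes).
#' @param min_size minimum module size (default 30).
#' @param seed RNG seed for the Leiden refinement.
#' @param animal_ids optional per-sample animal ids (aligned with
#'   `colnames(expr)`) enabling cross-tissue eigengene correlation.
#' @return a `module_set`: `modules` (list of `id`, `genes`, `eigengene`,
#'   `var_explained`), `unassigned` gene ids, sample/animal ids, and the seed
#'   used.
#' @export
detect_modules <- function(net, expr, min_size = 30, seed = 1,
                           animal_ids = NULL) {
  stopifnot(inherits(net, "coexpr_network"), is.matrix(expr))
  out <- structure(list(modules = list(), unassigned = net$nodes,
                        tissue = net$tissue, sample_ids = colnames(expr),
                        animal_ids = animal_ids, min_size = min_size,
                        seed = seed),
                   class = "module_set")
  if (nrow(net$edges) == 0L) return(out)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               weights = igraph::E(g)$rho, n_iterations = 10)
  memb <- igraph::membership(cl)
  comms <- split(names(memb), memb)
  comms <- comms[order(-lengths(comms), vapply(comms, min, ""))]
  comms <- comms[lengths(comms) >= min_size]
  prefix <- if (!is.null(net$tissue)) paste0(net$tissue, ".") else ""
  modules <- vector("list", length(comms))
  for (i in seq_along(comms)) {
    genes <- sort(comms[[i]])
    eg <- eigengene(expr[genes, , drop = FALSE])
    modules[[i]] <- list(id = paste0(prefix, "M", i - 1L), genes = genes,
                         eigengene = eg$eigengene,
                         var_explained = eg$var_explained)
  }
  names(modules) <- vapply(modules, `[[`, "", "id")
  out$modules <- modules
  out$unassigned <- setdiff(net$nodes, unlist(lapply(modules, `[[`, "genes")))
  out
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set%s: %d modules (>= %d genes), %d unassigned genes\n",
              if (!is.null(x$tissue)) paste0(" [", x$tissue, "]") else "",
              length(x$modules), x$min_size, length(x$unassigned)))
  for (m in x$modules)
    cat(sprintf("  %s: %d genes, eigengene explains %.1f%% of variance\n",
                m$id, length(m$genes), 100 * m$var_explained))
  invisible(x)
}

#' Module eigengene
#'
#' The first principal component of the gene-standardized expression matrix of
#' a module, as a unit-norm per-sample vector. The sign is fixed so the
#' eigengene correlates positively with the mean standardized module
#' expression, making it comparable across runs.
#'
#' @param expr_sub expression submatrix of the module, genes x samples
#'   (at least 2 genes and 3 samples).
#' @return list with `eigengene` (unit-norm vector named by sample) and
#'   `var_explained` (PC1 variance fraction in \[0, 1\]).
#' @export
eigengene <- function(expr_sub) {
  stopifnot(is.matrix(expr_sub))
  if (nrow(expr_sub) < 2L || ncol(expr_sub) < 3L)
    stop("eigengene needs at least 2 genes and 3 samples", call. = FALSE)
  sds <- apply(expr_sub, 1, sd)
  if (all(sds == 0))
    stop("constant module submatrix: eigengene undefined", call. = FALSE)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant gene(s) from eigengene")
    expr_sub <- expr_sub[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
    if (nrow(expr_sub) < 2L)
      stop("fewer than 2 varying genes: eigengene undefined", call. = FALSE)
  }
  std <- (expr_sub - rowMeans(expr_sub)) / sds
  sv <- svd(std)
  score <- sv$v[, 1]
  s <- sign(sum(score * colMeans(std)))
  if (s == 0) s <- 1
  list(eigengene = setNames(s * score, colnames(expr_sub)),
       var_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Module enrichment for differentially expressed genes
#'
#' Tests each module for over-representation of each directional DEG set
#' (hypergeometric upper tail; category = DEG set, draw = module genes), with
#' BH adjustment across the whole table.
#'
#' @param mods a `module_set`.
#' @param deg_list named list of `deg_sets`, one per contrast (e.g.
#'   `list(sucrose = ..., D1 = ...)`).
#' @param background_n gene universe size (defaults to the first contrast's
#'   tested-gene count).
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return data frame (module, contrast, direction, k, set_size, module_size,
#'   p, padj, significant), classed `module_enrichment`.
#' @export
module_deg_enrichment <- function(mods, deg_list,
                                  background_n = deg_list[[1]]$background_n,
                                  alpha = 0.05) {
  stopifnot(inherits(mods, "module_set"), length(deg_list) >= 1L,
            !is.null(names(deg_list)))
  rows <- list()
  for (m in mods$modules) {
    for (cn in names(deg_list)) {
      for (dir in c("up", "down")) {
        set <- deg_list[[cn]][[dir]]
        k <- length(intersect(m$genes, set))
        rows[[length(rows) + 1L]] <- data.frame(
          module = m$id, contrast = cn, direction = dir, k = k,
          set_size = length(set), module_size = length(m$genes),
          p = hypergeom_overlap(k, length(set), length(m$genes), background_n))
      }
    }
  }
  tbl <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = character(0), contrast = character(0),
               direction = character(0), k = integer(0),
               set_size = integer(0), module_size = integer(0), p = numeric(0))
  tbl$padj <- bh_adjust(tbl$p)
  tbl$significant <- !is.na(tbl$padj) & tbl$padj < alpha
  attr(tbl, "background_n") <- background_n
  class(tbl) <- c("module_enrichment", "data.frame")
  tbl
}

#' Classify module perturbation patterns
#'
#' Labels each module by the joint enrichment pattern across an intervention
#' contrast and a treatment contrast: `intervention_up.treatment_down`
#' (elevated by the intervention, suppressed by the treatment),
#' `intervention_down.treatment_up`, `intervention_only`, `treatment_only` or
#' `none`.
#'
#' @param enr a [module_deg_enrichment()] table.
#' @param intervention,treatment contrast names as used in `enr`.
#' @return data frame (module, pattern).
#' @export
module_patterns <- function(enr, intervention = "sucrose", treatment = "D1") {
  stopifnot(inherits(enr, "module_enrichment"))
  sig <- function(mod, cn, dir)
    any(enr$significant[enr$module == mod & enr$contrast == cn &
                          enr$direction == dir])
  mods <- unique(enr$module)
  pattern <- vapply(mods, function(m) {
    iu <- sig(m, intervention, "up"); id <- sig(m, intervention, "down")
    tu <- sig(m, treatment, "up"); td <- sig(m, treatment, "down")
    if (iu && td) "intervention_up.treatment_down"
    else if (id && tu) "intervention_down.treatment_up"
    else if (iu || id) "intervention_only"
    else if (tu || td) "treatment_only"
    else "none"
  }, "")
  data.frame(module = mods, pattern = pattern, row.names = NULL)
}

#' Correlate module eigengenes between tissues
#'
#' Aligns eigengenes of two tissues' modules by animal ID and computes the
#' Spearman correlation for every inter-tissue module pair, with BH adjustment
#' across all pairs tested.
#'
#' @param mods_a,mods_b `module_set`s from two different tissues, both built
#'   with `animal_ids`.
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return data frame (module_a, module_b, R, p, padj, significant), classed
#'   `cross_module_corr`.
#' @export
cross_tissue_module_correlation <- function(mods_a, mods_b, alpha = 0.05) {
  stopifnot(inherits(mods_a, "module_set"), inherits(mods_b, "module_set"))
  if (identical(mods_a$tissue, mods_b$tissue) && !is.null(mods_a$tissue))
    stop("module sets must come from different tissues", call. = FALSE)
  if (is.null(mods_a$animal_ids) || is.null(mods_b$animal_ids))
    stop("both module sets need `animal_ids` for cross-tissue pairing",
         call. = FALSE)
  shared <- intersect(mods_a$animal_ids, mods_b$animal_ids)
  if (length(shared) < 3L)
    stop("fewer than 3 shared animals between tissues", call. = FALSE)
  ia <- match(shared, mods_a$animal_ids)
  ib <- match(shared, mods_b$animal_ids)
  rows <- list()
  for (ma in mods_a$modules) {
    for (mb in mods_b$modules) {
      ct <- suppressWarnings(stats::cor.test(ma$eigengene[ia],
                                             mb$eigengene[ib],
                                             method = "spearman",
                                             exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        module_a = ma$id, module_b = mb$id,
        R = unname(ct$estimate), p = ct$p.value)
    }
  }
  tbl <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module_a = character(0), module_b = character(0),
               R = numeric(0), p = numeric(0))
  tbl$padj <- bh_adjust(tbl$p)
  tbl$significant <- !is.na(tbl$padj) & tbl$padj < alpha
  attr(tbl, "n_animals") <- length(shared)
  class(tbl) <- c("cross_module_corr", "data.frame")
  tbl
}
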