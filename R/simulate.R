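#' Configuration for the multi-tissue study simulator
#'
#' Describes a four-group intervention design (control, sucrose, and sucrose
#' plus a treatment at two doses) measured in several tissues of the same
#' animals, mirroring a sucrose-overfeeding study in rats. Defaults give a
#' desk-scale study: 4 tissues x 2000 genes x 40 animals.
#'
#' Counts are negative binomial with a DESeq2-style dispersion trend
#' `phi = a0 / mu + a1`. A fraction `frac_sucrose_deg` of genes is
#' differentially expressed in the sucrose group (half up, half down) with
#' |log2FC| drawn as `max(Normal(lfc_location, lfc_scale), 0.25)`. For a
#' "reversed" gene the treated groups return to the control baseline; for a
#' non-reversed DEG they retain the sucrose effect. Co-expression modules are
#' planted through per-animal latent factors acting multiplicatively
#' (`2^(loading * factor)`), and selected module pairs in different tissues
#' share a common factor scaled to `cross_module_corr`, joined by animal ID.
#'
#' @param tissues character vector of tissue labels.
#' @param n_genes_per_tissue number of genes (shared gene universe across
#'   tissues; baselines are tissue specific).
#' @param n_animals_per_group animals per group; a scalar or one integer per
#'   group (at least 3 each).
#' @param groups ordered group labels; the second label is the intervention
#'   ("sucrose") and later labels are treatments on top of it.
#' @param frac_sucrose_deg fraction of genes planted as sucrose DEGs.
#' @param lfc_location,lfc_scale location and scale of the planted |log2FC|
#'   magnitude distribution.
#' @param reversal_frac_d1,reversal_frac_d2 fraction of planted DEGs whose
#'   expression returns to control baseline under the first/second treatment.
#' @param n_modules_per_tissue planted co-expression modules per tissue.
#' @param module_size_range integer interval of module sizes (minimum 2).
#' @param module_loading log2-scale loading of genes on their module factor.
#' @param n_cross_tissue_pairs number of inter-tissue module pairs with coupled
#'   latent factors.
#' @param cross_module_corr target correlation of coupled factors, in (-1, 1).
#' @param dispersion_a0,dispersion_a1 NB dispersion trend coefficients.
#' @param libsize_log_sd standard deviation of log-normal library-size factors.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of baseline
#'   gene means.
#' @param seed integer seed; a fixed seed fixes every simulated bit.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_study()]
#' @export
sim_config <- function(tissues = c("Liver", "vWAT", "SkM", "Brain"),
                       n_genes_per_tissue = 2000,
                       n_animals_per_group = 10,
                       groups = c("control", "sucrose", "D1", "D2"),
                       frac_sucrose_deg = 0.14,
                       lfc_location = 1,
                       lfc_scale = 0.4,
                       reversal_frac_d1 = 0.6,
                       reversal_frac_d2 = 0.3,
                       n_modules_per_tissue = 3,
                       module_size_range = c(40, 60),
                       module_loading = 0.5,
                       n_cross_tissue_pairs = 2,
                       cross_module_corr = 0.7,
                       dispersion_a0 = 1,
                       dispersion_a1 = 0.05,
                       libsize_log_sd = 0.2,
                       baseline_meanlog = log(100),
                       baseline_sdlog = 1,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(is.character(tissues), length(tissues) >= 1L, !anyDuplicated(tissues))
  stopifnot(length(groups) >= 2L, !anyDuplicated(groups))
  n_per <- n_animals_per_group
  if (length(n_per) == 1L) n_per <- rep(n_per, length(groups))
  if (length(n_per) != length(groups))
    stop("`n_animals_per_group` must be a scalar or one value per group", call. = FALSE)
  if (any(n_per < 3L))
    stop("`n_animals_per_group` must be at least 3 in every group", call. = FALSE)
  cfg$n_animals_per_group <- as.integer(n_per)
  for (f in c("frac_sucrose_deg", "reversal_frac_d1", "reversal_frac_d2")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop("`", f, "` must be a proportion in [0, 1]", call. = FALSE)
  }
  if (abs(cross_module_corr) >= 1)
    stop("`cross_module_corr` must lie in (-1, 1)", call. = FALSE)
  stopifnot(length(module_size_range) == 2L,
            module_size_range[1] <= module_size_range[2])
  if (module_size_range[1] < 2)
    stop("`module_size_range` minimum must be at least 2", call. = FALSE)
  if (n_modules_per_tissue * module_size_range[2] > n_genes_per_tissue)
    stop("planted module sizes exceed the gene count: ",
         n_modules_per_tissue, " modules of up to ", module_size_range[2],
         " genes but only ", n_genes_per_tissue, " genes", call. = FALSE)
  if (n_cross_tissue_pairs > 0 && length(tissues) < 2L)
    stop("cross-tissue module pairs need at least two tissues", call. = FALSE)
  if (n_cross_tissue_pairs > n_modules_per_tissue * length(tissues) / 2)
    stop("not enough modules for `n_cross_tissue_pairs` disjoint pairs", call. = FALSE)
  stopifnot(dispersion_a0 >= 0, dispersion_a1 >= 0, libsize_log_sd >= 0)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Simulate a multi-tissue intervention study
#'
#' Generates one count dataset per tissue (shared animals, tissue-specific
#' baselines) together with the planted ground truth used by the
#' parameter-recovery tests. See [sim_config()] for the generative model.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `datasets` (named list of `count_dataset`, one
#'   per tissue) and `truth` (a `ground_truth` list: per-tissue planted DEG
#'   sets with true log2FC, reversed sets, module memberships and latent
#'   factors, plus the cross-tissue module pairs).
#' @examples
#' sim <- simulate_study(sim_config(tissues = "Liver", n_genes_per_tissue = 50,
#'                                  n_animals_per_group = 3,
#'                                  n_modules_per_tissue = 1,
#'                                  module_size_range = c(5, 8),
#'                                  n_cross_tissue_pairs = 0, seed = 7))
#' dim(sim$datasets$Liver$counts)
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)

  tissues <- config$tissues
  groups <- config$groups
  G <- config$n_genes_per_tissue
  n_per <- config$n_animals_per_group
  n_animals <- sum(n_per)
  animal_ids <- sprintf("A%03d", seq_len(n_animals))
  animal_group <- factor(rep(groups, times = n_per), levels = groups)
  gene_ids <- sprintf("g%05d", seq_len(G))
  gene_lengths <- setNames(pmax(round(rlnorm(G, log(1500), 0.6)), 200), gene_ids)

  K <- config$n_modules_per_tissue
  # latent module factors, one value per animal, iid N(0,1) before coupling
  latent <- lapply(tissues, function(t) {
    if (K == 0L) return(matrix(numeric(0), 0L, n_animals,
                               dimnames = list(NULL, animal_ids)))
    matrix(rnorm(K * n_animals), K, n_animals,
           dimnames = list(paste0("M", seq_len(K)), animal_ids))
  })
  names(latent) <- tissues

  # couple selected inter-tissue module pairs to the target correlation
  cross_pairs <- data.frame(tissue_a = character(0), module_a = character(0),
                            tissue_b = character(0), module_b = character(0),
                            target_corr = numeric(0))
  if (config$n_cross_tissue_pairs > 0) {
    free <- expand.grid(tissue = tissues, module = paste0("M", seq_len(K)),
                        stringsAsFactors = FALSE)
    r <- config$cross_module_corr
    for (i in seq_len(config$n_cross_tissue_pairs)) {
      ta <- sample(unique(free$tissue), 1L)
      ma <- sample(free$module[free$tissue == ta], 1L)
      free <- free[!(free$tissue == ta & free$module == ma), ]
      tb <- sample(setdiff(unique(free$tissue), ta), 1L)
      mb <- sample(free$module[free$tissue == tb], 1L)
      free <- free[!(free$tissue == tb & free$module == mb), ]
      z <- rnorm(n_animals)
      latent[[ta]][ma, ] <- sqrt(abs(r)) * z + sqrt(1 - abs(r)) * rnorm(n_animals)
      latent[[tb]][mb, ] <- sign(r) * sqrt(abs(r)) * z +
        sqrt(1 - abs(r)) * rnorm(n_animals)
      cross_pairs <- rbind(cross_pairs, data.frame(
        tissue_a = ta, module_a = ma, tissue_b = tb, module_b = mb,
        target_corr = r))
    }
  }

  truth <- list(tissues = list(), cross_pairs = cross_pairs, config = config)
  datasets <- list()
  sucrose <- groups[2]
  treat1 <- if (length(groups) >= 3) groups[3] else NULL
  treat2 <- if (length(groups) >= 4) groups[4] else NULL

  for (t in tissues) {
    mu0 <- setNames(rlnorm(G, config$baseline_meanlog, config$baseline_sdlog),
                    gene_ids)

    n_deg <- round(config$frac_sucrose_deg * G)
    deg <- sample(gene_ids, n_deg)
    n_up <- ceiling(n_deg / 2)
    up <- deg[seq_len(n_up)]
    down <- setdiff(deg, up)
    lfc <- setNames(pmax(rnorm(n_deg, config$lfc_location, config$lfc_scale),
                         0.25), deg)
    lfc[down] <- -lfc[down]
    rev_d1 <- sample(deg, round(config$reversal_frac_d1 * n_deg))
    rev_d2 <- sample(deg, round(config$reversal_frac_d2 * n_deg))

    # group-level means: sucrose applies the planted fold change; treated
    # groups return reversed genes to control baseline, others keep the effect
    grp_mu <- matrix(mu0, G, length(groups),
                     dimnames = list(gene_ids, groups))
    grp_mu[deg, sucrose] <- mu0[deg] * 2^lfc[deg]
    for (tg in c(treat1, treat2)) {
      reversed <- if (identical(tg, treat1)) rev_d1 else rev_d2
      keep_effect <- setdiff(deg, reversed)
      grp_mu[keep_effect, tg] <- grp_mu[keep_effect, sucrose]
      # reversed genes already equal the control baseline
    }

    # planted modules: disjoint gene blocks perturbed by their latent factor
    membership <- character(0)
    if (K > 0L) {
      size_pool <- seq(config$module_size_range[1], config$module_size_range[2])
      sizes <- size_pool[sample.int(length(size_pool), K, replace = TRUE)]
      pool <- sample(gene_ids, sum(sizes))
      membership <- setNames(rep(paste0("M", seq_len(K)), times = sizes), pool)
    }

    mu <- grp_mu[, as.integer(animal_group), drop = FALSE]
    colnames(mu) <- animal_ids
    if (length(membership) > 0L) {
      fac <- latent[[t]][membership, , drop = FALSE]  # gene x animal
      mu[names(membership), ] <- mu[names(membership), , drop = FALSE] *
        2^(config$module_loading * fac)
    }
    lib <- exp(rnorm(n_animals, 0, config$libsize_log_sd))
    mu <- sweep(mu, 2, lib, "*")
    phi <- pmax(config$dispersion_a0 / mu + config$dispersion_a1, 1e-8)
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / phi),
                     nrow = G, dimnames = dimnames(mu))
    storage.mode(counts) <- "integer"
    sample_ids <- paste(t, animal_ids, sep = "_")
    colnames(counts) <- sample_ids

    datasets[[t]] <- new_count_dataset(
      counts = counts, gene_ids = gene_ids, gene_lengths = gene_lengths,
      sample_ids = sample_ids, animal_ids = animal_ids,
      group = animal_group, tissue = t)
    truth$tissues[[t]] <- list(
      deg_up = lfc[up], deg_down = lfc[down],
      reversed_d1 = rev_d1, reversed_d2 = rev_d2,
      module_membership = membership,
      latent_factors = latent[[t]])
  }
  class(truth) <- "ground_truth"
  list(datasets = datasets, truth = truth)
}

new_count_dataset <- function(counts, gene_ids, gene_lengths, sample_ids,
                              animal_ids, group, tissue) {
  check_count_matrix(counts)
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique", call. = FALSE)
  stopifnot(length(sample_ids) == ncol(counts),
            length(gene_ids) == nrow(counts),
            length(animal_ids) == length(sample_ids),
            length(group) == length(sample_ids))
  structure(list(counts = counts, gene_ids = gene_ids,
                 gene_lengths = gene_lengths, sample_ids = sample_ids,
                 animal_ids = animal_ids, group = group, tissue = tissue),
            class = "count_dataset")
}

#' @export
print.count_dataset <- function(x, ...) {
  cat("count_dataset:", x$tissue, "-", nrow(x$counts), "genes x",
      ncol(x$counts), "samples\n")
  cat("groups:", paste(sprintf("%s (n=%d)", levels(x$group),
                               tabulate(x$group)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", length(x$tissues), "tissues\n")
  for (t in names(x$tissues)) {
    tt <- x$tissues[[t]]
    cat(sprintf("  %s: %d up / %d down planted DEGs, %d reversed (D1), %d modules\n",
                t, length(tt$deg_up), length(tt$deg_down),
                length(tt$reversed_d1),
                length(unique(tt$module_membership))))
  }
  if (nrow(x$cross_pairs))
    cat("cross-tissue pairs:",
        paste(sprintf("%s.%s~%s.%s (r=%.2f)", x$cross_pairs$tissue_a,
                      x$cross_pairs$module_a, x$cross_pairs$tissue_b,
                      x$cross_pairs$module_b, x$cross_pairs$target_corr),
              collapse = ", "), "\n")
  invisible(x)
}

#' Write a count dataset to tab-separated files
#'
#' Writes `<tissue>_counts.tsv` (genes as rows, header = sample ids),
#' `<tissue>_metadata.tsv` (sample_id, animal_id, tissue, group) and
#' `<tissue>_gene_lengths.tsv` (gene_id, length_bp) into `out_dir`.
#' [read_dataset()] reproduces the dataset exactly from these files.
#'
#' @param ds a `count_dataset`.
#' @param out_dir writable directory; created if absent.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(ds, out_dir) {
  stopifnot(inherits(ds, "count_dataset"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  if (file.access(out_dir, mode = 2L) != 0L)
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  paths <- file.path(out_dir, paste0(ds$tissue, c("_counts.tsv",
                                                  "_metadata.tsv",
                                                  "_gene_lengths.tsv")))
  cnt <- data.frame(gene_id = ds$gene_ids, ds$counts, check.names = FALSE)
  write.table(cnt, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = ds$sample_ids, animal_id = ds$animal_ids,
                     tissue = ds$tissue, group = as.character(ds$group))
  write.table(meta, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  len <- data.frame(gene_id = ds$gene_ids,
                    length_bp = unname(ds$gene_lengths[ds$gene_ids]))
  write.table(len, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a count dataset written by [write_dataset()]
#'
#' @param dir directory holding the three TSV files.
#' @param tissue tissue label (file prefix).
#' @param groups optional ordered group levels; defaults to order of appearance.
#' @return a `count_dataset`.
#' @export
read_dataset <- function(dir, tissue, groups = NULL) {
  pfx <- file.path(dir, tissue)
  for (s in c("_counts.tsv", "_metadata.tsv", "_gene_lengths.tsv"))
    if (!file.exists(paste0(pfx, s)))
      stop("missing dataset file: ", paste0(pfx, s), call. = FALSE)
  cnt <- read.delim(paste0(pfx, "_counts.tsv"), check.names = FALSE)
  meta <- read.delim(paste0(pfx, "_metadata.tsv"), colClasses = "character")
  len <- read.delim(paste0(pfx, "_gene_lengths.tsv"))
  counts <- as.matrix(cnt[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- cnt$gene_id
  lv <- groups %||% unique(meta$group)
  new_count_dataset(counts = counts, gene_ids = cnt$gene_id,
                    gene_lengths = setNames(as.numeric(len$length_bp), len$gene_id),
                    sample_ids = meta$sample_id, animal_ids = meta$animal_id,
                    group = factor(meta$group, levels = lv), tissue = tissue)
}

#' Write planted ground truth to JSON
#'
#' @param truth a `ground_truth` object from [simulate_study()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  out <- list(
    cross_pairs = truth$cross_pairs,
    tissues = lapply(truth$tissues, function(tt) list(
      deg_up = as.list(tt$deg_up), deg_down = as.list(tt$deg_down),
      reversed_d1 = tt$reversed_d1, reversed_d2 = tt$reversed_d2,
      module_membership = as.list(tt$module_membership),
      latent_factors = tt$latent_factors)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
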