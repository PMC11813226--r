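# Shared fixture builders; everything is generated in code at test time.

# Small two-group count dataset with optional planted fold changes.
tiny_dataset <- function(n_genes = 60, n_per_group = 5,
                         groups = c("control", "sucrose"),
                         mu = 100, phi = 0.05, planted = NULL, seed = 1,
                         tissue = "Liver") {
  set.seed(seed)
  n <- n_per_group * length(groups)
  grp <- factor(rep(groups, each = n_per_group), levels = groups)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  m <- matrix(mu, n_genes, n, dimnames = list(gene_ids, NULL))
  if (!is.null(planted)) {
    for (g in names(planted))
      m[g, grp == groups[2]] <- mu * 2^planted[[g]]
  }
  counts <- matrix(rnbinom(length(m), mu = m, size = 1 / phi),
                   n_genes, n)
  storage.mode(counts) <- "integer"
  sample_ids <- sprintf("%s_s%02d", tissue, seq_len(n))
  dimnames(counts) <- list(gene_ids, sample_ids)
  structure(list(counts = counts, gene_ids = gene_ids,
                 gene_lengths = setNames(rep(1000, n_genes), gene_ids),
                 sample_ids = sample_ids,
                 animal_ids = sprintf("A%02d", seq_len(n)),
                 group = grp, tissue = tissue),
            class = "count_dataset")
}

# Independent step-up BH oracle: sort descending, cumulative minimum of
# p * n / rank, capped at 1, mapped back to input order.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[ord] * n / seq(n, 1)))
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Exhaustive hypergeometric upper-tail oracle: enumerate every size-n draw
# from 1..N with category 1..K and count overlaps of at least k.
hyper_oracle <- function(k, K, n, N) {
  if (n == 0L) return(as.numeric(k == 0))
  draws <- utils::combn(N, n)
  ov <- colSums(draws <= K)
  mean(ov >= k)
}

# Exact two-sided Wilcoxon rank-sum oracle by enumeration of group
# assignments (no ties assumed).
wilcox_oracle <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(length(pooled), n1)
  w_all <- apply(sets, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# Planted-module expression fixture: modules of expressed genes driven by
# per-sample latent factors on a log2 scale.
planted_module_dataset <- function(n_modules = 3, module_size = 50,
                                   loading = 0.9, n_samples = 40, seed = 1,
                                   n_noise_genes = 0) {
  cfg <- sim_config(tissues = "Liver",
                    n_genes_per_tissue = n_modules * module_size + n_noise_genes,
                    n_animals_per_group = n_samples / 4,
                    frac_sucrose_deg = 0,
                    n_modules_per_tissue = n_modules,
                    module_size_range = c(module_size, module_size),
                    module_loading = loading,
                    n_cross_tissue_pairs = 0,
                    baseline_sdlog = 0.5,
                    seed = seed)
  sim <- simulate_study(cfg)
  list(ds = sim$datasets$Liver, truth = sim$truth$tissues$Liver)
}

# log-expression matrix for network construction
log_tpm <- function(ds) {
  log2(tpm(ds$counts, ds$gene_lengths) + 1)
}
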