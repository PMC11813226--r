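test_that("low-expression filter keeps the boundary and errors when empty", {
  m <- rbind(zero = c(0, 0, 0), boundary = c(1, 1, 1), high = c(9, 9, 9),
             low = c(0.5, 0.5, 0.5))
  colnames(m) <- paste0("s", 1:3)
  expect_setequal(filter_low_expression(m), c("boundary", "high"))
  expect_equal(filter_low_expression(m, threshold = 0.4),
               c("boundary", "high", "low"))
  expect_error(filter_low_expression(m, threshold = 100), "threshold")

  # direct mean-threshold oracle on random data
  set.seed(20)
  r <- matrix(rexp(600), 60, 10, dimnames = list(sprintf("g%02d", 1:60), NULL))
  expect_setequal(filter_low_expression(r, 1),
                  rownames(r)[rowMeans(r) >= 1])
})

test_that("a perfectly correlated pair survives the network cut", {
  set.seed(21)
  n <- 20
  base <- rnorm(n)
  expr <- rbind(a = base, b = 2 * base + 5,
                matrix(rnorm(10 * n), 10, n,
                       dimnames = list(paste0("noise", 1:10), NULL)))
  colnames(expr) <- paste0("s", 1:n)
  net <- build_network(expr, fdr = 0.05, top_frac = 0.5)
  ab <- net$edges[net$edges$gene_i == "a" & net$edges$gene_j == "b", ]
  expect_equal(nrow(ab), 1)
  expect_equal(ab$rho, 1)
  expect_true(all(net$edges$rho > 0))
  expect_true(all(net$edges$q < 0.05))
})

test_that("independent noise yields an essentially empty network", {
  set.seed(22)
  expr <- matrix(rnorm(60 * 10), 60, 10,
                 dimnames = list(sprintf("g%02d", 1:60), paste0("s", 1:10)))
  net <- build_network(expr)
  expect_lte(nrow(net$edges), 2)
})

test_that("network construction is rank-invariant and order-invariant", {
  set.seed(23)
  sim <- planted_module_dataset(n_modules = 2, module_size = 10,
                                n_samples = 16, seed = 23)
  expr <- log_tpm(sim$ds)
  net1 <- build_network(expr)
  # monotone transform leaves Spearman edges untouched
  net2 <- build_network(exp(expr / 4))
  expect_equal(net1$edges, net2$edges)
  # permuting samples changes nothing
  net3 <- build_network(expr[, sample(ncol(expr))])
  expect_equal(net1$edges, net3$edges)
})

test_that("constant genes are excluded from pair testing and counted", {
  set.seed(24)
  expr <- matrix(rnorm(8 * 10), 8, 10,
                 dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  expr[1, ] <- 3
  net <- build_network(expr)
  expect_equal(net$n_constant_excluded, 7)
  expect_equal(net$n_tested_pairs, choose(8, 2) - 7)
})

test_that("planted modules dominate the retained edge set", {
  sim <- planted_module_dataset(n_modules = 3, module_size = 50,
                                loading = 0.9, n_samples = 40, seed = 25)
  net <- build_network(log_tpm(sim$ds))
  memb <- sim$truth$module_membership
  same <- memb[net$edges$gene_i] == memb[net$edges$gene_j]
  expect_gte(mean(same, na.rm = TRUE), 0.9)
})

test_that("module detection resolves disjoint cliques and applies the size filter", {
  clique_net <- function(sets) {
    edges <- do.call(rbind, lapply(sets, function(g) {
      pairs <- t(utils::combn(sort(g), 2))
      data.frame(gene_i = pairs[, 1], gene_j = pairs[, 2], rho = 0.9,
                 p = 1e-8, q = 1e-6)
    }))
    structure(list(nodes = unlist(sets), edges = edges, tissue = "Liver",
                   n_tested_pairs = nrow(edges), n_candidates = nrow(edges),
                   n_constant_excluded = 0, fdr = 0.05, top_frac = 1),
              class = "coexpr_network")
  }
  genes_a <- sprintf("a%02d", 1:40)
  genes_b <- sprintf("b%02d", 1:40)
  set.seed(26)
  expr <- matrix(rnorm(80 * 12), 80, 12,
                 dimnames = list(c(genes_a, genes_b), paste0("s", 1:12)))
  mods <- detect_modules(clique_net(list(genes_a, genes_b)), expr,
                         min_size = 30, seed = 1)
  expect_length(mods$modules, 2)
  expect_setequal(mods$modules[[1]]$genes, genes_a)  # M0 ties broken stably
  expect_setequal(mods$modules[[2]]$genes, genes_b)
  expect_equal(names(mods$modules), c("Liver.M0", "Liver.M1"))

  # communities below the size floor are discarded to unassigned
  small_a <- sprintf("a%02d", 1:10)
  small_b <- sprintf("b%02d", 1:10)
  expr_s <- expr[c(small_a, small_b), ]
  mods_s <- detect_modules(clique_net(list(small_a, small_b)), expr_s,
                           min_size = 30, seed = 1)
  expect_length(mods_s$modules, 0)
  expect_setequal(mods_s$unassigned, c(small_a, small_b))

  # partition bookkeeping: module sizes plus unassigned cover all nodes
  expect_equal(length(unlist(lapply(mods$modules, `[[`, "genes"))) +
                 length(mods$unassigned), length(c(genes_a, genes_b)))
})

test_that("eigengene matches an independent decomposition and its conventions", {
  set.seed(27)
  expr <- matrix(rnorm(8 * 12), 8, 12,
                 dimnames = list(paste0("g", 1:8), paste0("s", 1:12)))
  eg <- eigengene(expr)
  std <- t(scale(t(expr)))
  oracle <- svd(std)$v[, 1]
  expect_equal(abs(sum(eg$eigengene * oracle)), 1, tolerance = 1e-10)
  expect_equal(sum(eg$eigengene^2), 1)
  expect_gte(cor(eg$eigengene, colMeans(std)), 0)

  # identical profiles: variance fully explained, eigengene tracks the profile
  prof <- rnorm(12)
  rep_mat <- matrix(rep(prof, each = 5), 5, 12,
                    dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  eg1 <- eigengene(rep_mat)
  expect_equal(eg1$var_explained, 1)
  expect_equal(abs(cor(eg1$eigengene, prof)), 1)

  # sign convention survives wholesale negation
  eg_neg <- eigengene(-expr)
  expect_gte(cor(eg_neg$eigengene, colMeans(t(scale(t(-expr))))), 0)

  expect_error(eigengene(matrix(1, 4, 5)), "constant")
})

test_that("module-DEG enrichment flags planted dual patterns", {
  set.seed(28)
  universe <- sprintf("g%03d", 1:400)
  mod_genes <- universe[1:40]
  other <- universe[301:340]
  mods <- structure(list(modules = list(
    M0 = list(id = "M0", genes = mod_genes, eigengene = NULL,
              var_explained = 0.5),
    M1 = list(id = "M1", genes = other, eigengene = NULL,
              var_explained = 0.5)),
    unassigned = character(0), tissue = NULL, sample_ids = NULL,
    animal_ids = NULL, min_size = 30, seed = 1), class = "module_set")
  degs <- list(
    sucrose = deg_sets(up = universe[1:50], down = universe[101:120],
                       background_n = 400),
    D1 = deg_sets(up = universe[201:210], down = universe[11:60],
                  background_n = 400))
  enr <- module_deg_enrichment(mods, degs, background_n = 400)
  pat <- module_patterns(enr)
  expect_equal(pat$pattern[pat$module == "M0"], "intervention_up.treatment_down")
  expect_equal(pat$pattern[pat$module == "M1"], "none")
  # maximal overlap gives the smallest p in its row block
  copy <- module_deg_enrichment(
    structure(list(modules = list(M = list(id = "M", genes = universe[1:50])),
                   unassigned = character(0)), class = "module_set"),
    degs, background_n = 400)
  expect_equal(copy$p[copy$contrast == "sucrose" & copy$direction == "up"],
               hypergeom_overlap(50, 50, 50, 400))
})

test_that("cross-tissue eigengene correlation pairs by animal", {
  set.seed(29)
  animals <- sprintf("A%02d", 1:20)
  eg <- rnorm(20); eg <- eg / sqrt(sum(eg^2))
  mk <- function(tissue, egs) structure(list(
    modules = lapply(seq_along(egs), function(i)
      list(id = paste0(tissue, ".M", i - 1), genes = paste0("g", 1:30),
           eigengene = setNames(egs[[i]], paste0(tissue, "_", animals)),
           var_explained = 0.5)),
    unassigned = character(0), tissue = tissue,
    sample_ids = paste0(tissue, "_", animals), animal_ids = animals,
    min_size = 30, seed = 1), class = "module_set")
  a <- mk("Liver", list(eg))
  b <- mk("SkM", list(eg, rnorm(20)))
  got <- cross_tissue_module_correlation(a, b)
  dup <- got[got$module_b == "SkM.M0", ]
  expect_equal(dup$R, 1)
  expect_true(dup$significant)

  expect_error(cross_tissue_module_correlation(a, a), "different tissues")
  b2 <- mk("SkM", list(eg))
  b2$animal_ids <- sprintf("B%02d", 1:20)
  expect_error(cross_tissue_module_correlation(a, b2), "shared animals")
})
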