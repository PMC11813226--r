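test_that("size factors match closed forms and a literal re-computation", {
  # identical columns are symmetric
  m <- matrix(rpois(300, 50), 50, 6,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:6)))
  same <- m[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_equal(unname(size_factors(same)), rep(1, 3))

  # doubling one sample splits the ratio symmetrically around 1
  two <- cbind(s1 = m[, 1], s2 = 2L * m[, 1])
  expect_equal(unname(size_factors(two)), c(1 / sqrt(2), sqrt(2)))

  # random matrix against the direct formula written out independently
  set.seed(8)
  r <- matrix(rpois(300, 30) + 1L, 50, 6,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:6)))
  ref <- apply(r, 1, function(x) exp(mean(log(x))))
  oracle <- apply(r, 2, function(col) median(col / ref))
  expect_equal(size_factors(r), oracle)

  # no all-positive gene suggests the fallback
  z <- diag(5); rownames(z) <- paste0("g", 1:5); colnames(z) <- paste0("s", 1:5)
  expect_error(size_factors(z), "pseudo-reference")
})

test_that("identical groups yield null fold changes and unit p-values", {
  ds <- tiny_dataset(n_genes = 40, n_per_group = 4, seed = 2)
  ds$counts[, ds$group == "sucrose"] <- ds$counts[, ds$group == "control"]
  fit <- nb_wald_contrast(ds, c("sucrose", "control"))
  expect_equal(fit$result$log2fc, rep(0, nrow(fit$result)))
  expect_equal(fit$result$p, rep(1, nrow(fit$result)))
  expect_length(fit$degs$up, 0)
  expect_length(fit$degs$down, 0)
})

test_that("contrast result keeps its internal Wald identity and contracts", {
  ds <- tiny_dataset(n_genes = 80, seed = 3)
  ds$counts[5, ] <- 0L  # all-zero gene must be excluded and recorded
  fit <- nb_wald_contrast(ds, c("sucrose", "control"))
  res <- fit$result
  expect_equal(abs(res$wald_z), abs(res$log2fc * log(2)) / res$se)
  expect_equal(attr(res, "excluded_genes"), "g0005")
  expect_false("g0005" %in% res$gene_id)
  expect_error(nb_wald_contrast(ds, c("sucrose", "absent")), "absent")
  expect_error(contrast_spec("a", "a"), "distinct")
})

test_that("planted effects are detected with high power and little bias", {
  # balanced up/down planting, as the simulator produces; an unbalanced
  # panel would shift the median-of-ratios reference by composition
  up <- sprintf("g%04d", 1:30)
  down <- sprintf("g%04d", 31:60)
  planted <- c(setNames(rep(2, 30), up), setNames(rep(-2, 30), down))
  ds <- tiny_dataset(n_genes = 400, n_per_group = 10, mu = 100, phi = 0.05,
                     planted = as.list(planted), seed = 11)
  fit <- nb_wald_contrast(ds, c("sucrose", "control"), alpha = 0.01)
  expect_gt(length(intersect(up, fit$degs$up)) / 30, 0.9)
  expect_gt(length(intersect(down, fit$degs$down)) / 30, 0.9)
  est_up <- fit$result$log2fc[match(up, fit$result$gene_id)]
  expect_lt(abs(mean(est_up) - 2), 3 * sd(est_up) / sqrt(30))
  est_down <- fit$result$log2fc[match(down, fit$result$gene_id)]
  expect_lt(abs(mean(est_down) + 2), 3 * sd(est_down) / sqrt(30))
})

test_that("DEG calls ignore sample and gene ordering", {
  ds <- tiny_dataset(n_genes = 100, n_per_group = 6, seed = 4,
                     planted = list(g0001 = 1.5, g0002 = -1.5))
  fit <- nb_wald_contrast(ds, c("sucrose", "control"), alpha = 0.05)
  perm_s <- sample(ncol(ds$counts))
  perm_g <- sample(nrow(ds$counts))
  ds2 <- ds
  ds2$counts <- ds$counts[perm_g, perm_s]
  ds2$group <- ds$group[perm_s]
  ds2$sample_ids <- ds$sample_ids[perm_s]
  ds2$animal_ids <- ds$animal_ids[perm_s]
  ds2$gene_ids <- ds$gene_ids[perm_g]
  fit2 <- nb_wald_contrast(ds2, c("sucrose", "control"), alpha = 0.05)
  expect_setequal(fit$degs$up, fit2$degs$up)
  expect_setequal(fit$degs$down, fit2$degs$down)
})

test_that("TPM normalizes lengths and columns", {
  single <- matrix(5, 1, 2, dimnames = list("g1", c("a", "b")))
  expect_equal(unname(tpm(single, 500)), matrix(1e6, 1, 2))

  eq <- matrix(7, 10, 3, dimnames = list(paste0("g", 1:10), paste0("s", 1:3)))
  expect_true(all(abs(tpm(eq, rep(800, 10)) - 1e5) < 1e-9))

  # hand-computed three-gene case: rates 10/1, 20/2, 30/0.5 = 10, 10, 60
  counts <- matrix(c(10, 20, 30), 3, 1, dimnames = list(paste0("g", 1:3), "s"))
  got <- tpm(counts, c(1000, 2000, 500))
  expect_equal(unname(got[, 1]), 1e6 * c(10, 10, 60) / 80)
  expect_equal(colSums(got), c(s = 1e6))

  expect_error(tpm(counts, c(1000, 0, 500)), "positive")
})

test_that("VST surrogate is a shifted log and monotone in counts", {
  m <- matrix(c(0, 1, 7), 3, 1, dimnames = list(paste0("g", 1:3), "s"))
  got <- vst_surrogate(m, sf = 1)
  expect_equal(unname(got[, 1]), log2(c(0, 1, 7) + 1))
  set.seed(5)
  x <- matrix(sort(rpois(50, 20)), 50, 1,
              dimnames = list(sprintf("g%02d", 1:50), "s"))
  expect_true(all(diff(vst_surrogate(x, sf = 2.3)[, 1]) >= 0))
})

test_that("PCA coordinates agree with prcomp and expose rank", {
  set.seed(6)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  pc <- pca_coords(m, n_components = 4)
  oracle <- prcomp(t(m), center = TRUE, scale. = FALSE)
  for (j in 1:4) {
    agree <- max(abs(pc$coords[, j] - oracle$x[, j]),
                 abs(pc$coords[, j] + oracle$x[, j]))
    expect_equal(min(abs(pc$coords[, j] - oracle$x[, j]),
                     abs(pc$coords[, j] + oracle$x[, j])), 0,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_true(all(diff(pc$var_fraction) <= 1e-12))

  # duplicated samples land on identical coordinates
  dup <- m[, c(1, 1, 2, 3)]
  colnames(dup) <- paste0("s", 1:4)
  cd <- pca_coords(dup, 2)$coords
  expect_equal(cd[1, ], cd[2, ])

  # rank-1 input concentrates all variance on PC1
  r1 <- outer(rnorm(20), rnorm(6))
  dimnames(r1) <- list(paste0("g", 1:20), paste0("s", 1:6))
  expect_equal(pca_coords(r1, 1)$var_fraction[1], 1)
  expect_warning(pca_coords(r1, 5), "rank")
})

test_that("BH adjustment equals the step-up oracle", {
  set.seed(7)
  for (i in 1:25) {
    p <- runif(sample(1:60, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})
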