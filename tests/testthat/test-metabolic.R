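test_that("model JSON parses, validates and round-trips", {
  fixture <- system.file("extdata", "linear_pathway.json", package = "crossnet")
  model <- read_metabolic_model(fixture)
  expect_equal(nrow(model$reactions), 3)
  expect_equal(sum(!vapply(model$gpr_ast, is.null, TRUE)), 1)
  expect_equal(model$S["A", "R_AB"], -1)

  out <- withr::local_tempfile(fileext = ".json")
  write_metabolic_model(model, out)
  back <- read_metabolic_model(out)
  expect_equal(back$S, model$S)
  expect_equal(back$reactions, model$reactions)

  # unknown metabolite names the offending reaction
  expect_error(
    metabolic_model(c("A"), data.frame(id = "R1", lower_bound = 0,
                                       upper_bound = 1, subsystem = "x",
                                       gpr = NA),
                    list(R1 = c(A = -1, GHOST = 1))),
    "R1.*GHOST")
  expect_error(
    metabolic_model(c("A"), data.frame(id = "R1", lower_bound = 2,
                                       upper_bound = 1, subsystem = "x",
                                       gpr = NA),
                    list(R1 = c(A = 1))),
    "lower <= upper")
})

test_that("GPR rules follow AND=min / OR=sum semantics", {
  m <- example_metabolic_model()
  expr <- matrix(c(5, 2, 7, 1, 3, 4, 5, 2, 1, 6, 9), 11, 1,
                 dimnames = list(paste0("g", 1:11), "s1"))
  re <- reaction_expression(m, expr)
  expect_equal(re["R1", 1], 5)                 # single gene
  expect_equal(re["R2", 1], min(2, 7))         # AND
  expect_equal(re["R3", 1], 1 + 3)             # OR
  expect_equal(re["R5", 1], min(5, 2) + 1)     # (g7 AND g8) OR g9 = 3
  expect_true(is.na(re["EX_A", 1]))            # unassociated

  # missing gene counts as zero with a warning
  short <- expr[1:10, , drop = FALSE]
  expect_warning(re2 <- reaction_expression(m, short), "g11")
  expect_equal(re2["R_DEAD", 1], 0)
})

test_that("malformed GPR rules fail with a position", {
  expect_error(parse_gpr("g1 AND"), "expected a gene id")
  expect_error(parse_gpr("(g1 OR g2"), "expected '\\)'")
  expect_error(parse_gpr("g1 g2"), "trailing")
  expect_error(parse_gpr("AND g1"), "expected a gene id")
  # parse structure of a nested rule
  ast <- parse_gpr("(g1 AND g2) OR g3")
  expect_equal(ast$op, "OR")
  expect_equal(ast$args[[1]]$op, "AND")
  expect_equal(ast$args[[2]]$gene, "g3")
})

test_that("the linear pathway reproduces the hand-solved optimum", {
  model <- linear_pathway_model("g1")
  expr <- matrix(9, 1, 1, dimnames = list("g1", "s1"))
  sc <- compass_scores(model, reaction_expression(model, expr), w = 0.95)
  # max flux 10; forced flux 9.5 through the one penalized reaction at
  # penalty 1/(1+9): optimal total penalty = 9.5 * 0.1
  expect_equal(unname(sc$vmax["R_AB"]), 10, tolerance = 1e-9)
  expect_equal(sc$penalties["R_AB", 1], 0.95, tolerance = 1e-6)
  expect_equal(sc$scores["R_AB", 1], -log(0.95 + 1e-10), tolerance = 1e-6)
})

test_that("raising a reaction's own expression never lowers its score", {
  model <- linear_pathway_model("g1")
  pen <- vapply(seq(0, 18, by = 2), function(e) {
    expr <- matrix(e, 1, 1, dimnames = list("g1", "s1"))
    compass_scores(model, reaction_expression(model, expr))$penalties["R_AB", 1]
  }, 0)
  expect_true(all(diff(pen) <= 1e-9))
})

test_that("dead-end reactions are flagged blocked and not scored", {
  m <- example_metabolic_model()
  set.seed(31)
  expr <- matrix(runif(22, 1, 10), 11, 2,
                 dimnames = list(paste0("g", 1:11), c("s1", "s2")))
  sc <- compass_scores(m, reaction_expression(m, expr))
  expect_true(sc$blocked["R_DEAD"])
  expect_true(all(is.na(sc$scores["R_DEAD", ])))
  expect_false(any(sc$blocked[setdiff(names(sc$blocked), "R_DEAD")]))
  expect_true(all(is.finite(sc$scores[!sc$blocked, ])))
})

test_that("bound scaling shifts scores by the implied log factor", {
  model <- linear_pathway_model("g1")
  expr <- matrix(4, 1, 1, dimnames = list("g1", "s1"))
  base <- compass_scores(model, reaction_expression(model, expr), epsilon = 0)
  scaled_model <- model
  scaled_model$reactions$lower_bound <- model$reactions$lower_bound * 3
  scaled_model$reactions$upper_bound <- model$reactions$upper_bound * 3
  scaled <- compass_scores(scaled_model, reaction_expression(model, expr),
                           epsilon = 0)
  expect_equal(scaled$scores["R_AB", 1], base$scores["R_AB", 1] - log(3),
               tolerance = 1e-8)
})

test_that("differential activity matches closed forms and enumeration", {
  mat <- rbind(r1 = c(1, 2, 3, 3, 4, 5), r2 = rep(2, 6))
  colnames(mat) <- paste0("s", 1:6)
  groups <- rep(c("a", "b"), each = 3)
  da <- differential_activity(mat, groups, c("a", "b"))
  expect_equal(da$cohens_d[da$reaction == "r1"], -2)
  expect_equal(da$cohens_d[da$reaction == "r2"], 0)
  expect_equal(da$p[da$reaction == "r2"], 1)
  expect_equal(da$sign, c("-", "0"))

  # exact Wilcoxon p equals enumeration over assignments at small n
  set.seed(32)
  for (sizes in list(c(3, 3), c(4, 5), c(6, 6))) {
    x <- rnorm(sizes[1]); y <- rnorm(sizes[2]) + 0.5
    mat2 <- matrix(c(x, y), 1, dimnames = list("r", NULL))
    colnames(mat2) <- paste0("s", seq_len(sum(sizes)))
    da2 <- differential_activity(mat2, rep(c("a", "b"), sizes), c("a", "b"))
    expect_equal(da2$p, wilcox_oracle(x, y),
                 info = paste(sizes, collapse = "x"))
  }
})

test_that("identical groups produce no differential activity", {
  set.seed(33)
  half <- matrix(rnorm(40), 10, 4)
  mat <- cbind(half, half)
  dimnames(mat) <- list(paste0("r", 1:10), paste0("s", 1:8))
  da <- differential_activity(mat, rep(c("a", "b"), each = 4), c("a", "b"))
  expect_equal(da$cohens_d, rep(0, 10), tolerance = 1e-12)
  expect_true(all(da$p > 0.99))
  expect_false(any(da$significant))
})

test_that("activity reversal accounting matches its definition", {
  d1 <- data.frame(reaction = paste0("r", 1:6),
                   subsystem = "x",
                   cohens_d = c(2, -2, 1.5, -1, 0.2, 1),
                   p = c(1e-5, 1e-5, 1e-4, 1e-4, 0.5, 0.9))
  d1$sign <- ifelse(d1$cohens_d > 0, "+", "-")
  d1$padj <- bh_adjust(d1$p)
  d1$significant <- d1$padj < 0.05
  class(d1) <- c("diff_activity", "data.frame")
  flip <- d1
  flip$cohens_d <- -d1$cohens_d
  flip$sign <- ifelse(flip$cohens_d > 0, "+", "-")
  rev <- reversal_of_activity(d1, flip)
  expect_equal(rev$fraction, 1)
  expect_setequal(rev$reversed_reactions, paste0("r", 1:4))

  none <- d1
  none$significant <- FALSE
  expect_true(is.na(reversal_of_activity(none, flip)$fraction))
  bad <- d1
  bad$reaction <- paste0("q", 1:6)
  expect_error(reversal_of_activity(d1, bad), "universes")
})

test_that("subsystem summary counts significant reactions by direction", {
  d <- data.frame(reaction = paste0("r", 1:5),
                  subsystem = c("tca", "tca", "fa", "fa", "fa"),
                  cohens_d = c(1, -1, 2, 2, -3),
                  p = c(1e-6, 1e-6, 1e-6, 0.9, 1e-6))
  d$sign <- ifelse(d$cohens_d > 0, "+", "-")
  d$padj <- bh_adjust(d$p)
  d$significant <- d$padj < 0.05
  class(d) <- c("diff_activity", "data.frame")
  s <- subsystem_summary(d)
  expect_equal(s$n[s$subsystem == "fa" & s$sign == "+"], 1)
  expect_equal(s$n[s$subsystem == "fa" & s$sign == "-"], 1)
  expect_equal(s$n[s$subsystem == "tca" & s$sign == "+"], 1)
})
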