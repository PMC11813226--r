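#' Construct a small stoichiometric metabolic model
#'
#' @param metabolites character vector of metabolite ids.
#' @param reactions data frame with columns `id`, `lower_bound`,
#'   `upper_bound`, `subsystem` and optionally `gpr` (boolean gene rule text;
#'   `NA` or `""` for reactions without gene association).
#' @param stoichiometry named list (by reaction id) of named numeric vectors
#'   (metabolite -> coefficient; negative = consumed).
#' @return a validated `metabolic_model`: the inputs plus `S` (dense
#'   stoichiometric matrix, metabolites x reactions) and `gpr_ast` (parsed
#'   AND/OR trees, `NULL` where unassociated).
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry) {
  stopifnot(is.character(metabolites), !anyDuplicated(metabolites),
            is.data.frame(reactions), !anyDuplicated(reactions$id))
  need <- c("id", "lower_bound", "upper_bound", "subsystem")
  if (!all(need %in% names(reactions)))
    stop("`reactions` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(reactions$gpr)) reactions$gpr <- NA_character_
  if (any(reactions$lower_bound > reactions$upper_bound))
    stop("reaction bounds must satisfy lower <= upper", call. = FALSE)
  if (any(is.na(reactions$subsystem) | !nzchar(reactions$subsystem)))
    stop("every reaction needs a nonempty subsystem label", call. = FALSE)
  S <- matrix(0, length(metabolites), nrow(reactions),
              dimnames = list(metabolites, reactions$id))
  for (rid in reactions$id) {
    st <- stoichiometry[[rid]]
    if (is.null(st)) stop("missing stoichiometry for reaction ", rid,
                          call. = FALSE)
    unknown <- setdiff(names(st), metabolites)
    if (length(unknown))
      stop("reaction ", rid, " references unknown metabolite(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    S[names(st), rid] <- as.numeric(st)
  }
  gpr_ast <- lapply(reactions$gpr, function(g) {
    if (is.na(g) || !nzchar(trimws(g))) NULL else parse_gpr(g)
  })
  names(gpr_ast) <- reactions$id
  structure(list(metabolites = metabolites, reactions = reactions,
                 stoichiometry = stoichiometry, S = S, gpr_ast = gpr_ast),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic_model: %d metabolites, %d reactions (%d gene-associated), %d subsystems\n",
              length(x$metabolites), nrow(x$reactions),
              sum(!vapply(x$gpr_ast, is.null, TRUE)),
              length(unique(x$reactions$subsystem))))
  invisible(x)
}

#' Read a metabolic model from JSON
#'
#' Schema (BiGG-style): top-level `metabolites` (list of `{id}`) and
#' `reactions` (list of `{id, stoichiometry: {met: coef}, lower_bound,
#' upper_bound, gpr, subsystem}`).
#'
#' @param path JSON file.
#' @return a `metabolic_model`.
#' @export
read_metabolic_model <- function(path) {
  if (!file.exists(path)) stop("cannot read model file: ", path, call. = FALSE)
  j <- jsonlite::read_json(path)
  mets <- vapply(j$metabolites, function(m) m$id, "")
  rx <- do.call(rbind, lapply(j$reactions, function(r) data.frame(
    id = r$id, lower_bound = as.numeric(r$lower_bound),
    upper_bound = as.numeric(r$upper_bound),
    subsystem = r$subsystem %||% "",
    gpr = if (is.null(r$gpr)) NA_character_ else as.character(r$gpr))))
  st <- lapply(j$reactions, function(r)
    unlist(lapply(r$stoichiometry, as.numeric)))
  names(st) <- rx$id
  metabolic_model(mets, rx, st)
}

#' Write a metabolic model to JSON
#'
#' @param model a `metabolic_model`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_metabolic_model <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  j <- list(
    metabolites = lapply(model$metabolites, function(m) list(id = m)),
    reactions = lapply(seq_len(nrow(model$reactions)), function(i) {
      r <- model$reactions[i, ]
      out <- list(id = r$id,
                  stoichiometry = as.list(model$stoichiometry[[r$id]]),
                  lower_bound = r$lower_bound, upper_bound = r$upper_bound,
                  subsystem = r$subsystem)
      if (!is.na(r$gpr)) out$gpr <- r$gpr
      out
    }))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# GPR parsing -------------------------------------------------------------

#' Parse a gene-protein-reaction boolean rule
#'
#' Grammar: `expr := term (OR term)*`, `term := factor (AND factor)*`,
#' `factor := '(' expr ')' | gene`. Keywords are case-insensitive; gene ids
#' may contain letters, digits, `_ . : -`.
#'
#' @param text rule text, e.g. `"(g1 AND g2) OR g3"`.
#' @return an AND/OR tree: `list(op = "AND"|"OR", args = list(...))` or
#'   `list(gene = id)`.
#' @export
parse_gpr <- function(text) {
  stopifnot(is_string(text))
  pat <- "\\(|\\)|[A-Za-z0-9_.:-]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1L) stop("empty GPR rule", call. = FALSE)
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  pos <- as.integer(m)
  stripped <- gsub(pat, "", text)
  if (grepl("[^[:space:]]", stripped))
    stop("invalid character(s) in GPR rule: '", text, "'", call. = FALSE)
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[i] else NA_character_
  take <- function() { t <- toks[i]; i <<- i + 1L; t }
  err <- function(msg) {
    at <- if (i <= length(toks)) paste0("at position ", pos[i]) else "at end of rule"
    stop("GPR parse error ", at, " in '", text, "': ", msg, call. = FALSE)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) err("expected a gene id or '('")
    if (t == "(") {
      take()
      e <- parse_expr()
      if (!identical(peek(), ")")) err("expected ')'")
      take()
      return(e)
    }
    if (t == ")" || toupper(t) %in% c("AND", "OR")) err("expected a gene id")
    list(gene = take())
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && toupper(peek()) == "AND") {
      take()
      args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1L) args[[1]] else list(op = "AND", args = args)
  }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && toupper(peek()) == "OR") {
      take()
      args[[length(args) + 1L]] <- parse_term()
    }
    if (length(args) == 1L) args[[1]] else list(op = "OR", args = args)
  }
  out <- parse_expr()
  if (!is.na(peek())) err("unexpected trailing token")
  out
}

eval_gpr <- function(ast, expr_vec, missing_genes) {
  if (!is.null(ast$gene)) {
    v <- expr_vec[ast$gene]
    if (is.na(v)) {
      missing_genes$add(ast$gene)
      return(0)
    }
    return(unname(v))
  }
  vals <- vapply(ast$args, eval_gpr, 0, expr_vec = expr_vec,
                 missing_genes = missing_genes)
  if (ast$op == "AND") min(vals) else sum(vals)
}

#' Resolve gene expression to reaction-level expression
#'
#' Evaluates each reaction's gene rule against per-sample expression: AND
#' takes the minimum of its operands (limiting subunit), OR the sum
#' (isoenzymes add capacity). Genes absent from `expr` contribute expression 0
#' (one warning lists them). Reactions without a rule get `NA` (unassociated).
#'
#' @param model a `metabolic_model`.
#' @param expr nonnegative gene x sample expression matrix with rownames.
#' @return reaction x sample matrix of reaction expression.
#' @export
reaction_expression <- function(model, expr) {
  stopifnot(inherits(model, "metabolic_model"), is.matrix(expr),
            !is.null(rownames(expr)))
  if (any(expr < 0)) stop("expression must be nonnegative", call. = FALSE)
  missed <- new.env()
  missed$genes <- character(0)
  tracker <- list(add = function(g) missed$genes <- union(missed$genes, g))
  out <- matrix(NA_real_, nrow(model$reactions), ncol(expr),
                dimnames = list(model$reactions$id, colnames(expr)))
  for (rid in model$reactions$id) {
    ast <- model$gpr_ast[[rid]]
    if (is.null(ast)) next
    for (s in seq_len(ncol(expr)))
      out[rid, s] <- eval_gpr(ast, setNames(expr[, s], rownames(expr)),
                              tracker)
  }
  if (length(missed$genes))
    warning("GPR gene(s) absent from expression matrix treated as 0: ",
            paste(sort(missed$genes), collapse = ", "))
  out
}

# LP machinery ------------------------------------------------------------

# Split-variable LP on the steady-state system: x = (forward, backward) >= 0,
# S(f - b) = 0, component bounds from the reaction bounds.
lp_parts <- function(model) {
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  R <- nrow(model$reactions)
  list(R = R,
       A3 = cbind(model$S, -model$S), b3 = rep(0, nrow(model$S)),
       fub = pmax(ub, 0), bub = pmax(-lb, 0),
       flb = pmax(lb, 0), blb = pmax(-ub, 0))
}

solve_split_lp <- function(parts, objective, maxi, extra_A2 = NULL,
                           extra_b2 = NULL) {
  R <- parts$R
  I <- diag(2 * R)
  A1 <- I
  b1 <- c(parts$fub, parts$bub)
  lower_rows <- which(c(parts$flb, parts$blb) > 0)
  A2 <- I[lower_rows, , drop = FALSE]
  b2 <- c(parts$flb, parts$blb)[lower_rows]
  if (!is.null(extra_A2)) {
    A2 <- rbind(A2, extra_A2)
    b2 <- c(b2, extra_b2)
  }
  res <- boot::simplex(a = objective, A1 = A1, b1 = b1,
                       A2 = if (nrow(A2)) A2 else NULL,
                       b2 = if (nrow(A2)) b2 else NULL,
                       A3 = parts$A3, b3 = parts$b3,
                       maxi = maxi, n.iter = 50 * (2 * R + length(parts$b3)),
                       eps = 1e-10)
  list(status = res$solved, value = res$value, solution = res$soln)
}

#' Reaction potential-activity scores
#'
#' A flux-balance-based score of how transcriptionally supported each
#' reaction's near-maximal flux is, computed per sample on a stoichiometric
#' model. Gene-associated reactions carry a penalty `1/(1 + reaction
#' expression)`; unassociated reactions carry zero penalty by default (they
#' contribute no expression evidence) or the sample's mean associated penalty
#' with `penalty_mode = "mean"`. For each reaction, a first LP maximizes its
#' flux subject to steady state (`S v = 0`) and bounds; reactions whose
#' maximum is at most `blocked_tol` are flagged blocked and not scored. A
#' second LP per sample minimizes the total penalty-weighted absolute flux
#' (reactions split into forward/backward parts) while forcing the reaction to
#' carry at least `w` of its maximum; the score is `-log(optimal penalty +
#' epsilon)`, larger meaning more active.
#'
#' @param model a `metabolic_model`.
#' @param rxn_expr reaction x sample expression from [reaction_expression()].
#' @param w fraction of maximal flux to sustain, in (0, 1\] (default 0.95).
#' @param epsilon additive offset inside the log (default 1e-10).
#' @param penalty_mode `"zero"` (default) or `"mean"` penalty for
#'   unassociated reactions.
#' @param blocked_tol flux below which a reaction counts as blocked.
#' @return a `reaction_scores` list: `scores` and `penalties` (reaction x
#'   sample; `NA` rows for blocked reactions), `vmax` per reaction, `blocked`
#'   logical vector, and `params`.
#' @export
compass_scores <- function(model, rxn_expr, w = 0.95, epsilon = 1e-10,
                           penalty_mode = c("zero", "mean"),
                           blocked_tol = 1e-6) {
  stopifnot(inherits(model, "metabolic_model"), is.matrix(rxn_expr))
  penalty_mode <- match.arg(penalty_mode)
  if (w <= 0 || w > 1) stop("`w` must lie in (0, 1]", call. = FALSE)
  rids <- model$reactions$id
  stopifnot(identical(rownames(rxn_expr), rids))
  parts <- lp_parts(model)
  R <- parts$R
  S_n <- ncol(rxn_expr)

  # per-sample penalties
  pen <- 1 / (1 + rxn_expr)
  unassoc <- vapply(model$gpr_ast, is.null, TRUE)
  if (penalty_mode == "zero") {
    pen[unassoc, ] <- 0
  } else {
    for (s in seq_len(S_n))
      pen[unassoc, s] <- mean(pen[!unassoc, s], na.rm = TRUE)
  }

  vmax <- setNames(numeric(R), rids)
  for (i in seq_len(R)) {
    obj <- numeric(2 * R)
    obj[i] <- 1; obj[R + i] <- -1
    sol <- solve_split_lp(parts, obj, maxi = TRUE)
    if (sol$status == -1)
      stop("flux maximization infeasible for reaction ", rids[i], call. = FALSE)
    if (sol$status != 1)
      stop("LP solver did not converge for reaction ", rids[i], call. = FALSE)
    vmax[i] <- sol$value
  }
  blocked <- vmax <= blocked_tol

  scores <- penalties <- matrix(NA_real_, R, S_n,
                                dimnames = list(rids, colnames(rxn_expr)))
  for (i in which(!blocked)) {
    target <- numeric(2 * R)
    target[i] <- 1; target[R + i] <- -1
    for (s in seq_len(S_n)) {
      obj <- c(pen[, s], pen[, s])
      sol <- solve_split_lp(parts, obj, maxi = FALSE,
                            extra_A2 = matrix(target, 1),
                            extra_b2 = w * vmax[i])
      if (sol$status == -1) {
        warning("penalty LP infeasible for reaction ", rids[i],
                " sample ", s, "; score left NA")
        next
      }
      if (sol$status != 1)
        stop("LP solver did not converge for reaction ", rids[i],
             " sample ", s, call. = FALSE)
      penalties[i, s] <- sol$value
      scores[i, s] <- -log(sol$value + epsilon)
    }
  }
  structure(list(scores = scores, penalties = penalties, vmax = vmax,
                 blocked = blocked,
                 params = list(w = w, epsilon = epsilon,
                               penalty_mode = penalty_mode,
                               blocked_tol = blocked_tol)),
            class = "reaction_scores")
}

#' @export
print.reaction_scores <- function(x, ...) {
  cat(sprintf("reaction_scores: %d reactions x %d samples (%d blocked), w = %g\n",
              nrow(x$scores), ncol(x$scores), sum(x$blocked), x$params$w))
  invisible(x)
}

#' Differential reaction activity between two groups
#'
#' Per reaction, a two-sided Wilcoxon rank-sum test on potential-activity
#' scores (exact when the smaller group has at most 10 samples and there are
#' no ties; normal approximation with continuity correction otherwise), BH
#' adjustment across reactions, and Cohen's d (mean difference over pooled
#' SD, numerator group minus denominator group).
#'
#' @param scores a `reaction_scores` object (or a reaction x sample matrix).
#' @param groups group label per sample (aligned with score columns).
#' @param contrast `c(numerator, denominator)` group labels or a
#'   [contrast_spec()].
#' @param model optional `metabolic_model` supplying subsystem labels.
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @return data frame (reaction, subsystem, cohens_d, sign, p, padj,
#'   significant), classed `diff_activity`; blocked reactions are omitted.
#' @export
differential_activity <- function(scores, groups, contrast, model = NULL,
                                  alpha = 0.05) {
  mat <- if (inherits(scores, "reaction_scores")) scores$scores else scores
  stopifnot(is.matrix(mat), length(groups) == ncol(mat))
  spec <- as_contrast_spec(contrast)
  groups <- as.character(groups)
  i1 <- groups == spec$numerator
  i2 <- groups == spec$denominator
  if (sum(i1) < 2L || sum(i2) < 2L)
    stop("both contrast groups need at least 2 samples", call. = FALSE)
  mat <- mat[rowSums(is.na(mat)) == 0, , drop = FALSE]
  sub <- if (!is.null(model))
    setNames(model$reactions$subsystem, model$reactions$id)[rownames(mat)]
  else rep(NA_character_, nrow(mat))
  n1 <- sum(i1); n2 <- sum(i2)
  res <- lapply(seq_len(nrow(mat)), function(i) {
    x <- mat[i, i1]; y <- mat[i, i2]
    if (length(unique(c(x, y))) == 1L) {
      p <- 1; d <- 0
    } else {
      ties <- anyDuplicated(c(x, y)) > 0L
      exact <- min(n1, n2) <= 10 && !ties
      p <- suppressWarnings(
        wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
      psd <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
      d <- if (psd == 0) sign(mean(x) - mean(y)) * Inf else
        (mean(x) - mean(y)) / psd
    }
    data.frame(reaction = rownames(mat)[i], subsystem = sub[i],
               cohens_d = d, p = p)
  })
  tbl <- do.call(rbind, res)
  rownames(tbl) <- NULL
  tbl$sign <- ifelse(tbl$cohens_d > 0, "+", ifelse(tbl$cohens_d < 0, "-", "0"))
  tbl$padj <- bh_adjust(tbl$p)
  tbl$significant <- !is.na(tbl$padj) & tbl$padj < alpha
  attr(tbl, "contrast") <- spec
  class(tbl) <- c("diff_activity", "data.frame")
  tbl
}

#' Count significant reactions per subsystem and direction
#'
#' @param diff a [differential_activity()] table.
#' @return data frame (subsystem, sign, n) over significant reactions.
#' @export
subsystem_summary <- function(diff) {
  stopifnot(inherits(diff, "diff_activity"))
  sig <- diff[diff$significant, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(data.frame(subsystem = character(0), sign = character(0),
                      n = integer(0)))
  agg <- stats::aggregate(list(n = sig$reaction),
                          by = list(subsystem = sig$subsystem, sign = sig$sign),
                          FUN = length)
  agg[order(agg$subsystem, agg$sign), , drop = FALSE]
}

#' Fraction of altered reactions reversed by a treatment
#'
#' Among reactions significantly altered in the intervention contrast, the
#' fraction also significant in the treatment contrast with the opposite
#' Cohen's d sign.
#'
#' @param diff_sucrose,diff_treat [differential_activity()] tables over the
#'   same reaction universe.
#' @return list with `fraction` (`NA` when nothing is significant in the
#'   intervention contrast), `n_significant` and `reversed_reactions`.
#' @export
reversal_of_activity <- function(diff_sucrose, diff_treat) {
  stopifnot(inherits(diff_sucrose, "diff_activity"),
            inherits(diff_treat, "diff_activity"))
  if (!setequal(diff_sucrose$reaction, diff_treat$reaction))
    stop("differential tables cover different reaction universes", call. = FALSE)
  trt <- diff_treat[match(diff_sucrose$reaction, diff_treat$reaction), ]
  sig <- diff_sucrose$significant
  if (!any(sig))
    return(list(fraction = NA_real_, n_significant = 0L,
                reversed_reactions = character(0)))
  reversed <- sig & trt$significant &
    sign(diff_sucrose$cohens_d) * sign(trt$cohens_d) < 0
  list(fraction = sum(reversed) / sum(sig),
       n_significant = sum(sig),
       reversed_reactions = diff_sucrose$reaction[reversed])
}

# bundled toy models ------------------------------------------------------

#' Three-reaction linear pathway model
#'
#' An uptake reaction, a gene-associated conversion and a secretion:
#' `-> A -> B ->`, all bounds \[0, 10\]; only the conversion carries a gene
#' rule. Useful as a hand-solvable scoring fixture: with `w = 0.95` and the
#' conversion gene at expression `e`, the optimal penalty is
#' `9.5 / (1 + e)`.
#'
#' @param gene gene id on the conversion reaction.
#' @return a `metabolic_model`.
#' @export
linear_pathway_model <- function(gene = "g1") {
  metabolic_model(
    metabolites = c("A", "B"),
    reactions = data.frame(
      id = c("EX_A", "R_AB", "EX_B"),
      lower_bound = c(0, 0, 0), upper_bound = c(10, 10, 10),
      subsystem = c("Transport", "Core pathway", "Transport"),
      gpr = c(NA, gene, NA)),
    stoichiometry = list(EX_A = c(A = 1), R_AB = c(A = -1, B = 1),
                         EX_B = c(B = -1)))
}

#' Branched toy metabolic model
#'
#' A ten-reaction network with two branches, a reversible interconversion, a
#' dead-end (blocked) reaction and AND/OR gene rules over eleven supplied
#' genes, partitioned into named subsystems. Synthetic stand-in at desk scale
#' for a genome-scale reconstruction; used by the pipeline smoke runs and
#' tests.
#'
#' @param genes character vector of at least 11 gene ids wired into the rules.
#' @return a `metabolic_model`.
#' @export
example_metabolic_model <- function(genes = paste0("g", 1:11)) {
  stopifnot(length(genes) >= 11L)
  g <- genes
  metabolic_model(
    metabolites = c("A", "B", "C", "D", "E", "F", "DEAD"),
    reactions = data.frame(
      id = c("EX_A", "R1", "R2", "R3", "R4", "R5", "R6", "EX_D", "EX_F",
             "R_DEAD"),
      lower_bound = c(0, 0, 0, 0, 0, 0, -100, 0, 0, 0),
      upper_bound = c(100, 100, 100, 100, 100, 100, 100, 100, 100, 100),
      subsystem = c("Transport", "Glycolysis", "Glycolysis",
                    "Citric acid cycle", "Fatty acid synthesis",
                    "Fatty acid synthesis", "Citric acid cycle", "Transport",
                    "Transport", "Miscellaneous"),
      gpr = c(NA, g[1], paste(g[2], "AND", g[3]), paste(g[4], "OR", g[5]),
              g[6], sprintf("(%s AND %s) OR %s", g[7], g[8], g[9]), g[10],
              NA, NA, g[11])),
    stoichiometry = list(
      EX_A = c(A = 1), R1 = c(A = -1, B = 1), R2 = c(B = -1, C = 1),
      R3 = c(C = -1, D = 1), R4 = c(B = -1, E = 1), R5 = c(E = -1, F = 1),
      R6 = c(D = -1, E = 1), EX_D = c(D = -1), EX_F = c(F = -1),
      R_DEAD = c(C = -1, DEAD = 1)))
}
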