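#' Configuration for an end-to-end pipeline run
#'
#' Bundles the simulation settings (or a directory of previously written
#' datasets), the stage thresholds and the output directory.
#'
#' @param sim a [sim_config()]; ignored when `data_dir` is given.
#' @param out_dir directory for stage artifacts and the report.
#' @param data_dir optional directory of [write_dataset()] files to analyse
#'   instead of simulating; `tissues` and `groups` must then be supplied.
#' @param tissues,groups tissue labels / ordered group labels when reading
#'   external data (defaults follow `sim`).
#' @param alpha_deg adjusted-p threshold for DEG calling (default 0.01).
#' @param fdr_edge edge FDR for the co-expression network (default 0.05).
#' @param top_frac retained fraction of candidate edges (default 0.10).
#' @param min_module minimum module size (default 30).
#' @param alpha_module significance level for module enrichment and
#'   cross-tissue module correlation (default 0.05).
#' @param alpha_metab significance level for differential reaction activity
#'   (default 0.05).
#' @param gmt_path optional GMT file for the enrichment stage; when absent and
#'   data are simulated, a collection is derived from the planted gene sets.
#' @param metab_n_tissues number of tissues scored in the metabolic stage
#'   (default 1).
#' @param seed pipeline seed (defaults to the simulation seed).
#' @return a `run_config` list.
#' @export
run_config <- function(sim = sim_config(), out_dir = tempfile("crossnet_run_"),
                       data_dir = NULL, tissues = sim$tissues,
                       groups = sim$groups,
                       alpha_deg = 0.01, fdr_edge = 0.05, top_frac = 0.10,
                       min_module = 30, alpha_module = 0.05,
                       alpha_metab = 0.05, gmt_path = NULL,
                       metab_n_tissues = 1, seed = sim$seed) {
  for (f in c("alpha_deg", "fdr_edge", "top_frac", "alpha_module",
              "alpha_metab")) {
    v <- get(f)
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop("`", f, "` must lie in (0, 1)", call. = FALSE)
  }
  structure(list(sim = sim, out_dir = out_dir, data_dir = data_dir,
                 tissues = tissues, groups = groups, alpha_deg = alpha_deg,
                 fdr_edge = fdr_edge, top_frac = top_frac,
                 min_module = min_module, alpha_module = alpha_module,
                 alpha_metab = alpha_metab, gmt_path = gmt_path,
                 metab_n_tissues = metab_n_tissues, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

pipeline_contrasts <- function(groups) {
  specs <- list(contrast_spec(groups[2], groups[1], name = groups[2]))
  for (g in groups[-(1:2)])
    specs[[length(specs) + 1L]] <- contrast_spec(g, groups[2], name = g)
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulate (or load), differential
#' expression, reversal accounting, co-expression modules with cross-tissue
#' correlation, gene-set enrichment, metabolic reaction activity — writing
#' every intermediate artifact under `config$out_dir` and assembling a study
#' report. With `resume = TRUE`, stages whose artifacts are present on disk
#' and whose upstream stages were not recomputed are reloaded instead of
#' recomputed; deleting one stage's artifacts recomputes that stage and
#' everything downstream of it.
#'
#' @param config a [run_config()].
#' @param resume reuse existing stage artifacts where valid (default FALSE).
#' @return a `study_report` list; see [render_report()].
#' @export
run_pipeline <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  status <- c()
  fresh <- FALSE  # TRUE once any stage has been recomputed

  stage <- function(name, artifacts, compute, load) {
    paths <- file.path(out, artifacts)
    if (resume && !fresh && all(file.exists(paths))) {
      status[name] <<- "cached"
      return(load(paths))
    }
    fresh <<- TRUE
    status[name] <<- "computed"
    compute(paths)
  }

  groups <- if (is.null(config$data_dir)) config$sim$groups else config$groups
  tissues <- if (is.null(config$data_dir)) config$sim$tissues else config$tissues
  specs <- pipeline_contrasts(groups)

  # -- datasets -----------------------------------------------------------
  datasets <- stage(
    "datasets",
    c(paste0(tissues, "_counts.tsv"), "planted_sets.gmt"),
    compute = function(paths) {
      if (is.null(config$data_dir)) {
        sim <- simulate_study(config$sim)
        for (ds in sim$datasets) write_dataset(ds, out)
        write_ground_truth(sim$truth, file.path(out, "ground_truth.json"))
        write_gmt(planted_gmt(sim$truth), file.path(out, "planted_sets.gmt"))
        sim$datasets
      } else {
        ds <- lapply(tissues, function(t)
          read_dataset(config$data_dir, t, groups = groups))
        names(ds) <- tissues
        for (d in ds) write_dataset(d, out)
        coll <- if (!is.null(config$gmt_path)) read_gmt(config$gmt_path) else
          geneset_collection(list(all_genes = ds[[1]]$gene_ids),
                             source = "fallback")
        write_gmt(coll, file.path(out, "planted_sets.gmt"))
        ds
      }
    },
    load = function(paths) {
      ds <- lapply(tissues, function(t) read_dataset(out, t, groups = groups))
      names(ds) <- tissues
      ds
    })

  # -- differential expression -------------------------------------------
  de_artifacts <- as.vector(outer(tissues, names(specs),
                                  function(t, s) paste0(t, "_", s, "_de.tsv")))
  de <- stage(
    "de", de_artifacts,
    compute = function(paths) {
      res <- list()
      for (t in tissues) {
        res[[t]] <- list()
        for (s in names(specs)) {
          fit <- nb_wald_contrast(datasets[[t]], specs[[s]],
                                  alpha = config$alpha_deg)
          write.table(as.data.frame(fit$result),
                      file.path(out, paste0(t, "_", s, "_de.tsv")),
                      sep = "\t", quote = FALSE, row.names = FALSE)
          res[[t]][[s]] <- fit
        }
      }
      res
    },
    load = function(paths) {
      res <- list()
      for (t in tissues) {
        res[[t]] <- list()
        for (s in names(specs)) {
          tbl <- read.delim(file.path(out, paste0(t, "_", s, "_de.tsv")))
          class(tbl) <- c("contrast_result", "data.frame")
          attr(tbl, "contrast") <- specs[[s]]
          degs <- deg_sets(
            up = tbl$gene_id[tbl$padj < config$alpha_deg & tbl$log2fc > 0],
            down = tbl$gene_id[tbl$padj < config$alpha_deg & tbl$log2fc < 0],
            alpha = config$alpha_deg, background_n = nrow(tbl))
          res[[t]][[s]] <- list(result = tbl, degs = degs)
        }
      }
      res
    })

  # -- reversal accounting ------------------------------------------------
  treatments <- setdiff(names(specs), groups[2])
  reversal <- stage(
    "reversal", "reversal.json",
    compute = function(paths) {
      rev <- list()
      for (t in tissues) {
        rev[[t]] <- lapply(treatments, function(s)
          reversal_report(de[[t]][[groups[2]]]$degs, de[[t]][[s]]$degs))
        names(rev[[t]]) <- treatments
      }
      conc <- list()
      if (length(tissues) >= 2L && length(treatments) >= 1L) {
        s <- treatments[1]
        for (i in seq_len(length(tissues) - 1L)) {
          for (j in seq((i + 1L), length(tissues))) {
            key <- paste(tissues[i], tissues[j], sep = "~")
            conc[[key]] <- cross_tissue_concordance(
              de[[tissues[i]]][[s]]$result, de[[tissues[j]]][[s]]$result,
              de[[tissues[i]]][[s]]$degs, de[[tissues[j]]][[s]]$degs)
          }
        }
      }
      obj <- list(reports = rev, concordance = conc)
      jsonlite::write_json(serialize_reversal(obj), paths[1],
                           auto_unbox = TRUE, digits = NA, na = "null")
      obj
    },
    load = function(paths) deserialize_reversal(jsonlite::read_json(paths[1])))

  # -- co-expression modules ---------------------------------------------
  coexpr <- stage(
    "coexpression",
    c(paste0(tissues, "_modules.tsv"), paste0(tissues, "_eigengenes.tsv"),
      paste0(tissues, "_edges.tsv"), "cross_module_corr.tsv",
      "module_enrichment.tsv"),
    compute = function(paths) {
      mods <- list(); nets <- list()
      for (t in tissues) {
        ds <- datasets[[t]]
        tp <- tpm(ds$counts, ds$gene_lengths)
        keep <- filter_low_expression(tp, threshold = 1)
        expr <- log2(tp[keep, , drop = FALSE] + 1)
        net <- build_network(expr, fdr = config$fdr_edge,
                             top_frac = config$top_frac, tissue = t)
        ms <- detect_modules(net, expr, min_size = config$min_module,
                             seed = config$seed, animal_ids = ds$animal_ids)
        nets[[t]] <- net
        mods[[t]] <- ms
        write.table(net$edges, file.path(out, paste0(t, "_edges.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        memb <- do.call(rbind, lapply(ms$modules, function(m)
          data.frame(module = m$id, gene = m$genes,
                     var_explained = m$var_explained)))
        if (is.null(memb))
          memb <- data.frame(module = character(0), gene = character(0),
                             var_explained = numeric(0))
        if (length(ms$unassigned))
          memb <- rbind(memb, data.frame(module = "_unassigned",
                                         gene = ms$unassigned,
                                         var_explained = NA_real_))
        write.table(memb, file.path(out, paste0(t, "_modules.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        eig <- do.call(rbind, lapply(ms$modules, function(m)
          data.frame(module = m$id, sample_id = names(m$eigengene),
                     animal_id = ds$animal_ids[match(names(m$eigengene),
                                                     ds$sample_ids)],
                     value = unname(m$eigengene))))
        if (is.null(eig))
          eig <- data.frame(module = character(0), sample_id = character(0),
                            animal_id = character(0), value = numeric(0))
        write.table(eig, file.path(out, paste0(t, "_eigengenes.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      cross <- cross_module_pairs(mods, config$alpha_module)
      write.table(cross, file.path(out, "cross_module_corr.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      enr <- module_enrichment_all(mods, de, tissues, config)
      write.table(enr, file.path(out, "module_enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      list(modules = mods, networks = nets, cross = cross, enrichment = enr)
    },
    load = function(paths) {
      mods <- list()
      for (t in tissues) {
        memb <- read.delim(file.path(out, paste0(t, "_modules.tsv")),
                           colClasses = c("character", "character", "numeric"))
        eig <- read.delim(file.path(out, paste0(t, "_eigengenes.tsv")))
        ms <- structure(list(modules = list(),
                             unassigned = memb$gene[memb$module == "_unassigned"],
                             tissue = t,
                             sample_ids = unique(eig$sample_id),
                             animal_ids = unique(eig$animal_id),
                             min_size = config$min_module, seed = config$seed),
                        class = "module_set")
        for (id in setdiff(unique(memb$module), "_unassigned")) {
          e <- eig[eig$module == id, ]
          ms$modules[[id]] <- list(
            id = id, genes = memb$gene[memb$module == id],
            eigengene = setNames(e$value, e$sample_id),
            var_explained = memb$var_explained[memb$module == id][1])
        }
        mods[[t]] <- ms
      }
      cross <- read.delim(file.path(out, "cross_module_corr.tsv"))
      enr <- read.delim(file.path(out, "module_enrichment.tsv"))
      list(modules = mods, networks = NULL, cross = cross, enrichment = enr)
    })

  # -- gene-set enrichment ------------------------------------------------
  enrichment <- stage(
    "enrichment", "geneset_enrichment.tsv",
    compute = function(paths) {
      coll <- if (!is.null(config$gmt_path)) read_gmt(config$gmt_path) else
        read_gmt(file.path(out, "planted_sets.gmt"))
      rows <- list()
      for (t in tissues) {
        universe <- de[[t]][[groups[2]]]$result$gene_id
        for (dir in c("up", "down")) {
          q <- de[[t]][[groups[2]]]$degs[[dir]]
          if (length(q) == 0L) next
          tbl <- enrich(q, coll, universe)
          if (nrow(tbl)) {
            tbl$tissue <- t; tbl$query <- paste0(groups[2], "_", dir)
            rows[[length(rows) + 1L]] <- tbl
          }
        }
      }
      res <- if (length(rows)) do.call(rbind, rows) else
        data.frame(set = character(0), k = integer(0), p = numeric(0),
                   padj = numeric(0), tissue = character(0),
                   query = character(0))
      write.table(res, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
      res
    },
    load = function(paths) read.delim(paths[1]))

  # -- metabolic activity -------------------------------------------------
  metab_tissues <- head(tissues, config$metab_n_tissues)
  metabolic <- stage(
    "metabolic", "metabolic_summary.json",
    compute = function(paths) {
      res <- list()
      for (t in metab_tissues) {
        ds <- datasets[[t]]
        tp <- tpm(ds$counts, ds$gene_lengths)
        model_genes <- names(sort(rowMeans(tp), decreasing = TRUE))[1:11]
        model <- example_metabolic_model(model_genes)
        rexpr <- reaction_expression(model, tp)
        sc <- compass_scores(model, rexpr)
        diffs <- list()
        for (s in c(groups[2], treatments[1])) {
          diffs[[s]] <- differential_activity(sc, ds$group, specs[[s]],
                                              model = model,
                                              alpha = config$alpha_metab)
        }
        rev <- reversal_of_activity(diffs[[groups[2]]], diffs[[treatments[1]]])
        res[[t]] <- list(scores = sc, diffs = diffs, reversal = rev,
                         model_genes = model_genes)
        write.table(data.frame(reaction = rownames(sc$scores), sc$scores,
                               check.names = FALSE),
                    file.path(out, paste0(t, "_reaction_scores.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        for (s in names(diffs))
          write.table(as.data.frame(diffs[[s]]),
                      file.path(out, paste0(t, "_", s, "_diff_activity.tsv")),
                      sep = "\t", quote = FALSE, row.names = FALSE)
      }
      summary <- lapply(res, function(r) list(
        n_significant_sucrose = sum(r$diffs[[groups[2]]]$significant),
        n_significant_treatment = sum(r$diffs[[treatments[1]]]$significant),
        reversal_fraction = r$reversal$fraction,
        n_blocked = sum(r$scores$blocked)))
      jsonlite::write_json(summary, paths[1], auto_unbox = TRUE, digits = NA,
                           na = "null")
      res
    },
    load = function(paths) {
      res <- list()
      for (t in metab_tissues) {
        diffs <- list()
        for (s in c(groups[2], treatments[1])) {
          tbl <- read.delim(file.path(out,
                                      paste0(t, "_", s, "_diff_activity.tsv")))
          class(tbl) <- c("diff_activity", "data.frame")
          attr(tbl, "contrast") <- specs[[s]]
          diffs[[s]] <- tbl
        }
        rev <- reversal_of_activity(diffs[[groups[2]]], diffs[[treatments[1]]])
        res[[t]] <- list(scores = NULL, diffs = diffs, reversal = rev)
      }
      res
    })

  report <- build_report(config, datasets, de, reversal, coexpr, enrichment,
                         metabolic, specs, status)
  writeLines(render_report(report), file.path(out, "report.txt"))
  jsonlite::write_json(report$summary, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  report
}

planted_gmt <- function(truth) {
  sets <- list()
  for (t in names(truth$tissues)) {
    tt <- truth$tissues[[t]]
    if (length(tt$deg_up))
      sets[[paste0(t, "_planted_up")]] <- names(tt$deg_up)
    if (length(tt$deg_down))
      sets[[paste0(t, "_planted_down")]] <- names(tt$deg_down)
    for (m in unique(tt$module_membership))
      sets[[paste0(t, "_planted_", m)]] <-
        names(tt$module_membership)[tt$module_membership == m]
  }
  if (length(sets) == 0L) sets <- list(empty_placeholder = "none")
  geneset_collection(sets, source = "planted ground truth")
}

cross_module_pairs <- function(mods, alpha) {
  tissues <- names(mods)
  rows <- list()
  for (i in seq_along(tissues)) {
    for (j in seq_along(tissues)) {
      if (j <= i) next
      a <- mods[[i]]; b <- mods[[j]]
      if (length(a$modules) == 0L || length(b$modules) == 0L) next
      tbl <- cross_tissue_module_correlation(a, b, alpha = alpha)
      if (nrow(tbl)) rows[[length(rows) + 1L]] <- as.data.frame(tbl)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module_a = character(0), module_b = character(0),
               R = numeric(0), p = numeric(0), padj = numeric(0),
               significant = logical(0))
  # BH must span every inter-tissue pair tested, not each tissue pair alone
  out$padj <- bh_adjust(out$p)
  out$significant <- !is.na(out$padj) & out$padj < alpha
  out
}

module_enrichment_all <- function(mods, de, tissues, config) {
  rows <- list()
  groups2 <- names(de[[1]])
  for (t in tissues) {
    ms <- mods[[t]]
    if (length(ms$modules) == 0L) next
    degl <- lapply(de[[t]], `[[`, "degs")
    tbl <- module_deg_enrichment(ms, degl, alpha = config$alpha_module)
    rows[[length(rows) + 1L]] <- cbind(tissue = t, as.data.frame(tbl))
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(tissue = character(0), module = character(0),
               contrast = character(0), direction = character(0),
               k = integer(0), p = numeric(0), padj = numeric(0),
               significant = logical(0))
}

serialize_reversal <- function(obj) {
  list(reports = lapply(obj$reports, function(tt)
    lapply(tt, function(r) unclass(r))),
    concordance = lapply(obj$concordance, unclass))
}

deserialize_reversal <- function(j) {
  rep_from <- function(r) {
    r <- lapply(r, function(x)
      if (is.list(x)) unlist(lapply(x, identity)) %||% character(0) else x)
    for (f in c("pct_suppressed", "pct_restored", "p_hyper_suppressed",
                "p_hyper_restored"))
      r[[f]] <- if (is.null(r[[f]])) NA_real_ else as.numeric(r[[f]])
    for (f in c("suppressed", "restored"))
      r[[f]] <- as.character(r[[f]] %||% character(0))
    class(r) <- "reversal_report"
    r
  }
  conc_from <- function(x) {
    x$shared <- as.character(x$shared %||% character(0))
    for (f in c("pct_same_sign", "spearman_rho", "p"))
      x[[f]] <- if (is.null(x[[f]])) NA_real_ else as.numeric(x[[f]])
    class(x) <- "concordance_report"
    x
  }
  list(reports = lapply(j$reports, function(tt) lapply(tt, rep_from)),
       concordance = lapply(j$concordance, conc_from))
}

build_report <- function(config, datasets, de, reversal, coexpr, enrichment,
                         metabolic, specs, status) {
  groups <- names(de[[1]])
  tissues <- names(de)
  deg_summary <- list()
  for (t in tissues) {
    deg_summary[[t]] <- lapply(names(de[[t]]), function(s) {
      d <- de[[t]][[s]]$degs
      list(contrast = s, n_up = length(d$up), n_down = length(d$down),
           n_total = length(d$up) + length(d$down),
           pct_of_universe = format_pct(length(d$up) + length(d$down),
                                        d$background_n),
           background_n = d$background_n)
    })
    names(deg_summary[[t]]) <- names(de[[t]])
  }
  module_summary <- lapply(coexpr$modules, function(ms) list(
    n_modules = length(ms$modules),
    sizes = unname(vapply(ms$modules, function(m) length(m$genes), 0L)),
    n_unassigned = length(ms$unassigned)))
  metab_summary <- lapply(metabolic, function(r) list(
    n_significant_sucrose = sum(r$diffs[[1]]$significant),
    n_significant_treatment = sum(r$diffs[[2]]$significant),
    reversal_fraction = r$reversal$fraction))
  summary <- list(
    deg = deg_summary,
    reversal = lapply(reversal$reports, function(tt) lapply(tt, function(r)
      r[c("n_sucrose_up", "n_sucrose_down", "n_suppressed", "n_restored",
          "pct_suppressed", "pct_restored")])),
    concordance = lapply(reversal$concordance, function(x)
      x[c("n_shared", "pct_same_sign", "spearman_rho")]),
    modules = module_summary,
    n_significant_cross_pairs = sum(coexpr$cross$significant),
    metabolic = metab_summary,
    provenance = list(config_hash = config_hash(config), seed = config$seed,
                      package_version = as.character(utils::packageVersion("crossnet")),
                      stage_status = as.list(status)))
  structure(list(config = config, summary = summary, de = de,
                 reversal = reversal, coexpr = coexpr,
                 enrichment = enrichment, metabolic = metabolic,
                 stage_status = status),
            class = "study_report")
}

#' Render a study report as text
#'
#' @param report a `study_report` from [run_pipeline()].
#' @param digits decimal places for percentages (default 1; 0 gives
#'   integer-percent rendering).
#' @return character vector of report lines.
#' @export
render_report <- function(report, digits = 1) {
  stopifnot(inherits(report, "study_report"))
  s <- report$summary
  fmt_pct <- function(x) {
    if (is.null(x) || is.na(x)) return("n/a")
    paste0(format(round(x, digits), nsmall = digits), "%")
  }
  lines <- c("== crossnet study report ==",
             paste0("config hash: ", s$provenance$config_hash,
                    "  seed: ", s$provenance$seed),
             "")
  lines <- c(lines, "-- differential expression --")
  for (t in names(s$deg)) {
    for (cs in s$deg[[t]]) {
      lines <- c(lines, sprintf(
        "%s %s: %d DEGs (%d up, %d down), %s of %d genes tested",
        t, cs$contrast, cs$n_total, cs$n_up, cs$n_down,
        fmt_pct(cs$pct_of_universe), cs$background_n))
    }
  }
  lines <- c(lines, "", "-- treatment reversal --")
  for (t in names(s$reversal)) {
    for (trt in names(s$reversal[[t]])) {
      r <- s$reversal[[t]][[trt]]
      lines <- c(lines, sprintf(
        "%s %s: suppressed %d/%d (%s) of intervention-up, restored %d/%d (%s) of intervention-down",
        t, trt, r$n_suppressed, r$n_sucrose_up,
        fmt_pct(format_pct(r$n_suppressed, r$n_sucrose_up, digits)),
        r$n_restored, r$n_sucrose_down,
        fmt_pct(format_pct(r$n_restored, r$n_sucrose_down, digits))))
    }
  }
  lines <- c(lines, "", "-- cross-tissue DEG concordance (first treatment) --")
  for (k in names(s$concordance)) {
    x <- s$concordance[[k]]
    lines <- c(lines, sprintf("%s: %d shared DEGs, %s same sign, Spearman rho = %s",
                              k, x$n_shared, fmt_pct(x$pct_same_sign),
                              if (is.na(x$spearman_rho)) "n/a" else
                                format(round(x$spearman_rho, 2))))
  }
  lines <- c(lines, "", "-- co-expression modules --")
  for (t in names(s$modules)) {
    m <- s$modules[[t]]
    lines <- c(lines, if (m$n_modules == 0L)
      sprintf("%s: no modules >= minimum size", t)
      else sprintf("%s: %d modules (sizes %s), %d genes unassigned", t,
                   m$n_modules, paste(m$sizes, collapse = ", "),
                   m$n_unassigned))
  }
  lines <- c(lines, sprintf("significant inter-tissue module pairs: %d",
                            s$n_significant_cross_pairs))
  lines <- c(lines, "", "-- metabolic reaction activity --")
  if (length(s$metabolic) == 0L) lines <- c(lines, "not run")
  for (t in names(s$metabolic)) {
    m <- s$metabolic[[t]]
    lines <- c(lines, sprintf(
      "%s: %d reactions altered by intervention, %d by treatment, reversal fraction %s",
      t, m$n_significant_sucrose, m$n_significant_treatment,
      if (is.na(m$reversal_fraction)) "n/a" else
        fmt_pct(100 * m$reversal_fraction)))
  }
  lines <- c(lines, "", "-- stage status --",
             paste(names(s$provenance$stage_status),
                   unlist(s$provenance$stage_status), sep = ": ",
                   collapse = "; "))
  lines
}

#' @export
print.study_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
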