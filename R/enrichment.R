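#' Read a gene-set collection from a GMT file
#'
#' Each line holds a set name, a description and one or more member genes,
#' tab-separated. Duplicate members within a set are collapsed.
#'
#' @param path GMT file path.
#' @param source label recorded on the collection (defaults to the file name).
#' @return a `geneset_collection`: `sets` (named list of unique gene-id
#'   vectors), `description` (named character) and `source`.
#' @export
read_gmt <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop("cannot read GMT file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); descr <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": expected at least 3 tab-separated ",
           "fields, got ", length(f), call. = FALSE)
    name <- f[1]
    if (name %in% names(sets))
      stop("duplicated set name '", name, "' at GMT line ", i, call. = FALSE)
    sets[[name]] <- unique(f[-(1:2)])
    descr[name] <- f[2]
  }
  structure(list(sets = sets, description = descr, source = source),
            class = "geneset_collection")
}

#' Write a gene-set collection to a GMT file
#'
#' @param coll a `geneset_collection`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(coll, path) {
  stopifnot(inherits(coll, "geneset_collection"))
  lines <- vapply(names(coll$sets), function(nm) {
    paste(c(nm, coll$description[nm] %||% "", coll$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Build a gene-set collection in code
#'
#' @param sets named list of gene-id vectors.
#' @param description optional named descriptions.
#' @param source label.
#' @return a `geneset_collection`.
#' @export
geneset_collection <- function(sets, description = NULL, source = "in-memory") {
  stopifnot(is.list(sets), !is.null(names(sets)), !anyDuplicated(names(sets)))
  descr <- setNames(rep("", length(sets)), names(sets))
  if (!is.null(description)) descr[names(description)] <- description
  structure(list(sets = lapply(sets, unique), description = descr,
                 source = source),
            class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("geneset_collection '%s': %d sets (sizes %s)\n", x$source,
              length(x$sets),
              paste(range(lengths(x$sets)), collapse = "-")))
  invisible(x)
}

#' Hypergeometric gene-set over-representation
#'
#' Tests a query gene list against every set in a collection. Set members are
#' first intersected with the universe; sets empty after intersection are
#' dropped. The p-value is the upper-tail hypergeometric probability
#' ([hypergeom_overlap()]) and BH adjustment is applied across the sets of the
#' collection. One-sided over-representation only.
#'
#' @param query gene-id vector (should lie within `universe`; ids outside it
#'   are dropped with a warning).
#' @param coll a `geneset_collection`.
#' @param universe background gene ids, typically the genes tested in the
#'   relevant tissue.
#' @return data frame (set, k, set_size, query_size, universe_size, p, padj),
#'   sorted by p.
#' @export
enrich <- function(query, coll, universe) {
  stopifnot(inherits(coll, "geneset_collection"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty gene universe", call. = FALSE)
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning("dropping ", length(outside), " query gene(s) outside the universe")
    query <- intersect(query, universe)
  }
  sets <- lapply(coll$sets, intersect, universe)
  sets <- sets[lengths(sets) > 0]
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    K <- length(sets[[nm]])
    k <- length(intersect(query, sets[[nm]]))
    data.frame(set = nm, k = k, set_size = K, query_size = n,
               universe_size = N, p = hypergeom_overlap(k, K, n, N))
  })
  tbl <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(0), k = integer(0), set_size = integer(0),
               query_size = integer(0), universe_size = integer(0),
               p = numeric(0))
  tbl$padj <- bh_adjust(tbl$p)
  tbl[order(tbl$p, tbl$set), , drop = FALSE]
}
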