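#' One-sided Fisher exact over-representation test
#'
#' Tests whether a query feature set over-represents a target set within a
#' universe: p = P(X >= overlap) under the hypergeometric null. The odds
#' ratio comes from the 2x2 table, with a 0.5 continuity correction when
#' any cell is zero.
#'
#' @param query,target_set feature id vectors, both subsets of `universe`.
#' @param universe feature id vector (>= 2 ids).
#' @param query_name,set_name labels carried into the result.
#' @return one-row data.frame: query, set, overlap, query_only, set_only,
#'   neither, odds_ratio, pvalue, overlap_ids (semicolon-joined).
#' @export
fisher_enrichment <- function(query, target_set, universe,
                              query_name = "query", set_name = "set") {
  universe <- unique(universe)
  if (length(universe) < 2) stop("universe must contain >= 2 features")
  bad <- setdiff(query, universe)
  if (length(bad)) stop("query ids outside the universe: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  query <- unique(query)
  target_set <- unique(intersect(target_set, universe))
  hits <- intersect(query, target_set)
  a <- length(hits)
  b <- length(query) - a
  cc <- length(target_set) - a
  d <- length(universe) - a - b - cc
  p <- stats::phyper(a - 1, length(target_set),
                     length(universe) - length(target_set),
                     length(query), lower.tail = FALSE)
  tab <- c(a, b, cc, d)
  if (any(tab == 0)) tab <- tab + 0.5
  or <- (tab[1] * tab[4]) / (tab[2] * tab[3])
  data.frame(query = query_name, set = set_name,
             overlap = a, query_only = b, set_only = cc, neither = d,
             odds_ratio = or, pvalue = p,
             overlap_ids = paste(sort(hits), collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Enrichment of query sets against a gene-set collection
#'
#' Runs [fisher_enrichment()] for every query x set pair, applies BH FDR
#' across the full result table, and sorts by FDR then p. Sets with no
#' member in the universe are skipped with a warning.
#'
#' @param queries named list of feature id vectors.
#' @param collection named list of feature id vectors (a
#'   [read_gene_sets()] result).
#' @param universe feature id vector.
#' @return data.frame of enrichment records with an `fdr` column.
#' @export
enrich_collection <- function(queries, collection, universe) {
  if (length(queries) &&
      (is.null(names(queries)) || any(names(queries) == "")))
    stop("queries must be named")
  if (is.null(names(collection)) || any(names(collection) == ""))
    stop("collection sets must be named")
  if (anyDuplicated(names(collection)))
    stop("duplicate set names in collection")
  rows <- list()
  for (q in names(queries)) {
    for (s in names(collection)) {
      inset <- intersect(collection[[s]], universe)
      if (!length(inset)) {
        warning("set has no members in the universe, skipped: ", s)
        next
      }
      rows[[paste(q, s, sep = "\r")]] <-
        fisher_enrichment(queries[[q]], inset, universe,
                          query_name = q, set_name = s)
    }
  }
  if (!length(rows))
    return(data.frame(query = character(), set = character(),
                      overlap = integer(), query_only = integer(),
                      set_only = integer(), neither = integer(),
                      odds_ratio = numeric(), pvalue = numeric(),
                      overlap_ids = character(), fdr = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$fdr <- stats::p.adjust(res$pvalue, "BH")
  res[order(res$fdr, res$pvalue, res$query, res$set), , drop = FALSE]
}

#' Read a gene-set collection (GMT or two-column TSV)
#'
#' GMT: one set per line, `name <tab> description <tab> member...`.
#' TSV: `(set_name, feature_id)` pairs, aggregated per set. Duplicate
#' members are dropped with a warning; an empty file yields an empty
#' collection with a warning.
#'
#' @param path file path.
#' @param format "gmt" or "tsv".
#' @return named list of feature id vectors.
#' @export
read_gene_sets <- function(path, format = c("gmt", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene-set file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty gene-set file: ", path)
    return(stats::setNames(list(), character(0)))
  }
  if (format == "gmt") {
    sets <- list()
    for (i in seq_along(lines)) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < 3)
        stop("malformed GMT line ", i, ": needs name, description, ",
             ">= 1 member")
      name <- f[1]
      if (name %in% names(sets)) stop("duplicate set name at line ", i,
                                      ": ", name)
      members <- f[-(1:2)]
      if (anyDuplicated(members)) {
        warning("duplicate members in set ", name, ", deduplicated")
        members <- unique(members)
      }
      sets[[name]] <- members
    }
    sets
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 2))
      stop("malformed TSV line ", which(nf < 2)[1], ": needs set_name and ",
           "feature_id")
    df <- data.frame(set = vapply(parts, `[`, "", 1),
                     id = vapply(parts, `[`, "", 2),
                     stringsAsFactors = FALSE)
    if (anyDuplicated(df)) warning("duplicate (set, feature) pairs, deduplicated")
    sets <- lapply(split(df$id, df$set), unique)
    sets[unique(df$set)]
  }
}
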