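#' Read a miRNA-target map from TSV
#'
#' Tab-delimited table with a header; the first two columns are taken as
#' miRNA id and target gene id (miRTarBase-style exports satisfy this), an
#' optional third column as evidence tag. Duplicate edges are dropped.
#'
#' @param path file path.
#' @return data.frame: mirna_id, target_gene_id, evidence.
#' @export
read_target_map <- function(path) {
  if (!file.exists(path)) stop("target map not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("target map needs >= 2 columns (miRNA, target)")
  out <- data.frame(mirna_id = as.character(df[[1]]),
                    target_gene_id = as.character(df[[2]]),
                    evidence = if (ncol(df) >= 3) as.character(df[[3]])
                               else NA_character_,
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$mirna_id)) || any(!nzchar(out$target_gene_id)))
    stop("target map contains empty ids")
  dup <- duplicated(out[, c("mirna_id", "target_gene_id")])
  if (any(dup)) {
    warning(sum(dup), " duplicate edges dropped from target map")
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# Row-wise Pearson correlation between matched rows of two matrices.
row_cor <- function(X, Y) {
  xc <- X - rowMeans(X)
  yc <- Y - rowMeans(Y)
  rowSums(xc * yc) / sqrt(rowSums(xc^2) * rowSums(yc^2))
}

#' Per-edge miRNA-target expression correlations
#'
#' Pearson (and Spearman) correlation across samples for every target-map
#' edge whose both endpoints are present and non-constant. The two
#' expression matrices must be standardized over the identical, identically
#' ordered sample set; a differing sample set is an error, never a silent
#' intersection. Dropped edges (absent or constant endpoint) are counted in
#' the `dropped` attribute.
#'
#' @param mirna_expr,mrna_expr standardized expression matrices
#'   ([standardize_features()]).
#' @param map target-map data.frame (mirna_id, target_gene_id).
#' @return data.frame of class `pair_cor`: mirna_id, target_gene_id,
#'   pearson, spearman, n_samples.
#' @export
pair_correlations <- function(mirna_expr, mrna_expr, map) {
  for (m in list(mirna_expr, mrna_expr))
    if (!identical(attr(m, "transform"), "zscore"))
      stop("expression matrices must be standardized (standardize_features)")
  if (!identical(colnames(mirna_expr), colnames(mrna_expr)))
    stop("miRNA and mRNA sample sets differ (ids/order must be identical)")
  n <- ncol(mirna_expr)
  if (n < 3) stop("need >= 3 shared samples")
  const_mir <- attr(mirna_expr, "constant")
  const_rna <- attr(mrna_expr, "constant")
  ok <- map$mirna_id %in% rownames(mirna_expr) &
    map$target_gene_id %in% rownames(mrna_expr)
  keep <- ok
  keep[ok] <- !(const_mir[map$mirna_id[ok]] |
                  const_rna[map$target_gene_id[ok]])
  dropped <- sum(!keep)
  if (dropped) message(dropped, " map edge(s) dropped ",
                       "(absent or constant endpoint)")
  sub <- map[keep, , drop = FALSE]
  X <- mirna_expr[sub$mirna_id, , drop = FALSE]
  Y <- mrna_expr[sub$target_gene_id, , drop = FALSE]
  pear <- row_cor(X, Y)
  Xr <- t(apply(X, 1, rank))
  Yr <- t(apply(Y, 1, rank))
  rho <- if (nrow(sub)) row_cor(Xr, Yr) else numeric(0)
  structure(data.frame(mirna_id = sub$mirna_id,
                       target_gene_id = sub$target_gene_id,
                       pearson = pear, spearman = rho, n_samples = n,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("pair_cor", "data.frame"), dropped = dropped)
}

#' Per-miRNA negative-shift test on target correlations
#'
#' One-sample one-sided Wilcoxon signed-rank test that a miRNA's target
#' Pearson correlations are shifted below zero (alternative: median < 0).
#' The exact null distribution is used when a miRNA has <= 25 usable
#' correlations with no zeros or tied magnitudes; otherwise the normal
#' approximation with continuity and tie corrections. miRNAs with fewer
#' than `min_targets` tested edges are omitted (the exact one-sided p
#' cannot reach 0.05 below n = 5).
#'
#' @param pairs a [pair_correlations()] result.
#' @param min_targets minimum tested targets per miRNA (default 5).
#' @return data.frame: mirna_id, n_targets, mean_r, mean_rho, p_shift,
#'   with omitted miRNAs recorded in the `omitted` attribute.
#' @export
regulator_shift_test <- function(pairs, min_targets = 5) {
  stopifnot(is.data.frame(pairs),
            all(c("mirna_id", "pearson") %in% names(pairs)))
  if (min_targets < 1) stop("min_targets must be >= 1")
  split_r <- split(seq_len(nrow(pairs)), pairs$mirna_id)
  n_all <- lengths(split_r)
  omitted <- names(split_r)[n_all < min_targets]
  keep <- names(split_r)[n_all >= min_targets]
  rows <- lapply(keep, function(m) {
    i <- split_r[[m]]
    r <- pairs$pearson[i]
    use_exact <- length(r) <= 25 && !any(r == 0) &&
      !anyDuplicated(abs(r))
    p <- suppressWarnings(stats::wilcox.test(
      r, mu = 0, alternative = "less",
      exact = use_exact, correct = TRUE)$p.value)
    data.frame(mirna_id = m, n_targets = length(r), mean_r = mean(r),
               mean_rho = mean(pairs$spearman[i]), p_shift = p,
               stringsAsFactors = FALSE)
  })
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(), n_targets = integer(),
               mean_r = numeric(), mean_rho = numeric(),
               p_shift = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, omitted = omitted)
}

#' Nominate candidate miRNA regulators
#'
#' A candidate miRNA (i) falls in a down trajectory class (down_down,
#' labeled `down_enhanced`, or down_up, labeled `down_counteracted`) and
#' (ii) shows a significant negative shift of its target correlations
#' (p < `p_threshold`). Candidates are ranked by ascending shift p, ties
#' broken by more negative mean correlation, then id. Each candidate
#' carries its anti-correlated targets: tested targets with r < 0 whose
#' mRNA class is up_up or up_down.
#'
#' @param shift a [regulator_shift_test()] result.
#' @param mirna_classes,mrna_classes [classify_features()] results for the
#'   miRNA and mRNA features.
#' @param pairs the [pair_correlations()] table behind `shift`.
#' @param p_threshold shift-test significance threshold (default 0.05).
#' @param adjust apply BH across miRNAs before thresholding (default FALSE,
#'   i.e. raw p < threshold).
#' @return data.frame of class `regulator_table`: mirna_id, class, flavor,
#'   n_targets, mean_r, mean_rho, p_shift, candidate, rank (NA for
#'   non-candidates), anticorrelated_targets (semicolon-joined).
#' @export
nominate_regulators <- function(shift, mirna_classes, mrna_classes, pairs,
                                p_threshold = 0.05, adjust = FALSE) {
  stopifnot(inherits(mirna_classes, "class_assignment"),
            inherits(mrna_classes, "class_assignment"))
  cls <- stats::setNames(mirna_classes$class, mirna_classes$feature_id)
  gcls <- stats::setNames(mrna_classes$class, mrna_classes$feature_id)
  res <- shift
  res$class <- unname(cls[res$mirna_id])
  res$class[is.na(res$class)] <- "unclassified"
  res$flavor <- c(down_down = "down_enhanced",
                  down_up = "down_counteracted")[res$class]
  p_use <- if (adjust) stats::p.adjust(res$p_shift, "BH") else res$p_shift
  res$candidate <- res$class %in% c("down_down", "down_up") &
    p_use < p_threshold
  anti <- vapply(res$mirna_id, function(m) {
    sub <- pairs[pairs$mirna_id == m & pairs$pearson < 0, , drop = FALSE]
    tg <- sub$target_gene_id[gcls[sub$target_gene_id] %in%
                               c("up_up", "up_down")]
    paste(sort(unique(tg)), collapse = ";")
  }, character(1))
  res$anticorrelated_targets <- unname(anti)
  res$rank <- NA_integer_
  cand <- which(res$candidate)
  if (length(cand)) {
    ord <- cand[order(res$p_shift[cand], res$mean_r[cand],
                      res$mirna_id[cand])]
    res$rank[ord] <- seq_along(ord)
  }
  res <- res[order(!res$candidate, res$rank, res$p_shift, res$mirna_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  structure(res[, c("mirna_id", "class", "flavor", "n_targets", "mean_r",
                    "mean_rho", "p_shift", "candidate", "rank",
                    "anticorrelated_targets")],
            class = c("regulator_table", "data.frame"))
}

#' Enrichment of pooled anti-correlated targets
#'
#' Pools the anti-correlated targets of all candidate regulators, split by
#' target trajectory class (up_up pool vs up_down pool), and runs
#' [enrich_collection()] on each pool. With no candidates the result is an
#' empty table with a warning.
#'
#' @param regulators a [nominate_regulators()] result.
#' @param mrna_classes the mRNA [classify_features()] result.
#' @param collection named list of gene sets.
#' @param universe feature id universe for the Fisher test.
#' @return enrichment data.frame with queries `up_up_targets` and
#'   `up_down_targets`.
#' @export
anticorrelated_target_enrichment <- function(regulators, mrna_classes,
                                             collection, universe) {
  stopifnot(inherits(regulators, "regulator_table"))
  cand <- regulators[regulators$candidate, , drop = FALSE]
  if (!nrow(cand)) {
    warning("no candidate regulators; empty enrichment table")
    return(enrich_collection(list(), collection, universe)[0, ])
  }
  targets <- unique(unlist(strsplit(
    cand$anticorrelated_targets[nzchar(cand$anticorrelated_targets)], ";",
    fixed = TRUE)))
  gcls <- stats::setNames(mrna_classes$class, mrna_classes$feature_id)
  pools <- list(up_up_targets = targets[gcls[targets] == "up_up"],
                up_down_targets = targets[gcls[targets] == "up_down"])
  pools <- lapply(pools, function(x) intersect(x, universe))
  pools <- pools[lengths(pools) > 0]
  if (!length(pools)) {
    warning("anti-correlated target pools are empty")
    return(enrich_collection(list(), collection, universe)[0, ])
  }
  enrich_collection(pools, collection, universe)
}
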