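#' Four-class trajectory assignment
#'
#' Crosses the differentiation-contrast call with the genotype-contrast
#' call: up_up = up in both, up_down = up in differentiation but down with
#' the null genotype, down_up and down_down analogously. Features not
#' significant in both contrasts are `unclassified`. The first token is
#' always the differentiation direction, the second the genotype-effect
#' direction.
#'
#' @param diff_call,geno_call [call_de()] results over the same universe.
#' @return data.frame of class `class_assignment`: feature_id, class.
#' @export
classify_features <- function(diff_call, geno_call) {
  stopifnot(inherits(diff_call, "de_call"), inherits(geno_call, "de_call"))
  if (!setequal(diff_call$universe, geno_call$universe))
    stop("DE calls are over different feature universes")
  universe <- diff_call$universe
  cls <- rep("unclassified", length(universe))
  names(cls) <- universe
  cls[intersect(diff_call$up, geno_call$up)] <- "up_up"
  cls[intersect(diff_call$up, geno_call$down)] <- "up_down"
  cls[intersect(diff_call$down, geno_call$up)] <- "down_up"
  cls[intersect(diff_call$down, geno_call$down)] <- "down_down"
  structure(data.frame(feature_id = universe, class = unname(cls),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("class_assignment", "data.frame"))
}

#' Per-class expression trajectories
#'
#' Mean and SD of standardized expression per trajectory class and
#' (genotype, stage) cell — the summary behind trajectory plots. Empty
#' classes are emitted with NA summaries and a warning.
#'
#' @param expr standardized expression matrix ([standardize_features()]).
#' @param design design data.frame covering all columns of `expr`.
#' @param assignment a [classify_features()] result.
#' @return data.frame: class, genotype, stage, n_features, mean, sd.
#' @export
class_trajectories <- function(expr, design, assignment) {
  stopifnot(inherits(assignment, "class_assignment"))
  if (!identical(attr(expr, "transform"), "zscore"))
    stop("expr must be standardized (see standardize_features)")
  if (!setequal(design$sample_id, colnames(expr)))
    stop("design does not cover the expression samples")
  classes <- c("up_up", "up_down", "down_up", "down_down")
  cells <- unique(design[, c("genotype", "stage")])
  out <- list()
  for (cl in classes) {
    feats <- intersect(assignment$feature_id[assignment$class == cl],
                       rownames(expr))
    if (!length(feats)) {
      warning("empty class: ", cl)
      out[[cl]] <- data.frame(class = cl, genotype = cells$genotype,
                              stage = cells$stage, n_features = 0L,
                              mean = NA_real_, sd = NA_real_,
                              stringsAsFactors = FALSE)
      next
    }
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      sam <- design$sample_id[design$genotype == cells$genotype[i] &
                                design$stage == cells$stage[i]]
      vals <- expr[feats, sam, drop = FALSE]
      data.frame(class = cl, genotype = cells$genotype[i],
                 stage = cells$stage[i], n_features = length(feats),
                 mean = mean(vals), sd = stats::sd(as.vector(vals)),
                 stringsAsFactors = FALSE)
    })
    out[[cl]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
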