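#' Validate a feature-by-sample count matrix
#'
#' Checks the container contract used throughout the package: an integer-like
#' numeric matrix with unique, non-empty feature ids as rownames and unique
#' sample ids as colnames, and no negative entries.
#'
#' @param counts numeric matrix, features in rows, samples in columns.
#' @param what label used in error messages.
#' @return the validated matrix (invisibly useful in pipes).
#' @export
validate_counts <- function(counts, what = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop(what, " must be a numeric matrix")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop(what, " must have unique feature ids as rownames")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop(what, " must have unique sample ids as colnames")
  if (anyNA(counts) || any(counts < 0))
    stop(what, " must be non-negative with no missing values")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop(what, " must contain integer counts")
  counts
}

#' Read a count matrix from TSV
#'
#' Expects a header row of sample ids and a first column of feature ids,
#' the layout written by [write_counts_tsv()].
#'
#' @param path file path.
#' @return integer count matrix with feature rownames and sample colnames.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  validate_counts(m, basename(path))
}

#' Write a count or expression matrix to TSV
#'
#' @param m matrix with feature rownames and sample colnames.
#' @param path output file path.
#' @param id_col name for the feature-id column.
#' @export
write_counts_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table from TSV
#'
#' Columns: sample_id, genotype, stage, replicate.
#'
#' @param path file path.
#' @return data.frame with the four design columns.
#' @export
read_design_tsv <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype", "stage", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("design file missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in design")
  df
}
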