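#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors with the method's published
#' defaults: reference sample chosen by upper-quartile proximity to the
#' mean, 30% two-sided trim on M-values, 5% on A-values, inverse
#' asymptotic-variance weights; genes with a zero count in either compared
#' sample drop out of each pairwise comparison. Factors are rescaled to a
#' geometric mean of 1, so effective library size = column sum x factor.
#'
#' @param counts count matrix (features x samples), >= 2 samples.
#' @return named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(counts) {
  validate_counts(counts)
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  libs <- colSums(counts)
  if (any(libs == 0))
    stop("all-zero sample(s): ", paste(colnames(counts)[libs == 0],
                                       collapse = ", "))
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  if (any(!is.finite(f))) {
    warning("sample(s) share no co-expressed genes with the reference; ",
            "factor set to 1: ",
            paste(colnames(counts)[!is.finite(f)], collapse = ", "))
    f[!is.finite(f)] <- 1
    f <- f / exp(mean(log(f)))
  }
  stats::setNames(f, colnames(counts))
}

#' Log2 counts-per-million
#'
#' log2 CPM against effective library sizes (column sum x TMM factor), with
#' a library-size-adjusted prior count so zeros stay finite. With
#' `prior_count = 0` plain CPM columns sum to 1e6.
#'
#' @param counts count matrix.
#' @param factors normalization factors named by sample id (default
#'   [tmm_factors()] of `counts`).
#' @param prior_count prior count added before the log (default 0.5).
#' @return matrix of log2 CPM values, tagged with attribute
#'   `transform = "log2cpm"`.
#' @export
log_cpm <- function(counts, factors = tmm_factors(counts),
                    prior_count = 0.5) {
  validate_counts(counts)
  if (prior_count < 0) stop("prior_count must be >= 0")
  if (is.null(names(factors)) ||
      !identical(names(factors), colnames(counts)))
    stop("normalization factors are not aligned with the sample ids")
  if (any(factors <= 0)) stop("normalization factors must be > 0")
  eff <- colSums(counts) * factors
  out <- edgeR::cpm(counts, lib.size = eff, log = TRUE,
                    prior.count = prior_count)
  dimnames(out) <- dimnames(counts)
  attr(out, "transform") <- "log2cpm"
  out
}

#' Z-score each feature across samples
#'
#' Centers and scales each row to mean 0, SD 1 (sample SD, n - 1 divisor).
#' Constant rows become all-zero and are flagged in the `constant`
#' attribute. This is the "standard normalized expression" fed to the
#' miRNA-target correlation analysis.
#'
#' @param expr numeric expression matrix (features x samples), >= 3 samples.
#' @return z-score matrix with attributes `transform = "zscore"` and
#'   `constant` (logical per feature).
#' @export
standardize_features <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expr must be a numeric matrix")
  if (ncol(expr) < 3) stop("standardization needs >= 3 samples")
  mu <- rowMeans(expr)
  centered <- expr - mu
  s <- sqrt(rowSums(centered^2) / (ncol(expr) - 1))
  const <- s < 1e-12
  s[const] <- 1
  z <- centered / s
  z[const, ] <- 0
  attr(z, "transform") <- "zscore"
  attr(z, "constant") <- stats::setNames(const, rownames(expr))
  z
}
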