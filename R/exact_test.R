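#' Define a two-group contrast
#'
#' @param name contrast label.
#' @param a,b character vectors of sample ids for the baseline (A) and
#'   comparison (B) groups; fold changes are B vs A.
#' @return list of class `contrast`.
#' @export
make_contrast <- function(name, a, b) {
  if (length(a) == 0 || length(b) == 0) stop("contrast groups must be non-empty")
  if (length(intersect(a, b))) stop("contrast groups must be disjoint")
  structure(list(name = name, a = a, b = b), class = "contrast")
}

#' Default contrasts for the 2x2 differentiation design
#'
#' `differentiation`: WT-RA vs WT-ESC (effect of retinoic-acid
#' differentiation in wild-type cells). `genotype`: dKO-RA vs WT-RA (effect
#' of the null genotype at the differentiated stage).
#'
#' @param design design data.frame (sample_id, genotype, stage).
#' @return named list of two [make_contrast()] objects.
#' @export
default_contrasts <- function(design) {
  pick <- function(g, s) design$sample_id[design$genotype == g & design$stage == s]
  list(
    differentiation = make_contrast("differentiation",
                                    a = pick("WT", "ESC"), b = pick("WT", "RA")),
    genotype = make_contrast("genotype",
                             a = pick("WT", "RA"), b = pick("dKO", "RA")))
}

#' Conditional NB exact p-value for one feature
#'
#' Two-sided exact p for group sums `(sa, sb)` of `na`/`nb`
#' library-equalized NB samples with fixed dispersion. Conditional on the
#' total `t = sa + sb`, the B-group sum follows a negative hypergeometric
#' distribution with shapes `nb/dispersion` and `na/dispersion` (the NB
#' probability parameter cancels), enumerated here in closed log form.
#' The two-sided p doubles the smaller tail (tie mass at the observed
#' value included in both tails), capped at 1.
#'
#' @param sa,sb group count sums.
#' @param na,nb group sample sizes.
#' @param dispersion NB dispersion (> 0).
#' @return the exact p-value.
#' @export
nb_exact_pvalue <- function(sa, sb, na, nb, dispersion) {
  t <- sa + sb
  if (t == 0) return(1)
  ra <- na / dispersion
  rb <- nb / dispersion
  b <- 0:t
  logp <- lgamma(b + rb) - lgamma(b + 1) +
    lgamma(t - b + ra) - lgamma(t - b + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  lower <- sum(p[b <= sb])
  upper <- sum(p[b >= sb])
  min(1, 2 * min(lower, upper))
}

#' Fixed-dispersion negative-binomial exact test
#'
#' Two-group exact test for count data under a negative-binomial model with
#' a single fixed dispersion (variance = mu + dispersion * mu^2). Sample
#' counts are first scaled to a common effective library size (the
#' geometric mean of the contrast samples' effective libraries, rounding
#' half to even) so that group sums are comparable; the test then
#' conditions on each feature's total and evaluates the two-sided tail
#' probability of the observed B-group sum, doubling the smaller tail.
#' Fold changes use prior-augmented group mean counts, so they stay finite.
#'
#' @param counts count matrix containing at least the contrast samples.
#' @param contrast a [make_contrast()] object; both groups >= 2 samples.
#' @param dispersion NB dispersion, > 0 (default 0.1).
#' @param factors optional TMM factors named by sample id (computed on the
#'   contrast samples when missing).
#' @param prior_count prior added to each group mean for the fold change.
#' @return data.frame of class `de_table`: feature_id, logFC (B vs A),
#'   logCPM (average over all contrast samples), pvalue, fdr (BH).
#' @export
nb_exact_test <- function(counts, contrast, dispersion = 0.1,
                          factors = NULL, prior_count = 0.5) {
  validate_counts(counts)
  if (!inherits(contrast, "contrast")) stop("contrast must be a `contrast` object")
  if (dispersion <= 0) stop("dispersion must be > 0")
  ids <- c(contrast$a, contrast$b)
  miss <- setdiff(ids, colnames(counts))
  if (length(miss)) stop("contrast samples absent from counts: ",
                         paste(miss, collapse = ", "))
  if (length(contrast$a) < 2 || length(contrast$b) < 2)
    stop("each contrast group needs >= 2 samples")
  sub <- counts[, ids, drop = FALSE]
  if (is.null(factors)) factors <- tmm_factors(sub)
  eff <- colSums(sub) * factors[ids]
  N <- exp(mean(log(eff)))
  scaled <- round(sweep(sub, 2, N / eff, `*`))

  na <- length(contrast$a)
  nb <- length(contrast$b)
  sa <- rowSums(scaled[, contrast$a, drop = FALSE])
  sb <- rowSums(scaled[, contrast$b, drop = FALSE])
  pvals <- vapply(seq_len(nrow(scaled)), function(i)
    nb_exact_pvalue(sa[i], sb[i], na, nb, dispersion), numeric(1))

  cpm_a <- (sa / na + prior_count) / N * 1e6
  cpm_b <- (sb / nb + prior_count) / N * 1e6
  logfc <- log2(cpm_b) - log2(cpm_a)
  logfc[sa + sb == 0] <- 0
  logcpm <- log2(((sa + sb) / (na + nb) + prior_count) / N * 1e6)

  structure(data.frame(feature_id = rownames(counts), logFC = logfc,
                       logCPM = logcpm, pvalue = pvals,
                       fdr = stats::p.adjust(pvals, "BH"),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("de_table", "data.frame"),
            contrast = contrast$name, dispersion = dispersion)
}

#' Threshold a DE table into up/down calls
#'
#' A feature is called up when raw p < `p_max`, logFC > `lfc_min` and
#' average logCPM > `logcpm_min`; down analogously with logFC < -`lfc_min`.
#' The BH-adjusted p is carried in the table but not used for calling.
#'
#' @param table a [nb_exact_test()] result.
#' @param p_max raw p-value threshold in (0, 1] (default 0.05).
#' @param lfc_min absolute log2 fold-change threshold (default 0.75).
#' @param logcpm_min average log2 CPM threshold (default 0).
#' @return list of class `de_call`: `up`, `down` (feature id vectors),
#'   `universe`, `thresholds`.
#' @export
call_de <- function(table, p_max = 0.05, lfc_min = 0.75, logcpm_min = 0) {
  stopifnot(is.data.frame(table),
            all(c("feature_id", "logFC", "logCPM", "pvalue") %in% names(table)))
  if (!is.finite(p_max) || p_max <= 0 || p_max > 1)
    stop("p_max must be in (0, 1]")
  if (!is.finite(lfc_min) || !is.finite(logcpm_min))
    stop("thresholds must be finite")
  ok <- table$pvalue < p_max & table$logCPM > logcpm_min
  up <- table$feature_id[ok & table$logFC > lfc_min]
  down <- table$feature_id[ok & table$logFC < -lfc_min]
  structure(list(up = up, down = down, universe = table$feature_id,
                 thresholds = c(p_max = p_max, lfc_min = lfc_min,
                                logcpm_min = logcpm_min)),
            class = "de_call")
}

#' Shared/specific partition of two DE calls
#'
#' Venn-style partition of the up and down sets of two calls over the same
#' feature universe, plus the shared fraction |A and B| / |A or B| per
#' direction.
#'
#' @param call_a,call_b [call_de()] results over the identical universe.
#' @return list with per-direction elements `shared`, `a_specific`,
#'   `b_specific`, `shared_fraction`.
#' @export
venn_partition <- function(call_a, call_b) {
  stopifnot(inherits(call_a, "de_call"), inherits(call_b, "de_call"))
  if (!setequal(call_a$universe, call_b$universe))
    stop("DE calls are over different feature universes")
  one <- function(a, b) {
    u <- union(a, b)
    list(shared = intersect(a, b),
         a_specific = setdiff(a, b),
         b_specific = setdiff(b, a),
         shared_fraction = if (length(u)) length(intersect(a, b)) / length(u)
                           else NA_real_)
  }
  list(up = one(call_a$up, call_b$up),
       down = one(call_a$down, call_b$down))
}
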