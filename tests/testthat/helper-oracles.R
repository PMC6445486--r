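# Independent brute-force oracles used to validate the analysis routines.
# Each oracle takes a different computational route than the implementation
# it checks (explicit enumeration / step-by-step arithmetic).

# Step-by-step trimmed-mean-of-M-values factors, written out explicitly:
# upper-quartile reference choice, pairwise M/A values on depth-scaled
# counts, rank-based double trim, inverse asymptotic-variance weights,
# geometric-mean rescaling.
oracle_tmm <- function(counts) {
  lib <- colSums(counts)
  counts <- counts[rowSums(counts > 0) > 0, , drop = FALSE]
  uq <- vapply(seq_len(ncol(counts)),
               function(j) stats::quantile(counts[, j], 0.75) / lib[j],
               numeric(1))
  ref <- which.min(abs(uq - mean(uq)))
  one <- function(obs, nO, refc, nR) {
    logR <- log2((obs / nO) / (refc / nR))
    absE <- (log2(obs / nO) + log2(refc / nR)) / 2
    w <- (nO - obs) / (nO * obs) + (nR - refc) / (nR * refc)
    fin <- is.finite(logR) & is.finite(absE) & absE > -1e10
    logR <- logR[fin]; absE <- absE[fin]; w <- w[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loM <- floor(0.3 * n) + 1; hiM <- n + 1 - loM
    loA <- floor(0.05 * n) + 1; hiA <- n + 1 - loA
    keep <- rank(logR) >= loM & rank(logR) <= hiM &
      rank(absE) >= loA & rank(absE) <= hiA
    2^(sum(logR[keep] / w[keep]) / sum(1 / w[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), function(j)
    one(counts[, j], lib[j], counts[, ref], lib[ref]), numeric(1))
  f / exp(mean(log(f)))
}

# Hypergeometric upper-tail P(X >= k) as an explicit sum of lchoose terms.
oracle_hyper_tail <- function(k, set_size, universe_size, query_size) {
  hi <- min(set_size, query_size)
  if (k > hi) return(0)
  sum(exp(lchoose(set_size, k:hi) +
            lchoose(universe_size - set_size, query_size - (k:hi)) -
            lchoose(universe_size, query_size)))
}

# Full 2^n enumeration of the one-sample signed-rank statistic V (sum of
# ranks carrying a positive sign). Returns the sorted null sample of V.
oracle_signrank_null <- function(n) {
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  as.vector(signs %*% seq_len(n))
}

# One-sided p (alternative: shifted below zero) for observed values x by
# enumeration: P(V <= v_obs) over all sign patterns.
oracle_signrank_p_less <- function(x) {
  v_obs <- sum(rank(abs(x))[x > 0])
  null <- oracle_signrank_null(length(x))
  mean(null <= v_obs)
}

# Conditional NB exact test by brute force: the unnormalized conditional
# split distribution from stats::dnbinom at an arbitrary common
# probability parameter (it cancels after normalization), then the
# doubled smaller tail.
oracle_nb_exact_p <- function(sa, sb, na, nb, dispersion, prob = 0.5) {
  t <- sa + sb
  if (t == 0) return(1)
  b <- 0:t
  pr <- stats::dnbinom(b, size = nb / dispersion, prob = prob) *
    stats::dnbinom(t - b, size = na / dispersion, prob = prob)
  pr <- pr / sum(pr)
  min(1, 2 * min(sum(pr[b <= sb]), sum(pr[b >= sb])))
}

# Small standardized expression matrix from raw values.
make_zscore <- function(m) {
  standardize_features(m)
}

# Tiny planted dataset shared by several tests.
small_sim <- function(seed = 101, ...) {
  simulate_dataset(sim_config(n_genes = 600, n_mirnas = 40,
                              n_regulator_mirnas = 6, targets_per_mirna = 8,
                              seed = seed, ...))
}
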