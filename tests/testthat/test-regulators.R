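zmat <- function(m, ids, samples = paste0("s", seq_len(ncol(m)))) {
  dimnames(m) <- list(ids, samples)
  standardize_features(m)
}

test_that("pair correlations recover perfect anti-correlation and drop
           degenerate edges", {
  mir <- zmat(rbind(c(1, 0, -1), c(2, 5, 3)), c("mirA", "mirB"))
  rna <- zmat(rbind(c(-1, 0, 1), c(4, 4, 4)), c("g1", "g2"))
  map <- data.frame(mirna_id = c("mirA", "mirA", "mirB", "mirA"),
                    target_gene_id = c("g1", "g2", "g1", "missing"),
                    stringsAsFactors = FALSE)
  expect_message(pc <- pair_correlations(mir, rna, map), "dropped")
  expect_equal(nrow(pc), 2)  # g2 constant, `missing` absent
  expect_equal(pc$pearson[pc$mirna_id == "mirA"], -1, tolerance = 1e-12)
  expect_equal(attr(pc, "dropped"), 2)
})

test_that("pair correlations reject differing sample sets", {
  mir <- zmat(matrix(rnorm(6), 2), c("mirA", "mirB"))
  rna <- zmat(matrix(rnorm(6), 2), c("g1", "g2"), paste0("x", 1:3))
  map <- data.frame(mirna_id = "mirA", target_gene_id = "g1")
  expect_error(pair_correlations(mir, rna, map), "sample sets differ")
  raw <- mir
  attr(raw, "transform") <- NULL
  expect_error(pair_correlations(raw, rna, map), "standardized")
})

test_that("independent vectors give near-zero mean correlation", {
  set.seed(41)
  n_edges <- 1000
  mir <- zmat(matrix(rnorm(12 * 50), 50), sprintf("m%02d", 1:50))
  rna <- zmat(matrix(rnorm(12 * 200), 200), sprintf("g%03d", 1:200))
  map <- data.frame(mirna_id = sample(rownames(mir), n_edges, TRUE),
                    target_gene_id = sample(rownames(rna), n_edges, TRUE))
  map <- unique(map)
  pc <- pair_correlations(mir, rna, map)
  se <- sd(pc$pearson) / sqrt(nrow(pc))
  expect_lt(abs(mean(pc$pearson)), 3 * se + 0.02)
})

test_that("shift test: all-negative targets give the exact minimum p and
           small sets are omitted", {
  pc <- data.frame(mirna_id = c(rep("mirA", 10), rep("mirB", 4)),
                   target_gene_id = paste0("g", 1:14),
                   pearson = c(-seq(0.1, 1, by = 0.1), rep(-0.5, 4)),
                   spearman = 0, n_samples = 12)
  res <- regulator_shift_test(pc, min_targets = 5)
  expect_equal(res$mirna_id, "mirA")
  expect_equal(res$p_shift, 1 / 1024, tolerance = 1e-12)
  expect_equal(attr(res, "omitted"), "mirB")
})

test_that("shift test p is >= 0.5 for correlations symmetric about zero", {
  pc <- data.frame(mirna_id = "m", target_gene_id = paste0("g", 1:8),
                   pearson = c(0.31, -0.31, 0.22, -0.22, 0.13, -0.13,
                               0.44, -0.44) + 1e-9,
                   spearman = 0, n_samples = 12)
  res <- regulator_shift_test(pc, min_targets = 5)
  expect_gte(res$p_shift, 0.5 - 1e-6)
})

test_that("exact Wilcoxon branch matches full sign-pattern enumeration", {
  mags <- function(n) seq_len(n) / (n + 1)
  for (n in 5:9) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    for (i in seq_len(nrow(signs))) {
      x <- signs[i, ] * mags(n)
      pc <- data.frame(mirna_id = "m", target_gene_id = paste0("g", 1:n),
                       pearson = x, spearman = 0, n_samples = 12)
      p_impl <- regulator_shift_test(pc, min_targets = 5)$p_shift
      expect_equal(p_impl, oracle_signrank_p_less(x), tolerance = 1e-12)
    }
  }
})

test_that("nomination applies the direction filter, p threshold, tie-break
           and target annotation", {
  shift <- data.frame(
    mirna_id = c("m1", "m2", "m3", "m4", "m5"),
    n_targets = 10,
    mean_r = c(-0.6, -0.5, -0.62, -0.1, -0.7),
    mean_rho = -0.5,
    p_shift = c(0.001, 0.001, 0.002, 1e-6, 0.5),
    stringsAsFactors = FALSE)
  cls <- function(ids, classes) structure(
    data.frame(feature_id = ids, class = classes, stringsAsFactors = FALSE),
    class = c("class_assignment", "data.frame"))
  mirna_cls <- cls(paste0("m", 1:5),
                   c("down_down", "down_up", "down_up", "up_up", "down_down"))
  genes <- paste0("g", 1:6)
  mrna_cls <- cls(genes, c("up_up", "up_up", "up_down", "unclassified",
                           "up_down", "down_down"))
  pairs <- data.frame(
    mirna_id = rep(c("m1", "m2", "m3", "m4", "m5"), each = 3),
    target_gene_id = rep(c("g1", "g4", "g6"), 5),
    pearson = rep(c(-0.8, -0.5, 0.3), 5),
    spearman = 0, n_samples = 12, stringsAsFactors = FALSE)
  reg <- nominate_regulators(shift, mirna_cls, mrna_cls, pairs,
                             p_threshold = 0.05)
  # m4 excluded by direction despite smallest p; m5 by p threshold
  expect_setequal(reg$mirna_id[reg$candidate], c("m1", "m2", "m3"))
  # equal p tie between m1 and m2 broken by more negative mean r
  expect_equal(reg$mirna_id[match(1:3, reg$rank)], c("m1", "m2", "m3"))
  expect_equal(reg$flavor[reg$mirna_id == "m1"], "down_enhanced")
  expect_equal(reg$flavor[reg$mirna_id == "m2"], "down_counteracted")
  # anti-correlated targets: r < 0 and up-class only (g1; g4 unclassified)
  expect_equal(reg$anticorrelated_targets[reg$mirna_id == "m1"], "g1")
})

test_that("nomination is invariant to target-map row order", {
  ds <- small_sim(seed = 91)
  z_rna <- standardize_features(log_cpm(ds$mrna_counts))
  z_mir <- standardize_features(log_cpm(ds$mirna_counts))
  run <- function(map) {
    pc <- pair_correlations(z_mir, z_rna, map)
    sh <- regulator_shift_test(pc)
    cons <- default_contrasts(ds$design)
    de_m <- lapply(cons, function(ct)
      call_de(nb_exact_test(ds$mirna_counts, ct)))
    de_g <- lapply(cons, function(ct)
      call_de(nb_exact_test(ds$mrna_counts, ct)))
    nominate_regulators(sh, classify_features(de_m[[1]], de_m[[2]]),
                        classify_features(de_g[[1]], de_g[[2]]), pc)
  }
  set.seed(1)
  shuffled <- ds$target_map[sample(nrow(ds$target_map)), ]
  expect_equal(run(ds$target_map), run(shuffled), ignore_attr = TRUE)
})

test_that("anti-correlated target pools are disjoint and a planted set
           ranks first; no candidates give an empty table", {
  set.seed(51)
  genes <- paste0("g", 1:300)
  cls <- structure(data.frame(
    feature_id = genes,
    class = sample(c("up_up", "up_down", "unclassified"), 300, TRUE),
    stringsAsFactors = FALSE), class = c("class_assignment", "data.frame"))
  up_down_genes <- cls$feature_id[cls$class == "up_down"]
  phenotype <- c(sample(up_down_genes, round(0.6 * length(up_down_genes))),
                 sample(genes, 10))
  collection <- list(phenotype = unique(phenotype),
                     other = sample(genes, 40))
  reg <- structure(data.frame(
    mirna_id = "m1", class = "down_up", flavor = "down_counteracted",
    n_targets = length(up_down_genes), mean_r = -0.5, mean_rho = -0.4,
    p_shift = 0.001, candidate = TRUE, rank = 1L,
    anticorrelated_targets = paste(up_down_genes, collapse = ";"),
    stringsAsFactors = FALSE), class = c("regulator_table", "data.frame"))
  res <- anticorrelated_target_enrichment(reg, cls, collection, genes)
  expect_true(all(res$query == "up_down_targets"))
  expect_equal(res$set[1], "phenotype")

  reg_none <- reg; reg_none$candidate <- FALSE
  expect_warning(empty <- anticorrelated_target_enrichment(
    reg_none, cls, collection, genes), "no candidate")
  expect_equal(nrow(empty), 0)
})
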