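test_that("factorial design has the expected shape and rejects n_reps < 2", {
  d3 <- build_design(sim_config(n_reps_per_condition = 3))
  expect_equal(nrow(d3), 12)
  expect_equal(unname(table(d3$genotype, d3$stage)), matrix(3L, 2, 2))
  expect_false(anyDuplicated(d3$sample_id) > 0)

  d2 <- build_design(sim_config(n_reps_per_condition = 2))
  expect_equal(nrow(d2), 8)

  cfg <- sim_config(n_reps_per_condition = 2)
  cfg$n_reps_per_condition <- 1L
  expect_error(build_design(cfg), "replication")
})

test_that("config validation rejects infeasible or out-of-range settings", {
  expect_error(sim_config(frac_diff_up = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(dispersion_true = 0), "> 0")
  expect_error(sim_config(n_genes = 100, n_regulator_mirnas = 20,
                          targets_per_mirna = 10), "infeasible")
})

test_that("same config and seed give bit-identical datasets", {
  a <- small_sim(seed = 55)
  b <- small_sim(seed = 55)
  expect_identical(a$mrna_counts, b$mrna_counts)
  expect_identical(a$mirna_counts, b$mirna_counts)
  expect_identical(a$target_map, b$target_map)
  expect_identical(a$truth, b$truth)
  c <- small_sim(seed = 56)
  expect_false(identical(a$mrna_counts, c$mrna_counts))
})

test_that("counts are non-negative integers with library sums near target", {
  ds <- simulate_dataset(sim_config(n_genes = 3000, n_mirnas = 50,
                                    frac_diff_up = 0, frac_diff_down = 0,
                                    n_regulator_mirnas = 0,
                                    repression_strength = 0, seed = 9))
  expect_true(all(ds$mrna_counts >= 0))
  expect_true(all(ds$mrna_counts == round(ds$mrna_counts)))
  cfg <- ds$config
  sd_lib <- cfg$lib_size_mean * cfg$lib_size_cv
  expect_true(all(abs(colSums(ds$mrna_counts) - cfg$lib_size_mean) <
                    4 * sd_lib))
})

test_that("truth ledger matches configured class fractions and edge rules", {
  cfg <- sim_config(n_genes = 4000, n_mirnas = 60, n_regulator_mirnas = 10,
                    targets_per_mirna = 12, seed = 13)
  ds <- simulate_dataset(cfg)
  tr <- ds$truth
  n_diff <- sum(tr$gene_lfc_diff != 0)
  expect_equal(n_diff, round((cfg$frac_diff_up + cfg$frac_diff_down) *
                               cfg$n_genes))
  n_four <- sum(tr$gene_class != "none")
  expected_four <- 2 * round(cfg$frac_geno_effect *
                               round(cfg$frac_diff_up * cfg$n_genes))
  # multinomial sampling affects only the sign split, not the total
  expect_equal(n_four, expected_four)
  # classes consistent with planted effect signs
  expect_true(all(tr$gene_lfc_diff[tr$gene_class == "up_down"] > 0))
  expect_true(all(tr$gene_lfc_geno[tr$gene_class == "up_down"] < 0))
  # regulators are a subset of miRNA ids, planted in down classes
  expect_true(all(tr$regulators %in% rownames(ds$mirna_counts)))
  expect_true(all(tr$mirna_class[tr$regulators] %in%
                    c("down_down", "down_up")))
  # functional edges point to up-class genes, decoys to untouched genes
  map <- ds$target_map
  fun <- tr$edge_functional
  expect_true(all(tr$gene_class[map$target_gene_id[fun]] %in%
                    c("up_up", "up_down")))
  decoy_targets <- map$target_gene_id[!fun]
  expect_true(all(tr$gene_lfc_diff[decoy_targets] == 0 &
                    tr$gene_lfc_geno[decoy_targets] == 0))
  expect_true(all(map$mirna_id[fun] %in% tr$regulators))
})

test_that("repression coupling yields negative regulator-target correlation", {
  ds <- small_sim(seed = 77, repression_strength = 1)
  z_rna <- standardize_features(log_cpm(ds$mrna_counts))
  z_mir <- standardize_features(log_cpm(ds$mirna_counts))
  pc <- pair_correlations(z_mir, z_rna, ds$target_map)
  fun <- ds$truth$edge_functional
  key <- paste(ds$target_map$mirna_id, ds$target_map$target_gene_id)
  pc_key <- paste(pc$mirna_id, pc$target_gene_id)
  fun_r <- pc$pearson[pc_key %in% key[fun]]
  expect_lt(mean(fun_r), 0)
  expect_gt(mean(fun_r < 0), 0.9)
})

test_that("dataset round-trips through the TSV writers", {
  ds <- small_sim(seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  m <- read_counts_tsv(paths[["mrna"]])
  expect_equal(m, ds$mrna_counts)
  d <- read_design_tsv(paths[["design"]])
  expect_equal(d, ds$design, ignore_attr = TRUE)
  tm <- read_target_map(paths[["targets"]])
  expect_equal(tm$mirna_id, ds$target_map$mirna_id)
  expect_equal(tm$target_gene_id, ds$target_map$target_gene_id)
})
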