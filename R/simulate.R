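#' Simulation configuration for the synthetic differentiation dataset
#'
#' Builds a validated configuration for [simulate_dataset()]. The generator
#' emulates the statistical structure the downstream analysis assumes: a
#' 2-genotype (WT, dKO) x 2-stage (ESC, RA) negative-binomial count design
#' with log-normal library-size variation, differentiation and genotype
#' effects planted in the four trajectory classes, and miRNA->target
#' repression coupling that produces negative miRNA/target expression
#' correlations.
#'
#' @param n_genes number of mRNA features.
#' @param n_mirnas number of miRNA features.
#' @param n_reps_per_condition replicates per genotype x stage cell (>= 2).
#' @param lib_size_mean expected library size (reads per sample), used for
#'   both the mRNA and the miRNA libraries.
#' @param lib_size_cv coefficient of variation of the log-normal library
#'   size distribution.
#' @param dispersion_true NB dispersion used to draw counts
#'   (variance = mu + dispersion * mu^2).
#' @param frac_diff_up,frac_diff_down fractions of genes up-/down-regulated
#'   by differentiation (stage effect, RA vs ESC).
#' @param frac_geno_effect fraction of differentiation-responsive genes that
#'   additionally receive a genotype effect (dKO vs WT), sign drawn at
#'   random, defining the four trajectory classes.
#' @param effect_lfc_diff,effect_lfc_geno planted log2 fold-change
#'   magnitudes for the two effects.
#' @param n_regulator_mirnas number of planted regulator miRNAs; half are
#'   planted down_down, half down_up.
#' @param targets_per_mirna annotated targets per miRNA in the target map.
#' @param repression_strength log2 units of target suppression per unit of
#'   the regulator's standardized latent abundance (0 disables coupling).
#' @param decoy_target_fraction fraction of a regulator's map edges that
#'   point to genes with no planted repression.
#' @param baseline_meanlog,baseline_sdlog parameters of the log-normal
#'   baseline abundance distribution (before normalization to relative
#'   abundances); sdlog around 1.8 gives a realistic dynamic range so the
#'   logCPM > 0 expression filter removes a non-trivial low tail.
#' @param seed integer seed; every stochastic draw derives from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       n_mirnas = 200,
                       n_reps_per_condition = 3,
                       lib_size_mean = 2e6,
                       lib_size_cv = 0.2,
                       dispersion_true = 0.1,
                       frac_diff_up = 0.15,
                       frac_diff_down = 0.15,
                       frac_geno_effect = 0.3,
                       effect_lfc_diff = 2,
                       effect_lfc_geno = 2,
                       n_regulator_mirnas = 20,
                       targets_per_mirna = 25,
                       repression_strength = 1,
                       decoy_target_fraction = 0.25,
                       baseline_meanlog = 0,
                       baseline_sdlog = 1.8,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
              n_reps_per_condition = as.integer(n_reps_per_condition),
              lib_size_mean = lib_size_mean, lib_size_cv = lib_size_cv,
              dispersion_true = dispersion_true,
              frac_diff_up = frac_diff_up, frac_diff_down = frac_diff_down,
              frac_geno_effect = frac_geno_effect,
              effect_lfc_diff = effect_lfc_diff,
              effect_lfc_geno = effect_lfc_geno,
              n_regulator_mirnas = as.integer(n_regulator_mirnas),
              targets_per_mirna = as.integer(targets_per_mirna),
              repression_strength = repression_strength,
              decoy_target_fraction = decoy_target_fraction,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              seed = as.integer(seed))
  fracs <- c("frac_diff_up", "frac_diff_down", "frac_geno_effect",
             "decoy_target_fraction", "lib_size_cv")
  for (f in fracs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  if (cfg$frac_diff_up + cfg$frac_diff_down > 1)
    stop("frac_diff_up + frac_diff_down must not exceed 1")
  for (f in c("n_genes", "n_mirnas", "n_reps_per_condition"))
    if (cfg[[f]] < 1) stop(f, " must be >= 1")
  if (cfg$dispersion_true <= 0) stop("dispersion_true must be > 0")
  if (cfg$lib_size_mean <= 0) stop("lib_size_mean must be > 0")
  if (cfg$repression_strength < 0) stop("repression_strength must be >= 0")
  if (cfg$targets_per_mirna * cfg$n_regulator_mirnas > cfg$n_genes)
    stop("infeasible config: targets_per_mirna * n_regulator_mirnas ",
         "exceeds n_genes")
  if (cfg$n_regulator_mirnas > cfg$n_mirnas)
    stop("n_regulator_mirnas exceeds n_mirnas")
  class(cfg) <- "sim_config"
  cfg
}

#' Build the factorial sample design
#'
#' Deterministic 2 x 2 x n design: genotypes WT/dKO, stages ESC/RA,
#' `n_reps_per_condition` replicates per cell. Sample ids are
#' `<genotype>_<stage>_r<rep>`.
#'
#' @param config a [sim_config()] object (only `n_reps_per_condition` used).
#' @return data.frame(sample_id, genotype, stage, replicate).
#' @export
build_design <- function(config) {
  n <- config$n_reps_per_condition
  if (n < 2) stop("n_reps_per_condition must be >= 2 (contrasts need replication)")
  grid <- expand.grid(replicate = seq_len(n),
                      stage = c("ESC", "RA"),
                      genotype = c("WT", "dKO"),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("genotype", "stage", "replicate")]
  grid$sample_id <- sprintf("%s_%s_r%d", grid$genotype, grid$stage,
                            grid$replicate)
  grid[, c("sample_id", "genotype", "stage", "replicate")]
}

# Draw a log-normal vector with given arithmetic mean and CV.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a paired mRNA/miRNA dataset with planted ground truth
#'
#' Counts are drawn NB with mean
#' `mu_gs = lib_s * q_g * 2^(x_RA * L_diff_g + x_dKO * L_geno_g - r * z_ms)`
#' where `x_RA`, `x_dKO` are stage/genotype indicators, `L_*` the planted
#' log2 effects, and the repression term couples each functional target to
#' the standardized latent (noise-free) log2 abundance `z_ms` of its
#' regulator miRNA in the same sample, scaled by `repression_strength`.
#' Regulator miRNAs are planted in the down_down/down_up classes; their
#' functional targets are drawn from the up_up/up_down gene pools
#' (down_down regulators -> up_up targets, down_up -> up_down), so the
#' planted anti-correlation reinforces, never contradicts, the targets'
#' planted trajectories. Decoy map edges point to genes with no planted
#' effect; non-regulator miRNAs receive decoy-only edges so the map does
#' not leak regulator identity.
#'
#' All draws derive from `config$seed` in a fixed order (gene baselines,
#' libraries, class assignment, miRNA baselines, target map, miRNA counts,
#' mRNA counts), so an identical config reproduces bit-identical output.
#'
#' @param config a [sim_config()] object.
#' @return list of class `sim_dataset` with elements `mrna_counts`,
#'   `mirna_counts` (matrices), `design` (data.frame), `target_map`
#'   (data.frame: mirna_id, target_gene_id, evidence), and `truth` (list:
#'   per-gene `gene_class`, `gene_lfc_diff`, `gene_lfc_geno`; per-miRNA
#'   `mirna_class`; `regulators`; per-edge `edge_functional`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  design <- build_design(config)
  S <- nrow(design)
  x_ra  <- as.numeric(design$stage == "RA")
  x_dko <- as.numeric(design$genotype == "dKO")

  gene_ids  <- sprintf("gene%05d", seq_len(config$n_genes))
  mirna_ids <- sprintf("mir%04d", seq_len(config$n_mirnas))

  ## 1. gene baselines (relative abundances)
  q_g <- stats::rlnorm(config$n_genes, config$baseline_meanlog,
                       config$baseline_sdlog)
  q_g <- q_g / sum(q_g)

  ## 2. library sizes
  lib_mrna  <- rlnorm_mean_cv(S, config$lib_size_mean, config$lib_size_cv)
  lib_mirna <- rlnorm_mean_cv(S, config$lib_size_mean, config$lib_size_cv)

  ## 3. planted gene effects and classes
  n_up   <- round(config$frac_diff_up * config$n_genes)
  n_down <- round(config$frac_diff_down * config$n_genes)
  diff_idx <- sample.int(config$n_genes, n_up + n_down)
  up_idx   <- diff_idx[seq_len(n_up)]
  down_idx <- setdiff(diff_idx, up_idx)
  L_diff <- numeric(config$n_genes)
  L_diff[up_idx]   <-  config$effect_lfc_diff
  L_diff[down_idx] <- -config$effect_lfc_diff
  L_geno <- numeric(config$n_genes)
  pick_geno <- function(idx) {
    k <- round(config$frac_geno_effect * length(idx))
    if (k < 1) return(integer(0))
    sample(idx, k)
  }
  geno_idx <- c(pick_geno(up_idx), pick_geno(down_idx))
  if (length(geno_idx))
    L_geno[geno_idx] <- config$effect_lfc_geno *
      sample(c(-1, 1), length(geno_idx), replace = TRUE)
  gene_class <- rep("none", config$n_genes)
  gene_class[L_diff > 0 & L_geno > 0] <- "up_up"
  gene_class[L_diff > 0 & L_geno < 0] <- "up_down"
  gene_class[L_diff < 0 & L_geno > 0] <- "down_up"
  gene_class[L_diff < 0 & L_geno < 0] <- "down_down"

  ## 4. miRNA baselines and planted regulators
  q_m <- stats::rlnorm(config$n_mirnas, config$baseline_meanlog,
                       config$baseline_sdlog)
  q_m <- q_m / sum(q_m)
  Lm_diff <- numeric(config$n_mirnas)
  Lm_geno <- numeric(config$n_mirnas)
  mirna_class <- rep("none", config$n_mirnas)
  reg_idx <- integer(0)
  if (config$n_regulator_mirnas > 0) {
    reg_idx <- sample.int(config$n_mirnas, config$n_regulator_mirnas)
    n_dd <- ceiling(config$n_regulator_mirnas / 2)
    dd_idx <- reg_idx[seq_len(n_dd)]
    du_idx <- setdiff(reg_idx, dd_idx)
    Lm_diff[reg_idx] <- -config$effect_lfc_diff
    Lm_geno[dd_idx] <- -config$effect_lfc_geno
    Lm_geno[du_idx] <-  config$effect_lfc_geno
    mirna_class[dd_idx] <- "down_down"
    mirna_class[du_idx] <- "down_up"
  }

  ## latent (noise-free) miRNA log2 abundance, standardized per miRNA
  latent <- log2(q_m) +
    outer(Lm_diff, x_ra) + outer(Lm_geno, x_dko)   # miRNA x sample
  z_lat <- t(apply(latent, 1, function(a) {
    s <- stats::sd(a)
    if (s < 1e-12) rep(0, length(a)) else (a - mean(a)) / s
  }))

  ## 5. target map
  null_pool <- which(L_diff == 0 & L_geno == 0)
  pool_uu <- which(gene_class == "up_up")
  pool_ud <- which(gene_class == "up_down")
  n_func <- round(config$targets_per_mirna * (1 - config$decoy_target_fraction))
  edges <- vector("list", config$n_mirnas)
  functional <- vector("list", config$n_mirnas)
  for (m in seq_len(config$n_mirnas)) {
    if (m %in% reg_idx && n_func > 0) {
      pool <- if (mirna_class[m] == "down_down") pool_uu else pool_ud
      if (length(pool) < n_func)
        stop("not enough planted up-class genes for functional targets; ",
             "increase frac_geno_effect or n_genes")
      func <- sample(pool, n_func)
      deco <- sample(null_pool, config$targets_per_mirna - n_func)
      edges[[m]] <- c(func, deco)
      functional[[m]] <- c(rep(TRUE, n_func),
                           rep(FALSE, config$targets_per_mirna - n_func))
    } else {
      edges[[m]] <- sample(null_pool, config$targets_per_mirna)
      functional[[m]] <- rep(FALSE, config$targets_per_mirna)
    }
  }
  target_map <- data.frame(
    mirna_id = rep(mirna_ids, lengths(edges)),
    target_gene_id = gene_ids[unlist(edges)],
    evidence = "curated",
    stringsAsFactors = FALSE)
  edge_functional <- unlist(functional)

  ## repression term per gene x sample (sum over functional regulators)
  repress <- matrix(0, config$n_genes, S)
  if (config$repression_strength > 0) {
    for (m in reg_idx) {
      tg <- edges[[m]][functional[[m]]]
      if (length(tg))
        repress[tg, ] <- repress[tg, ] +
          config$repression_strength * matrix(z_lat[m, ], length(tg), S,
                                              byrow = TRUE)
    }
  }

  ## 6. counts: miRNAs first, then mRNAs (documented draw order)
  size <- 1 / config$dispersion_true
  mu_mirna <- sweep(2^(outer(Lm_diff, x_ra) + outer(Lm_geno, x_dko)) * q_m,
                    2, lib_mirna, `*`)
  mirna_counts <- matrix(
    stats::rnbinom(length(mu_mirna), size = size, mu = mu_mirna),
    nrow = config$n_mirnas, dimnames = list(mirna_ids, design$sample_id))

  log2mu <- outer(L_diff, x_ra) + outer(L_geno, x_dko) - repress
  mu_mrna <- sweep(2^log2mu * q_g, 2, lib_mrna, `*`)
  mrna_counts <- matrix(
    stats::rnbinom(length(mu_mrna), size = size, mu = mu_mrna),
    nrow = config$n_genes, dimnames = list(gene_ids, design$sample_id))

  truth <- list(
    gene_class = stats::setNames(gene_class, gene_ids),
    gene_lfc_diff = stats::setNames(L_diff, gene_ids),
    gene_lfc_geno = stats::setNames(L_geno, gene_ids),
    mirna_class = stats::setNames(mirna_class, mirna_ids),
    regulators = mirna_ids[sort(reg_idx)],
    edge_functional = edge_functional)

  structure(list(mrna_counts = mrna_counts, mirna_counts = mirna_counts,
                 design = design, target_map = target_map, truth = truth,
                 config = config),
            class = "sim_dataset")
}

#' Write a simulated dataset to a directory of TSV files
#'
#' Writes mrna_counts.tsv, mirna_counts.tsv, design.tsv, targets.tsv and
#' truth.tsv (per-feature truth labels plus a regulator flag).
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(mrna = file.path(dir, "mrna_counts.tsv"),
         mirna = file.path(dir, "mirna_counts.tsv"),
         design = file.path(dir, "design.tsv"),
         targets = file.path(dir, "targets.tsv"),
         truth = file.path(dir, "truth.tsv"),
         truth_edges = file.path(dir, "truth_edges.tsv"))
  write_counts_tsv(dataset$mrna_counts, p["mrna"])
  write_counts_tsv(dataset$mirna_counts, p["mirna"])
  utils::write.table(dataset$design, p["design"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$target_map, p["targets"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- dataset$truth
  truth_df <- rbind(
    data.frame(feature_id = names(tr$gene_class), feature_type = "gene",
               true_class = unname(tr$gene_class),
               lfc_diff = unname(tr$gene_lfc_diff),
               lfc_geno = unname(tr$gene_lfc_geno),
               regulator = FALSE, stringsAsFactors = FALSE),
    data.frame(feature_id = names(tr$mirna_class), feature_type = "mirna",
               true_class = unname(tr$mirna_class),
               lfc_diff = NA_real_, lfc_geno = NA_real_,
               regulator = names(tr$mirna_class) %in% tr$regulators,
               stringsAsFactors = FALSE))
  utils::write.table(truth_df, p["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  edge_df <- dataset$target_map[, c("mirna_id", "target_gene_id")]
  edge_df$functional <- dataset$truth$edge_functional
  utils::write.table(edge_df, p["truth_edges"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(p)
}
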