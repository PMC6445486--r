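#' Default pipeline configuration
#'
#' Flat list of every analysis threshold with its standard default:
#' `dispersion` 0.1, `p_max` 0.05, `lfc_min` 0.75, `logcpm_min` 0 for DE
#' calling; `prior_count` 0.5 for log-CPM; `min_targets` 5 and
#' `wilcoxon_p` 0.05 for regulator nomination. `sim` holds the
#' [sim_config()] used when `simulate` is TRUE; otherwise `mrna_counts`,
#' `mirna_counts`, `design`, `targets` must point to input TSV files.
#' `gene_sets` may name a GMT file for class enrichment.
#'
#' @param ... overrides for any top-level key or [sim_config()] argument.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  sim_args <- over[names(over) %in% names(formals(sim_config))]
  cfg <- list(simulate = TRUE,
              mrna_counts = NA_character_, mirna_counts = NA_character_,
              design = NA_character_, targets = NA_character_,
              gene_sets = NA_character_,
              dispersion = 0.1, p_max = 0.05, lfc_min = 0.75,
              logcpm_min = 0, prior_count = 0.5,
              min_targets = 5, wilcoxon_p = 0.05,
              sim = do.call(sim_config, sim_args))
  rest <- over[!names(over) %in% names(formals(sim_config))]
  bad <- setdiff(names(rest), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(rest)] <- rest
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a flat key=value pipeline configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Keys are the
#' top-level [pipeline_config()] keys plus any [sim_config()] argument.
#'
#' @param path file path.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- lapply(kv, function(x) {
    v <- x[2]
    if (v %in% c("TRUE", "FALSE", "true", "false"))
      return(as.logical(toupper(v)))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  do.call(pipeline_config, stats::setNames(vals, keys))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Fixed stage order: simulate (or load) -> TMM normalization and log-CPM
#' -> NB exact tests for the differentiation and genotype contrasts (mRNA
#' and miRNA) -> DE calling -> four-class trajectory assignment ->
#' miRNA-target correlations, shift test and regulator nomination ->
#' optional class enrichment -> recovery scoring against planted truth
#' (simulated inputs only). Every intermediate table is written to
#' `out_dir`; `log.txt` records per-stage feature counts and
#' `run_info.txt` the seed, config hash and session versions. For a fixed
#' config and seed all result tables are byte-identical across runs
#' (`run_info.txt` carries the only timestamp).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if needed.
#' @return invisible list with all in-memory results and `paths` of the
#'   written files.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  ## stage 1: inputs
  truth <- NULL
  if (isTRUE(config$simulate)) {
    ds <- simulate_dataset(config$sim)
    mrna <- ds$mrna_counts; mirna <- ds$mirna_counts
    design <- ds$design; target_map <- ds$target_map
    truth <- ds$truth
    note("input: simulated dataset, seed ", config$sim$seed)
  } else {
    for (key in c("mrna_counts", "mirna_counts", "design", "targets"))
      if (is.na(config[[key]]) || !file.exists(config[[key]]))
        stop("stage input: missing file for '", key, "': ", config[[key]])
    mrna <- read_counts_tsv(config$mrna_counts)
    mirna <- read_counts_tsv(config$mirna_counts)
    design <- read_design_tsv(config$design)
    target_map <- read_target_map(config$targets)
    note("input: loaded from files")
  }
  if (!setequal(design$sample_id, colnames(mrna)) ||
      !identical(colnames(mrna), colnames(mirna)))
    stop("stage input: design/count sample ids are inconsistent")
  note("features: ", nrow(mrna), " genes, ", nrow(mirna), " miRNAs, ",
       nrow(design), " samples, ", nrow(target_map), " map edges")

  ## stage 2: normalization
  f_mrna <- tmm_factors(mrna)
  f_mirna <- tmm_factors(mirna)
  lcpm_mrna <- log_cpm(mrna, f_mrna, config$prior_count)
  lcpm_mirna <- log_cpm(mirna, f_mirna, config$prior_count)
  z_mrna <- standardize_features(lcpm_mrna)
  z_mirna <- standardize_features(lcpm_mirna)
  note("normalization: TMM factors in [",
       sprintf("%.3f", min(f_mrna, f_mirna)), ", ",
       sprintf("%.3f", max(f_mrna, f_mirna)), "]")

  ## stage 3: differential expression
  contrasts <- default_contrasts(design)
  de <- list()
  calls <- list()
  for (feat in c("mrna", "mirna")) {
    counts <- if (feat == "mrna") mrna else mirna
    for (cn in names(contrasts)) {
      tab <- nb_exact_test(counts, contrasts[[cn]],
                           dispersion = config$dispersion,
                           prior_count = config$prior_count)
      key <- paste(feat, cn, sep = "_")
      de[[key]] <- tab
      calls[[key]] <- call_de(tab, config$p_max, config$lfc_min,
                              config$logcpm_min)
      note("de ", key, ": ", length(calls[[key]]$up), " up, ",
           length(calls[[key]]$down), " down of ", nrow(tab))
    }
  }

  ## stage 4: trajectory classes
  classes_mrna <- classify_features(calls$mrna_differentiation,
                                    calls$mrna_genotype)
  classes_mirna <- classify_features(calls$mirna_differentiation,
                                     calls$mirna_genotype)
  traj <- withCallingHandlers(
    class_trajectories(z_mrna, design, classes_mrna),
    warning = function(w) {
      note("trajectories: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  note("classes mrna: ",
       paste(names(table(classes_mrna$class)), table(classes_mrna$class),
             sep = "=", collapse = " "))
  note("classes mirna: ",
       paste(names(table(classes_mirna$class)), table(classes_mirna$class),
             sep = "=", collapse = " "))

  ## stage 5: miRNA regulators
  pairs <- suppressMessages(pair_correlations(z_mirna, z_mrna, target_map))
  shift <- regulator_shift_test(pairs, config$min_targets)
  regulators <- nominate_regulators(shift, classes_mirna, classes_mrna,
                                    pairs, config$wilcoxon_p)
  note("regulators: ", sum(regulators$candidate), " candidates among ",
       nrow(regulators), " tested miRNAs (",
       length(attr(shift, "omitted")), " below min_targets)")

  ## stage 6: optional class enrichment
  enrichment <- NULL
  universe <- de$mrna_differentiation$feature_id[
    de$mrna_differentiation$logCPM > config$logcpm_min]
  if (!is.na(config$gene_sets)) {
    sets <- read_gene_sets(config$gene_sets)
    queries <- split(classes_mrna$feature_id, classes_mrna$class)
    queries <- queries[setdiff(names(queries), "unclassified")]
    queries <- lapply(queries, intersect, universe)
    enrichment <- enrich_collection(queries[lengths(queries) > 0],
                                    sets, universe)
    note("enrichment: ", nrow(enrichment), " query x set records")
  }

  ## stage 7: recovery vs planted truth
  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- evaluate_recovery(truth, regulators, classes_mrna,
                                  de_tables = de[c("mrna_differentiation",
                                                   "mrna_genotype")])
    note("recovery: recall ", sprintf("%.3f", recovery$regulator_recall),
         ", precision ", ifelse(is.na(recovery$regulator_precision), "NA",
                                sprintf("%.3f", recovery$regulator_precision)))
  }

  ## outputs
  paths <- c()
  cfg_path <- file.path(out_dir, "config.tsv")
  flat <- config[setdiff(names(config), "sim")]
  cfg_df <- data.frame(
    key = c(names(flat), paste0("sim.", names(unclass(config$sim)))),
    value = c(vapply(flat, as.character, ""),
              vapply(unclass(config$sim), as.character, "")),
    stringsAsFactors = FALSE)
  write_tsv(cfg_df, cfg_path)
  paths["config"] <- cfg_path
  for (key in names(de))
    paths[paste0("de_", key)] <-
      write_tsv(de[[key]], file.path(out_dir, paste0("de_", key, ".tsv")))
  paths["classes_mrna"] <- write_tsv(classes_mrna,
                                     file.path(out_dir, "classes_mrna.tsv"))
  paths["classes_mirna"] <- write_tsv(classes_mirna,
                                      file.path(out_dir, "classes_mirna.tsv"))
  paths["trajectories"] <- write_tsv(traj,
                                     file.path(out_dir, "trajectories.tsv"))
  paths["pair_correlations"] <-
    write_tsv(pairs, file.path(out_dir, "pair_correlations.tsv"))
  reg_out <- regulators
  paths["regulators"] <- write_tsv(reg_out,
                                   file.path(out_dir, "regulators.tsv"))
  if (!is.null(enrichment))
    paths["enrichment"] <- write_tsv(enrichment,
                                     file.path(out_dir, "enrichment.tsv"))
  if (!is.null(recovery)) {
    rec_df <- data.frame(metric = c("regulator_recall",
                                    "regulator_precision",
                                    "null_de_rate_mrna_differentiation",
                                    "null_de_rate_mrna_genotype"),
                         value = c(recovery$regulator_recall,
                                   recovery$regulator_precision,
                                   recovery$null_de_rate),
                         stringsAsFactors = FALSE)
    paths["recovery"] <- write_tsv(rec_df, file.path(out_dir, "recovery.tsv"))
    paths["class_metrics"] <-
      write_tsv(recovery$class_metrics,
                file.path(out_dir, "class_metrics.tsv"))
  }
  paths["log"] <- file.path(out_dir, "log.txt")
  writeLines(log_lines, paths["log"])
  info <- c(paste0("package_version=", as.character(
                     utils::packageVersion("mirtraj"))),
            paste0("r_version=", R.version.string),
            paste0("config_hash=", unname(tools::md5sum(cfg_path))),
            paste0("seed=", config$sim$seed),
            paste0("timestamp=", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  writeLines(info, file.path(out_dir, "run_info.txt"))

  invisible(list(de = de, calls = calls, classes_mrna = classes_mrna,
                 classes_mirna = classes_mirna, trajectories = traj,
                 pairs = pairs, shift = shift, regulators = regulators,
                 enrichment = enrichment, recovery = recovery,
                 truth = truth, design = design, paths = paths))
}

#' Score recovery of planted structure
#'
#' Exact set arithmetic against the simulator's truth ledger: regulator
#' recall (nominated true regulators / true regulators) and precision
#' (true among nominated; NA when nothing is nominated), per-class
#' sensitivity and specificity of the gene classification, and, when DE
#' tables are supplied, the raw-p < 0.05 rate among truth-null genes per
#' contrast.
#'
#' @param truth the `truth` element of a [simulate_dataset()] result.
#' @param regulators a [nominate_regulators()] result.
#' @param classes the mRNA [classify_features()] result.
#' @param de_tables optional named list of [nb_exact_test()] tables.
#' @param p_null p threshold for the null-gene type-I rate.
#' @return list: regulator_recall, regulator_precision, class_metrics
#'   (data.frame), null_de_rate (named vector or NULL).
#' @export
evaluate_recovery <- function(truth, regulators, classes,
                              de_tables = NULL, p_null = 0.05) {
  if (is.null(truth) || is.null(truth$gene_class) ||
      !length(truth$gene_class))
    stop("empty truth ledger")
  stopifnot(inherits(regulators, "regulator_table"),
            inherits(classes, "class_assignment"))
  nominated <- regulators$mirna_id[regulators$candidate]
  true_reg <- truth$regulators
  recall <- if (length(true_reg))
    length(intersect(nominated, true_reg)) / length(true_reg) else NA_real_
  precision <- if (length(nominated))
    length(intersect(nominated, true_reg)) / length(nominated) else NA_real_

  truth_cls <- truth$gene_class[classes$feature_id]
  called_cls <- stats::setNames(classes$class, classes$feature_id)
  four <- c("up_up", "up_down", "down_up", "down_down")
  class_metrics <- do.call(rbind, lapply(four, function(cl) {
    pos <- names(truth_cls)[truth_cls == cl]
    neg <- names(truth_cls)[truth_cls != cl]
    data.frame(class = cl, n_true = length(pos),
               sensitivity = if (length(pos))
                 mean(called_cls[pos] == cl) else NA_real_,
               specificity = if (length(neg))
                 mean(called_cls[neg] != cl) else NA_real_,
               stringsAsFactors = FALSE)
  }))

  null_de_rate <- NULL
  if (!is.null(de_tables)) {
    null_genes <- names(truth$gene_class)[truth$gene_class == "none" &
                                            truth$gene_lfc_diff == 0 &
                                            truth$gene_lfc_geno == 0]
    null_de_rate <- vapply(de_tables, function(tab) {
      sub <- tab[tab$feature_id %in% null_genes, ]
      mean(sub$pvalue < p_null)
    }, numeric(1))
  }

  list(regulator_recall = recall, regulator_precision = precision,
       class_metrics = class_metrics, null_de_rate = null_de_rate)
}
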