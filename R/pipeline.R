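#' Configure an end-to-end pipeline run
#'
#' Exactly one input source must be given: either file paths (count table,
#' tree, metadata) or a [scenario_config()] describing a synthetic dataset.
#' Every stochastic stage derives its seed deterministically from `seed`
#' (rarefaction `seed + 10`, NRI `seed + 11`, betaNRI `seed + 12`, RC_bray
#' `seed + 13`, correlogram `seed + 14`), so a config reproduces its outputs
#' byte for byte.
#'
#' @param table_path,tree_path,metadata_path Input file paths
#'   (`metadata_path` optional; required for month grouping and signal).
#' @param scenario A [scenario_config()], mutually exclusive with the paths.
#' @param depth Rarefaction depth: `"min"` (the smallest sample total, the
#'   conventional choice) or a positive integer.
#' @param n_reps Null-model randomizations for NRI, betaNRI and RC_bray
#'   (default 999).
#' @param thresholds A [classification_thresholds()] object.
#' @param grouping Grouping for process summaries: `"all"` or `"month"`.
#' @param signal_variable Environmental variable for the phylogenetic-signal
#'   stage, or `NULL` to skip it.
#' @param out_dir Output directory.
#' @param seed Global integer seed.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(table_path = NULL, tree_path = NULL,
                       metadata_path = NULL, scenario = NULL,
                       depth = "min", n_reps = 999L,
                       thresholds = classification_thresholds(),
                       grouping = c("all", "month"),
                       signal_variable = NULL,
                       out_dir = "ecoassembly_run", seed = 1L) {
  grouping <- match.arg(grouping)
  have_paths <- !is.null(table_path) || !is.null(tree_path) ||
    !is.null(metadata_path)
  if (have_paths && !is.null(scenario)) {
    stop("give either input paths or a scenario_config, not both")
  }
  if (!have_paths && is.null(scenario)) {
    stop("give input paths or a scenario_config")
  }
  if (have_paths && (is.null(table_path) || is.null(tree_path))) {
    stop("file input needs both table_path and tree_path")
  }
  if (!is.null(scenario)) stopifnot(inherits(scenario, "scenario_config"))
  if (!identical(depth, "min") && (!is.numeric(depth) || depth < 1)) {
    stop("depth must be \"min\" or a positive integer")
  }
  structure(list(table_path = table_path, tree_path = tree_path,
                 metadata_path = metadata_path, scenario = scenario,
                 depth = depth, n_reps = as.integer(n_reps),
                 thresholds = thresholds, grouping = grouping,
                 signal_variable = signal_variable,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full assembly-inference pipeline
#'
#' Loads (or simulates) the inputs, validates their consistency, rarefies
#' the count table to uniform depth, computes alpha diversity and NRI,
#' pairwise betaNRI and RC_bray, classifies every sample pair into one of
#' the five assembly processes, summarizes process fractions, and (when an
#' environmental variable is named) tests for phylogenetic signal with a
#' Mantel correlogram. All artifacts are written as TSV/JSON under
#' `cfg$out_dir` together with a run log recording every seed and every
#' dropped sample or taxon. When the input is synthetic, a
#' truth-versus-inferred confusion table is also emitted.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory results (`table`, `alpha`,
#'   `turnover`, `summary`, `correlogram`, `confusion`, `paths`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("ecoassembly run, global seed %d", cfg$seed),
                 sprintf("n_reps = %d, grouping = %s", cfg$n_reps, cfg$grouping))
  truth <- NULL
  if (!is.null(cfg$scenario)) {
    ds <- assemble_communities(cfg$scenario)
    inputs <- write_synthetic_dataset(ds, file.path(cfg$out_dir, "inputs"))
    table <- ds$table; tree <- ds$tree; metadata <- ds$metadata
    truth <- ds$truth
    log_lines <- c(log_lines,
                   sprintf("simulated scenario '%s' (seed %d) -> inputs/",
                           cfg$scenario$scenario, cfg$scenario$seed))
  } else {
    table <- read_community_table(cfg$table_path)
    tree <- read_phylogeny(cfg$tree_path)
    metadata <- if (!is.null(cfg$metadata_path)) {
      read_sample_metadata(cfg$metadata_path)
    } else NULL
  }
  report <- validate_consistency(table, tree, metadata)
  if (!report$is_valid) {
    stop("input validation failed: ",
         length(report$taxa_missing_from_tree), " taxa missing from tree, ",
         length(report$samples_missing_metadata), " samples without metadata")
  }
  depth <- if (identical(cfg$depth, "min")) min(colSums(table)) else
    as.integer(cfg$depth)
  rare <- withCallingHandlers(
    rarefy_table(table, depth, seed = cfg$seed + 10L),
    message = function(m) {
      log_lines <<- c(log_lines, sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  log_lines <- c(log_lines,
                 sprintf("rarefied to depth %d (seed %d): %d taxa x %d samples kept",
                         depth, cfg$seed + 10L, nrow(rare), ncol(rare)))
  paths <- c(rarefied = write_tsv(
    data.frame(taxon_id = rownames(rare), rare, check.names = FALSE),
    file.path(cfg$out_dir, "rarefied_counts.tsv")))

  alpha <- alpha_diversity(rare)
  alpha$faith_pd <- as.numeric(faith_pd(rare, tree))
  nri_res <- nri(rare, tree, n_reps = cfg$n_reps, seed = cfg$seed + 11L)
  alpha <- merge(alpha, nri_res[c("sample_id", "mpd_obs", "null_mean",
                                  "null_sd", "nri")],
                 by = "sample_id", sort = TRUE)
  paths["alpha"] <- write_tsv(alpha, file.path(cfg$out_dir, "alpha_diversity.tsv"))

  bn <- beta_nri(rare, tree, n_reps = cfg$n_reps, seed = cfg$seed + 12L)
  rc <- raup_crick_bray(rare, n_reps = cfg$n_reps, seed = cfg$seed + 13L)
  turnover <- data.frame(bn[c("sample_a", "sample_b", "beta_mpd_obs",
                              "beta_nri")],
                         rc[c("bray_curtis_obs", "rc_bray")],
                         n_reps = cfg$n_reps, stringsAsFactors = FALSE)
  turnover$process <- classify_pair(turnover$beta_nri, turnover$rc_bray,
                                    cfg$thresholds)
  paths["turnover"] <- write_tsv(turnover,
                                 file.path(cfg$out_dir, "pairwise_turnover.tsv"))

  summary_df <- summarize_processes(turnover, metadata = metadata,
                                    grouping = cfg$grouping,
                                    thresholds = cfg$thresholds)
  paths["summary"] <- write_tsv(summary_df,
                                file.path(cfg$out_dir, "process_summary.tsv"))
  jsonlite::write_json(
    list(thresholds = unclass(cfg$thresholds), grouping = cfg$grouping,
         n_reps = cfg$n_reps, seed = cfg$seed,
         n_pairs = nrow(turnover),
         n_flagged_undefined = sum(is.na(turnover$process)),
         summary = summary_df),
    file.path(cfg$out_dir, "process_summary.json"),
    auto_unbox = TRUE, digits = NA)
  paths["summary_json"] <- file.path(cfg$out_dir, "process_summary.json")

  correlogram <- NULL
  if (!is.null(cfg$signal_variable)) {
    if (is.null(metadata)) stop("signal stage needs metadata")
    niche <- withCallingHandlers(
      niche_values(rare, metadata, cfg$signal_variable),
      message = function(m) {
        log_lines <<- c(log_lines, sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
    D <- cophenetic_matrix(tree)[names(niche), names(niche)]
    nd <- as.matrix(stats::dist(niche))
    correlogram <- mantel_correlogram(D, nd, n_permutations = cfg$n_reps,
                                      seed = cfg$seed + 14L)
    paths["correlogram"] <- write_tsv(as.data.frame(correlogram),
                                      file.path(cfg$out_dir, "correlogram.tsv"))
  }

  confusion <- NULL
  if (!is.null(truth)) {
    merged <- merge(turnover, truth, by = c("sample_a", "sample_b"))
    confusion <- as.data.frame.matrix(
      table(expected = merged$expected_process, inferred = merged$process))
    confusion <- cbind(expected = rownames(confusion), confusion)
    paths["confusion"] <- write_tsv(confusion,
                                    file.path(cfg$out_dir, "confusion.tsv"))
  }
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  paths["log"] <- file.path(cfg$out_dir, "run_log.txt")
  invisible(list(table = rare, alpha = alpha, turnover = turnover,
                 summary = summary_df, correlogram = correlogram,
                 confusion = confusion, paths = paths))
}
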