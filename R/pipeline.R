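# End-to-end orchestration: configuration, the simulate -> preprocess ->
# evaluate -> tree -> bag -> accuracy sequence, tree serialization, and
# the banded-circle tree visualization description.

#' Default pipeline configuration
#'
#' @param seed master seed; each stage derives its own seed from it.
#' @param n cohort size to simulate.
#' @param spec a [tree_spec()] (default: the standard eight-leaf
#'   generator).
#' @param use_mirna include the miRNA levels among the tree predictors;
#'   `FALSE` gives the clinical-only model for paired comparisons.
#' @param fit_config a [tree_config()].
#' @param n_iterations bagging iterations.
#' @param horizon iAUC horizon in months (`NULL` = end of follow-up).
#' @param definition_id IRV definition.
#' @param mi_m imputed datasets for the chained-MI Cox fits.
#' @param stages character vector of stages to run, in order, from
#'   `simulate`, `preprocess`, `evaluate`, `tree`, `bag`, `accuracy`.
#' @param cohort_file optional CSV path to load instead of simulating.
#' @param out_dir optional directory for TSV/JSON artifacts.
#' @return a named list of class `hd_run_config`.
#' @export
run_config <- function(seed = 1, n = 400, spec = tree_spec(),
                       use_mirna = TRUE, fit_config = tree_config(),
                       n_iterations = 200, horizon = NULL,
                       definition_id = "wtd_abs_dev", mi_m = 20,
                       stages = c("simulate", "preprocess", "evaluate",
                                  "tree", "bag", "accuracy"),
                       cohort_file = NULL, out_dir = NULL) {
  structure(list(seed = seed, n = n, spec = spec, use_mirna = use_mirna,
                 fit_config = fit_config, n_iterations = n_iterations,
                 horizon = horizon, definition_id = definition_id,
                 mi_m = mi_m, stages = stages, cohort_file = cohort_file,
                 out_dir = out_dir),
            class = "hd_run_config")
}

clinical_predictors <- function() {
  c("age", "albumin", "hscrp", "hist_cvd", "hist_diabetes")
}

mirna_predictors <- function() {
  c("miR_632", "miR_186_5p", "miR_210_3p")
}

#' Run the full risk-stratification pipeline
#'
#' Executes the configured stages in sequence on one cohort: simulate
#' (or load), inject phase-II-style missingness, per-miRNA biomarker
#' evaluation (group comparisons, Cox models under complete-case /
#' median / chained-MI strategies, ROC AUC), survival-tree fitting,
#' bagging, and accuracy indices. Identical configuration and seed give
#' identical results. Artifacts are written under `out_dir` when set.
#'
#' @param config a [run_config()].
#' @return a list with the per-stage results (`cohort`, `evaluation`,
#'   `tree`, `bagging`, `accuracy`, `bands`, `summary`); `summary` is a
#'   flat, JSON-ready list of the headline numbers, labelled
#'   `"clinical+miRNA"` or `"clinical-only"`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "hd_run_config"))
  if (!is.null(config$cohort_file) && !file.exists(config$cohort_file))
    stop("cohort file not found: ", config$cohort_file)
  seeds <- derive_seeds(config$seed, 6)
  res <- list()
  stage_on <- function(s) s %in% config$stages
  log_stage <- function(s)
    message(format(Sys.time(), "%H:%M:%S"), " stage: ", s)

  # -- simulate / load -------------------------------------------------
  if (!is.null(config$cohort_file)) {
    log_stage("load")
    cohort <- utils::read.csv(config$cohort_file,
                              stringsAsFactors = FALSE)
  } else if (stage_on("simulate")) {
    log_stage("simulate")
    cohort <- generate_cohort(config$spec, config$n, seed = seeds[1])
  } else stop("no cohort: enable the simulate stage or set cohort_file")

  if (stage_on("preprocess") &&
      length(config$spec$missing_rates) > 0 &&
      is.null(config$cohort_file)) {
    log_stage("preprocess")
    cohort <- inject_missingness(cohort, config$spec$missing_rates,
                                 seed = seeds[2])
  }
  res$cohort <- cohort

  predictors <- clinical_predictors()
  if (config$use_mirna) predictors <- c(predictors, mirna_predictors())
  model_label <- if (config$use_mirna) "clinical+miRNA" else
    "clinical-only"

  # -- evaluate --------------------------------------------------------
  if (stage_on("evaluate")) {
    log_stage("evaluate")
    mirnas <- intersect(mirna_predictors(), names(cohort))
    res$evaluation <- list(
      group_comparisons = compare_groups(
        cohort, c(clinical_predictors(), mirnas)),
      cox = do.call(rbind, lapply(mirnas, function(m) {
        do.call(rbind, lapply(
          c("complete_case", "median_impute", "chained_mi"),
          function(st) fit_cox(
            cohort, m, coding = "continuous",
            adjustment_set = c("age", "albumin"),
            missing_strategy = st, m = config$mi_m,
            seed = seeds[3])))
      })),
      auc = do.call(rbind, lapply(mirnas, function(m) {
        cbind(predictor = m,
              roc_auc(cohort[[m]], cohort$case_flag))
      })))
  }

  # -- tree ------------------------------------------------------------
  if (stage_on("tree")) {
    log_stage("tree")
    res$tree <- fit_tree(cohort, predictors, config$fit_config)
  }

  # -- bag -------------------------------------------------------------
  if (stage_on("bag")) {
    if (is.null(res$tree)) stop("stage 'bag' requires stage 'tree'")
    log_stage("bag")
    res$bagging <- run_bagging(
      cohort, predictors, config$fit_config,
      n_iterations = config$n_iterations, seed = seeds[4],
      horizon = config$horizon, definition_id = config$definition_id)
  }

  # -- accuracy --------------------------------------------------------
  if (stage_on("accuracy")) {
    if (is.null(res$tree)) stop("stage 'accuracy' requires stage 'tree'")
    log_stage("accuracy")
    res$accuracy <- accuracy_indices(
      res$tree, cohort, horizon = config$horizon,
      definition_id = config$definition_id)
    res$bands <- render_tree_bands(
      res$tree, horizon = max(cohort$time))
  }

  summary <- list(model = model_label, seed = config$seed,
                  n = nrow(cohort))
  if (!is.null(res$tree)) {
    summary$n_leaves <- nrow(res$tree$leaf_summary)
    summary$leaf_ir <- res$tree$leaf_summary$ir
    summary$split_variables <- unique(tree_split_variables(res$tree))
  }
  if (!is.null(res$accuracy)) {
    summary$iauc <- res$accuracy$iauc
    summary$irv <- res$accuracy$irv
    summary$irv_definition <- res$accuracy$definition_id
  }
  if (!is.null(res$bagging)) {
    summary$oob_error <- res$bagging$oob_error
    summary$iauc_ci <- unname(res$bagging$index_cis$iauc)
    summary$irv_ci <- unname(res$bagging$index_cis$irv)
  }
  res$summary <- summary

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cohort, file.path(config$out_dir, "cohort.csv"),
                     row.names = FALSE)
    if (!is.null(res$tree))
      tree_to_json(res$tree, file.path(config$out_dir, "tree.json"))
    if (!is.null(res$evaluation)) {
      utils::write.table(
        res$evaluation$cox,
        file.path(config$out_dir, "cox_results.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' Banded-circle description of a fitted tree
#'
#' For each node, partitions the follow-up horizon by the times at which
#' the node's Kaplan-Meier survival first drops below 0.8, 0.6, 0.4 and
#' 0.2. Each of the five bands (survival 1.0-0.8, 0.8-0.6, ..., 0.2-0)
#' gets a length proportional to the time patients spend in that survival
#' range, so a node whose survival never leaves 0.8-1.0 is a single band
#' covering the whole horizon. Band lengths per node always sum to the
#' horizon.
#'
#' @param tree an `hd_tree` (nodes carry their training KM curves).
#' @param horizon follow-up horizon in months (> 0).
#' @param thresholds decreasing survival thresholds delimiting the bands.
#' @return `data.frame` with `node_id`, `depth`, `is_leaf`, `band`
#'   (survival range label), `start`, `end`, `length`, `fraction`.
#' @export
render_tree_bands <- function(tree, horizon,
                              thresholds = c(0.8, 0.6, 0.4, 0.2)) {
  if (!is.numeric(horizon) || horizon <= 0)
    stop("horizon must be > 0")
  stopifnot(!is.unsorted(rev(thresholds), strictly = TRUE))
  out <- list()
  for (nd in tree$nodes) {
    if (is.null(nd$km)) {
      warning("node ", nd$node_id, " has no KM curve; skipped")
      next
    }
    cross <- vapply(thresholds, function(thr) {
      i <- which(nd$km$surv < thr)
      if (length(i)) min(nd$km$time[i[1]], horizon) else horizon
    }, numeric(1))
    cuts <- c(0, cummax(cross), horizon)
    lens <- diff(cuts)
    labs <- c(sprintf("%.1f-%.1f", c(1, thresholds),
                      c(thresholds, 0)))
    out[[length(out) + 1L]] <- data.frame(
      node_id = nd$node_id, depth = nd$depth, is_leaf = nd$is_leaf,
      band = labs, start = cuts[-length(cuts)], end = cuts[-1],
      length = lens, fraction = lens / horizon,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Serialize a fitted tree to JSON
#'
#' Writes (or returns) a JSON representation preserving all split rules,
#' surrogates, node summaries, KM curves and the leaf risk ordering;
#' [tree_from_json()] restores a functionally identical `hd_tree`.
#'
#' @param tree an `hd_tree`.
#' @param path output file; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
tree_to_json <- function(tree, path = NULL) {
  nodes <- lapply(tree$nodes, function(nd)
    nd[setdiff(names(nd), "member_idx")])
  obj <- list(nodes = nodes,
              leaf_summary = tree$leaf_summary,
              reference_leaf = tree$reference_leaf,
              config = unclass(tree$config),
              predictors = tree$predictors, n = tree$n)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname tree_to_json
#' @param json a path to a JSON file or a JSON string.
#' @export
tree_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE,
                            simplifyVector = TRUE)
  nodes <- lapply(obj$nodes, function(nd) {
    nd$km <- as.data.frame(nd$km)
    if (!is.null(nd$split)) {
      nd$split <- as.list(nd$split)
      if (!is.null(nd$split$left_categories))
        nd$split$left_categories <- unlist(nd$split$left_categories)
    }
    nd$surrogates <- lapply(nd$surrogates, as.list)
    nd
  })
  ls <- as.data.frame(obj$leaf_summary)
  structure(
    list(nodes = nodes,
         config = do.call(tree_config, obj$config),
         predictors = unlist(obj$predictors), n = obj$n,
         leaf_summary = ls, reference_leaf = obj$reference_leaf),
    class = "hd_tree")
}
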