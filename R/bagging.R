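# Bagging over bootstrap cohorts: variable selection frequency,
# surrogate-aware importance, out-of-bag discrimination error, and
# percentile confidence intervals for the accuracy indices.

# importance credit of one fitted tree: the primary split variable earns
# the split's chi-square improvement; each kept surrogate earns
# improvement x agreement (rpart-like convention)
tree_importance_credit <- function(tree, predictors) {
  imp <- setNames(numeric(length(predictors)), predictors)
  for (nd in tree$nodes) {
    if (nd$is_leaf) next
    s <- nd$split$statistic
    imp[nd$split$variable] <- imp[nd$split$variable] + s
    for (su in nd$surrogates)
      imp[su$variable] <- imp[su$variable] + s * su$agreement
  }
  imp
}

#' Bagging for variable selection and error measurement
#'
#' Repeatedly bootstraps the cohort (whole patients, with replacement),
#' fits a survival tree to each resample, and aggregates across
#' iterations: how often each variable is used in a primary split, its
#' surrogate-aware importance (split-statistic improvement credited to
#' primary and surrogate variables, averaged and normalized so the top
#' variable scores 100), the out-of-bag discrimination error (one minus
#' the iAUC of each patient's average out-of-bag risk prediction), and
#' percentile confidence intervals for the iAUC and IRV of the
#' bootstrap-fitted trees.
#'
#' @param cohort cohort `data.frame` (`time` in months, `event`,
#'   predictors).
#' @param predictors character vector of predictor columns.
#' @param fit_config a [tree_config()].
#' @param n_iterations number of bootstrap iterations (>= 2; 1000 in a
#'   full run).
#' @param seed master seed; per-iteration seeds are derived from it.
#' @param horizon iAUC horizon in months (default: end of follow-up).
#' @param definition_id IRV definition (see [irv_index()]).
#' @param progress_every log progress to stderr every this many
#'   iterations; 0 disables.
#' @return list of class `hd_bagging`: `n_iterations`,
#'   `selection_frequency`, `importance` (top variable = 100),
#'   `oob_error`, `index_cis` (percentile intervals for iAUC and IRV),
#'   `iauc_values`, `irv_values`.
#' @export
run_bagging <- function(cohort, predictors, fit_config = tree_config(),
                        n_iterations = 1000, seed = 1, horizon = NULL,
                        definition_id = "wtd_abs_dev",
                        progress_every = 100) {
  stopifnot(n_iterations >= 2)
  n <- nrow(cohort)
  seeds <- derive_seeds(seed, n_iterations)
  sel_count <- setNames(numeric(length(predictors)), predictors)
  imp_sum <- setNames(numeric(length(predictors)), predictors)
  oob_sum <- numeric(n); oob_n <- numeric(n)
  iauc_values <- rep(NA_real_, n_iterations)
  irv_values <- rep(NA_real_, n_iterations)

  for (it in seq_len(n_iterations)) {
    set.seed(seeds[it])
    idx <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(idx))
    boot <- cohort[idx, , drop = FALSE]
    tree <- tryCatch(
      suppressWarnings(fit_tree(boot, predictors, fit_config)),
      error = function(e) NULL)
    if (is.null(tree)) next
    used <- unique(tree_split_variables(tree))
    sel_count[used] <- sel_count[used] + 1
    imp_sum <- imp_sum + tree_importance_credit(tree, predictors)
    if (length(used) > 0) {  # non-degenerate tree: indices + OOB
      acc <- tryCatch(
        accuracy_indices(tree, boot, horizon = horizon,
                         definition_id = definition_id),
        error = function(e) NULL)
      if (!is.null(acc)) {
        iauc_values[it] <- acc$iauc
        irv_values[it] <- acc$irv
      }
      if (length(oob)) {
        r <- predict_risk(tree, cohort[oob, , drop = FALSE])
        oob_sum[oob] <- oob_sum[oob] + r
        oob_n[oob] <- oob_n[oob] + 1
      }
    }
    if (progress_every > 0 && it %% progress_every == 0)
      message("bagging iteration ", it, "/", n_iterations)
  }

  freq <- sel_count / n_iterations
  imp <- imp_sum / n_iterations
  if (max(imp) > 0) imp <- 100 * imp / max(imp)
  has_oob <- oob_n > 0
  oob_error <- NA_real_
  if (sum(has_oob) > 1 && sum(cohort$event[has_oob]) > 0) {
    oob_risk <- oob_sum[has_oob] / oob_n[has_oob]
    troc <- time_roc(oob_risk, cohort$time[has_oob],
                     cohort$event[has_oob])
    if (nrow(troc) >= 2)
      oob_error <- 1 - integrated_auc(troc, horizon)
  }
  cis <- list(
    iauc = if (sum(is.finite(iauc_values)) >= 20)
      percentile_ci(iauc_values) else c(low = NA_real_, high = NA_real_),
    irv = if (sum(is.finite(irv_values)) >= 20)
      percentile_ci(irv_values) else c(low = NA_real_, high = NA_real_))
  structure(
    list(n_iterations = n_iterations, selection_frequency = freq,
         importance = imp, oob_error = oob_error, index_cis = cis,
         iauc_values = iauc_values, irv_values = irv_values),
    class = "hd_bagging")
}

#' @export
print.hd_bagging <- function(x, ...) {
  cat("Bagging report (", x$n_iterations, " iterations)\n", sep = "")
  tab <- data.frame(selection_frequency = round(x$selection_frequency, 3),
                    importance = round(x$importance, 1))
  print(tab[order(-tab$importance), ])
  cat("OOB error (1 - iAUC):", round(x$oob_error, 4), "\n")
  invisible(x)
}
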