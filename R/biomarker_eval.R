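# Per-biomarker evaluation layer: case/control group comparisons, ROC AUC
# with a DeLong-style variance, and the fold-change screening filter.

#' Case/control group comparisons
#'
#' Compares each variable between cases and controls: continuous
#' variables by the two-sided Wilcoxon rank-sum test (exact when sample
#' sizes permit, as implemented by [stats::wilcox.test()]); categorical
#' variables by Fisher's exact test when any expected cell count is below
#' 5, otherwise by the chi-square test.
#'
#' @param cohort `data.frame` with a logical `case_flag` column.
#' @param variables character vector of column names to compare.
#' @return `data.frame` with one row per variable: `variable`,
#'   `test_name`, `statistic`, `p_value` and formatted `group_summaries`
#'   (median and IQR for continuous, count and percent for categorical).
#'   A variable constant in both groups gets `test_name = "none"` and an
#'   `NA` p-value.
#' @export
compare_groups <- function(cohort, variables) {
  stopifnot("case_flag" %in% names(cohort))
  grp <- cohort$case_flag
  if (!any(grp) || !any(!grp)) stop("both groups must be non-empty")
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    if (is.null(x)) stop("variable not in cohort: ", v)
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2L)
      return(data.frame(variable = v, test_name = "none",
                        statistic = NA_real_, p_value = NA_real_,
                        summary_controls = NA_character_,
                        summary_cases = NA_character_,
                        stringsAsFactors = FALSE))
    if (is.numeric(x)) {
      wt <- suppressWarnings(
        wilcox.test(x[grp & ok], x[!grp & ok], exact = NULL))
      fmt <- function(g) {
        q <- quantile(x[g & ok], c(0.25, 0.5, 0.75), type = 7)
        sprintf("%.2f (%.2f-%.2f)", q[2], q[1], q[3])
      }
      data.frame(variable = v, test_name = "wilcoxon",
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 summary_controls = fmt(!grp), summary_cases = fmt(grp),
                 stringsAsFactors = FALSE)
    } else {
      tab <- table(factor(grp[ok], levels = c(FALSE, TRUE)), x[ok])
      expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      fmt <- function(r) paste(
        sprintf("%d (%.1f%%)", tab[r, ], 100 * tab[r, ] / sum(tab[r, ])),
        collapse = " / ")
      if (any(expd < 5)) {
        ft <- fisher.test(tab)
        data.frame(variable = v, test_name = "fisher",
                   statistic = NA_real_, p_value = ft$p.value,
                   summary_controls = fmt(1), summary_cases = fmt(2),
                   stringsAsFactors = FALSE)
      } else {
        ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
        data.frame(variable = v, test_name = "chi_square",
                   statistic = unname(ct$statistic), p_value = ct$p.value,
                   summary_controls = fmt(1), summary_cases = fmt(2),
                   stringsAsFactors = FALSE)
      }
    }
  })
  do.call(rbind, rows)
}

#' ROC AUC with a DeLong-style confidence interval
#'
#' Estimates the area under the ROC curve as the Mann-Whitney concordance
#' probability with the tie correction (ties count one half), with the
#' asymptotic placement (DeLong) variance for the 95% confidence interval
#' and a two-sided test against AUC = 0.5.
#'
#' @param scores numeric predictor values, higher meaning more case-like.
#' @param labels logical or 0/1 case indicator, same length as `scores`.
#' @return one-row `data.frame`: `auc`, `ci_low`, `ci_high`, `p_value`.
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc  # 1
#' roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  x <- scores[labels]   # cases
  y <- scores[!labels]  # controls
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0) stop("both classes must be present")
  # placements: for each case, fraction of controls it beats (ties = 1/2)
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(cmp)
  v10 <- rowMeans(cmp)  # per-case placement
  v01 <- colMeans(cmp)  # per-control placement
  s2 <- if (m > 1) var(v10) / m else 0
  s2 <- s2 + if (n > 1) var(v01) / n else 0
  se <- sqrt(s2)
  z <- qnorm(0.975)
  p <- if (se > 0) 2 * pnorm(-abs(auc - 0.5) / se)
       else as.numeric(auc == 0.5)
  data.frame(auc = auc,
             ci_low = max(0, auc - z * se),
             ci_high = min(1, auc + z * se),
             p_value = p)
}

#' Screen candidate biomarkers by fold change and significance
#'
#' Keeps features with at least `fc_min`-fold differential expression in
#' either direction (case-vs-control ratio `>= fc_min` or `<= 1/fc_min`)
#' and a p-value strictly below `p_max`, sorted by p-value.
#'
#' @param stats_table `data.frame` with columns `feature`, `fold_change`
#'   (case vs control; > 1 means up in cases) and `p_value`.
#' @param fc_min minimum fold change (default 2.5).
#' @param p_max strict significance cutoff (default 0.05).
#' @param two_sided also accept down-regulation when `TRUE` (default).
#' @return the selected rows, ordered by increasing p-value.
#' @export
screen_candidates <- function(stats_table, fc_min = 2.5, p_max = 0.05,
                              two_sided = TRUE) {
  need <- c("feature", "fold_change", "p_value")
  miss <- setdiff(need, names(stats_table))
  if (length(miss))
    stop("stats_table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(stats_table) == 0) stop("stats_table is empty")
  fc <- stats_table$fold_change
  hit_fc <- fc >= fc_min
  if (two_sided) hit_fc <- hit_fc | fc <= 1 / fc_min
  keep <- hit_fc & stats_table$p_value < p_max
  out <- stats_table[keep, , drop = FALSE]
  out[order(out$p_value), , drop = FALSE]
}
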