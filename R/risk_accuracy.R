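# Accuracy indices for an ordinal risk partition of censored data:
# cumulative/dynamic time-dependent ROC AUC (inverse probability of
# censoring weighting), its integral over a horizon (iAUC), and the
# incidence-rate variation index (IRV).

# Kaplan-Meier estimate of the censoring survival G(t) evaluated just
# before t (left limit), from (time, event)
censor_km <- function(time, event) {
  sf <- survfit(Surv(time, 1 - event) ~ 1)
  step_t <- sf$time; step_s <- sf$surv
  function(t, left = FALSE) {
    tt <- if (left) t - sqrt(.Machine$double.eps) * max(1, abs(t)) else t
    i <- findInterval(tt, step_t)
    ifelse(i == 0, 1, step_s[pmax(i, 1)])
  }
}

#' Cumulative/dynamic time-dependent AUC at one time
#'
#' Discrimination at time `t` between cumulative cases (event by `t`) and
#' dynamic controls (event-free past `t`), estimated by inverse
#' probability of censoring weighting: each case observed at time `T_i`
#' is weighted by `1/G(T_i-)` and each control by `1/G(t)`, with `G` the
#' Kaplan-Meier estimate of the censoring distribution. Ties in the risk
#' score count one half. Without censoring this reduces to the plain
#' Mann-Whitney AUC of the dichotomized outcome.
#'
#' @param risk per-patient risk score (higher = riskier); ordinal or
#'   continuous.
#' @param times,events follow-up times and 0/1 event indicators.
#' @param t evaluation time (same unit as `times`).
#' @return `AUC(t)` in `[0, 1]`, or `NA` when the case or control set at
#'   `t` is empty.
#' @export
cd_auc <- function(risk, times, events, t) {
  stopifnot(length(risk) == length(times), length(times) == length(events))
  cd_auc_impl(risk, times, events, t, censor_km(times, events))
}

# weighted concordance via prefix sums over the sorted control risks;
# O((m + k) log k) instead of the m x k outer product
cd_auc_impl <- function(risk, times, events, t, G) {
  case <- times <= t & events == 1
  ctrl <- times > t
  if (!any(case) || !any(ctrl)) return(NA_real_)
  w_case <- 1 / G(times[case], left = TRUE)
  w_ctrl_tot <- sum(ctrl) / G(t)   # controls share one weight 1/G(t)
  rc <- risk[case]; rk <- sort(risk[ctrl])
  k <- length(rk)
  cw <- seq_len(k) / k * w_ctrl_tot          # uniform control weights
  n_lt <- findInterval(rc, rk, left.open = TRUE)  # controls strictly below
  n_le <- findInterval(rc, rk)                    # controls at or below
  w_lt <- ifelse(n_lt == 0, 0, cw[pmax(n_lt, 1)])
  w_le <- ifelse(n_le == 0, 0, cw[pmax(n_le, 1)])
  num <- sum(w_case * (w_lt + 0.5 * (w_le - w_lt)))
  num / (sum(w_case) * w_ctrl_tot)
}

#' Time-dependent ROC curve over a grid
#'
#' Evaluates [cd_auc()] on a grid of times (by default the distinct event
#' times with at least one subject still at risk beyond them).
#'
#' @inheritParams cd_auc
#' @param grid evaluation times; defaults to the admissible distinct
#'   event times, thinned to at most `max_grid` evenly spaced ones.
#' @param max_grid cap on the default grid size.
#' @param min_group_frac default grid times are restricted to those with
#'   at least this fraction of the sample (never fewer than 20 subjects)
#'   in both the cumulative case set and the dynamic control set; the
#'   IPCW estimator is unstable once either group empties out.
#' @return `data.frame(time, auc)` of class `hd_time_roc`; rows where the
#'   AUC is undefined are dropped.
#' @export
time_roc <- function(risk, times, events, grid = NULL, max_grid = 50,
                     min_group_frac = 0.2) {
  if (is.null(grid)) {
    floor_n <- max(20, min_group_frac * length(times))
    grid <- sort(unique(times[events == 1]))
    n_case <- vapply(grid, function(t)
      sum(times <= t & events == 1), numeric(1))
    n_ctrl <- vapply(grid, function(t) sum(times > t), numeric(1))
    grid <- grid[n_case >= floor_n & n_ctrl >= floor_n]
    if (length(grid) > max_grid)
      grid <- grid[unique(round(seq(1, length(grid),
                                    length.out = max_grid)))]
  }
  stopifnot(!is.unsorted(grid, strictly = TRUE))
  G <- censor_km(times, events)
  auc <- vapply(grid, function(t) cd_auc_impl(risk, times, events, t, G),
                numeric(1))
  out <- data.frame(time = grid, auc = auc)
  out <- out[!is.na(out$auc), , drop = FALSE]
  class(out) <- c("hd_time_roc", "data.frame")
  out
}

#' Integrated time-dependent AUC (iAUC)
#'
#' Trapezoidal average of `AUC(t)` over the grid times up to the horizon,
#' with uniform weighting in `t`.
#'
#' @param troc a [time_roc()] result (`data.frame(time, auc)`).
#' @param horizon upper integration limit (same time unit as the grid);
#'   defaults to the last grid time.
#' @return the integrated AUC, a number in `[0, 1]`.
#' @examples
#' tr <- data.frame(time = 1:5, auc = rep(0.73, 5))
#' integrated_auc(tr)  # 0.73
#' @export
integrated_auc <- function(troc, horizon = NULL) {
  tt <- troc$time; aa <- troc$auc
  if (is.null(horizon)) horizon <- max(tt)
  keep <- tt <= horizon
  if (sum(keep) < 2)
    stop("fewer than 2 grid times at or before the horizon (",
         horizon, ")")
  tt <- tt[keep]; aa <- aa[keep]
  dt <- diff(tt)
  sum(dt * (aa[-1] + aa[-length(aa)]) / 2) / (max(tt) - min(tt))
}

#' Incidence-rate variation index (IRV)
#'
#' Heterogeneity of leaf-level incidence rates around the pooled
#' population rate. With `IR` the pooled incidence rate, `IR_i` and `n_i`
#' the rate and size of leaf `i`:
#' * `wtd_abs_dev` (default): `sum_i (n_i/n) |IR_i - IR|` — same units as
#'   the incidence rate (per 100 patient-years);
#' * `wtd_sd`: size-weighted standard deviation
#'   `sqrt(sum_i (n_i/n) (IR_i - IR)^2)`;
#' * `cv`: `wtd_sd / IR` (dimensionless).
#'
#' @param leaf_table `data.frame` with columns `n`, `events`,
#'   `person_years` (one row per leaf, at least two).
#' @param definition_id which definition to use.
#' @return the index value, with attribute `definition_id`.
#' @examples
#' lt <- data.frame(n = c(10, 10), events = c(5, 15),
#'                  person_years = c(10, 10))
#' irv_index(lt)  # 50
#' @export
irv_index <- function(leaf_table, definition_id = "wtd_abs_dev") {
  known <- c("wtd_abs_dev", "wtd_sd", "cv")
  if (!definition_id %in% known)
    stop("unknown IRV definition '", definition_id, "'; available: ",
         paste(known, collapse = ", "))
  if (nrow(leaf_table) < 2) stop("IRV needs at least 2 leaves")
  if (any(leaf_table$person_years <= 0))
    stop("every leaf needs positive person-time")
  ir_i <- incidence_rate(leaf_table$events, leaf_table$person_years)
  ir <- incidence_rate(sum(leaf_table$events),
                       sum(leaf_table$person_years))
  wt <- leaf_table$n / sum(leaf_table$n)
  val <- switch(definition_id,
    wtd_abs_dev = sum(wt * abs(ir_i - ir)),
    wtd_sd = sqrt(sum(wt * (ir_i - ir)^2)),
    cv = sqrt(sum(wt * (ir_i - ir)^2)) / ir)
  attr(val, "definition_id") <- definition_id
  val
}

#' Accuracy indices of a fitted tree on a cohort
#'
#' Convenience wrapper: scores the cohort by leaf incidence rate, builds
#' the time-dependent ROC, integrates it to the horizon, and computes the
#' IRV of the leaf partition.
#'
#' @param tree an `hd_tree`.
#' @param cohort cohort `data.frame` (`time` in months).
#' @param horizon integration horizon in months (default: end of
#'   follow-up).
#' @param definition_id IRV definition (see [irv_index()]).
#' @return list with `iauc`, `iauc_horizon`, `irv`, `definition_id`,
#'   `time_roc`, `leaf_table`.
#' @export
accuracy_indices <- function(tree, cohort, horizon = NULL,
                             definition_id = "wtd_abs_dev") {
  risk <- predict_risk(tree, cohort)
  troc <- time_roc(risk, cohort$time, cohort$event)
  iauc <- integrated_auc(troc, horizon)
  lt <- node_summaries(tree, cohort)
  irv <- if (nrow(lt) >= 2) irv_index(lt, definition_id) else NA_real_
  list(iauc = iauc,
       iauc_horizon = if (is.null(horizon)) max(troc$time) else horizon,
       irv = as.numeric(irv), definition_id = definition_id,
       time_roc = troc, leaf_table = lt)
}
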