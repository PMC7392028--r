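# Cox associations between a biomarker and the time-to-event endpoint,
# under three missing-data strategies: complete observations, median
# imputation, and chained-equation multiple imputation (predictive mean
# matching) pooled by Rubin's rules.

#' Cox regression for one predictor under a missing-data strategy
#'
#' Fits a Cox proportional-hazards model (Efron tie handling) for one
#' predictor, optionally adjusted for additional covariates, with the
#' time-to-event endpoint in months. The predictor can enter continuously
#' or dichotomized by [binarize()]. Missing values in the adjustment
#' covariates are handled by the requested strategy; `chained_mi` draws
#' `m` completed datasets by chained-equation predictive mean matching and
#' pools the fits by Rubin's rules.
#'
#' @param cohort `data.frame` with `time` (months), `event` (0/1), the
#'   predictor and the adjustment columns.
#' @param predictor column name of the biomarker.
#' @param coding `"continuous"` or one of the binary codings of
#'   [binarize()].
#' @param adjustment_set character vector of adjustment column names.
#' @param missing_strategy one of `"none"`, `"complete_case"`,
#'   `"median_impute"`, `"chained_mi"`. `"none"` and `"complete_case"`
#'   both fit on complete observations (the former is the label used when
#'   the data have no missing values).
#' @param m number of imputed datasets for `chained_mi` (default 100).
#' @param cycles chained-equation burn-in sweeps per dataset (default 10).
#' @param seed integer seed for the imputation draws.
#' @return one-row `data.frame`: `predictor`, `coding`, `coef`, `se`,
#'   `hr`, `ci_low`, `ci_high`, `p_value`, `n_events`, `adjustment_set`,
#'   `missing_strategy`.
#' @export
fit_cox <- function(cohort, predictor,
                    coding = c("continuous", "gt_tertile1", "gt_median",
                               "gt_tertile2"),
                    adjustment_set = character(),
                    missing_strategy = c("none", "complete_case",
                                         "median_impute", "chained_mi"),
                    m = 100, cycles = 10, seed = 1) {
  coding <- match.arg(coding)
  missing_strategy <- match.arg(missing_strategy)
  need <- c("time", "event", predictor, adjustment_set)
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  if (sum(cohort$event, na.rm = TRUE) < 10)
    stop("fewer than 10 events; Cox fit refused")

  x <- cohort[[predictor]]
  if (coding != "continuous") {
    b <- binarize(x, coding)
    x <- as.numeric(b)
  }
  if (length(unique(x[!is.na(x)])) < 2L)
    stop("predictor '", predictor, "' is constant after coding")
  dat <- cohort[, c("time", "event", adjustment_set), drop = FALSE]
  dat$.x <- x

  fml <- as.formula(paste(
    "survival::Surv(time, event) ~ .x",
    if (length(adjustment_set))
      paste("+", paste(adjustment_set, collapse = " + ")) else ""))

  fit_one <- function(d) {
    fit <- coxph(fml, data = d, ties = "efron")
    j <- grep("^\\.x", names(coef(fit)))[1]  # .x or .xTRUE
    c(coef = unname(coef(fit)[j]), var = unname(vcov(fit)[j, j]))
  }

  if (missing_strategy %in% c("none", "complete_case")) {
    cc <- dat[complete.cases(dat), , drop = FALSE]
    if (sum(cc$event) < 10)
      stop("complete-case analysis leaves ", sum(cc$event),
           " events (< 10)")
    est <- fit_one(cc)
    co <- est["coef"]; se <- sqrt(est["var"])
    p <- 2 * pnorm(-abs(co / se))
    lo <- co - qnorm(0.975) * se; hi <- co + qnorm(0.975) * se
    nev <- sum(cc$event)
  } else if (missing_strategy == "median_impute") {
    d <- dat
    for (v in names(d)) {
      if (is.numeric(d[[v]]) && anyNA(d[[v]]))
        d[[v]][is.na(d[[v]])] <- median(d[[v]], na.rm = TRUE)
    }
    est <- fit_one(d)
    co <- est["coef"]; se <- sqrt(est["var"])
    p <- 2 * pnorm(-abs(co / se))
    lo <- co - qnorm(0.975) * se; hi <- co + qnorm(0.975) * se
    nev <- sum(d$event)
  } else {  # chained_mi
    imps <- impute_chained_pmm(dat, m = m, cycles = cycles, seed = seed)
    fits <- vapply(imps, fit_one, numeric(2))
    qbar <- mean(fits["coef", ])
    wbar <- mean(fits["var", ])
    bvar <- if (m > 1) var(fits["coef", ]) else 0
    tvar <- wbar + (1 + 1 / m) * bvar
    se <- sqrt(tvar)
    if (bvar > 0) {
      df <- (m - 1) * (1 + wbar / ((1 + 1 / m) * bvar))^2
      p <- 2 * pt(-abs(qbar / se), df)
      crit <- qt(0.975, df)
    } else {
      p <- 2 * pnorm(-abs(qbar / se))
      crit <- qnorm(0.975)
    }
    co <- qbar; lo <- qbar - crit * se; hi <- qbar + crit * se
    nev <- sum(dat$event)
  }

  data.frame(predictor = predictor, coding = coding,
             coef = unname(co), se = unname(se),
             hr = exp(unname(co)), ci_low = exp(unname(lo)),
             ci_high = exp(unname(hi)), p_value = unname(p),
             n_events = nev,
             adjustment_set = paste(adjustment_set, collapse = "+"),
             missing_strategy = missing_strategy,
             stringsAsFactors = FALSE)
}

#' Chained-equation multiple imputation by predictive mean matching
#'
#' Generates `m` completed copies of a data frame whose numeric columns
#' may contain missing values. Each copy is produced by `cycles` sweeps of
#' chained equations: every incomplete numeric column is regressed on all
#' other columns (plus `event` and `log(time)` when present, so the
#' imputation model respects the outcome), regression parameters are drawn
#' from their approximate Bayesian posterior, and each missing cell
#' receives the observed value of one of the `k` donors whose predicted
#' means are closest to its drawn prediction.
#'
#' With no missing values the input is returned `m` times unchanged.
#'
#' @param data `data.frame`; only numeric columns are imputed.
#' @param m number of completed datasets.
#' @param cycles sweeps of the chained equations per dataset.
#' @param k donor-pool size for predictive mean matching.
#' @param seed integer seed.
#' @return list of `m` completed `data.frame`s.
#' @export
impute_chained_pmm <- function(data, m = 100, cycles = 10, k = 5,
                               seed = 1) {
  targets <- names(data)[vapply(data, function(c)
    is.numeric(c) && anyNA(c), logical(1))]
  if (length(targets) == 0) return(rep(list(data), m))
  nonnum <- names(data)[vapply(data, function(c)
    !is.numeric(c) && anyNA(c), logical(1))]
  if (length(nonnum))
    stop("non-numeric columns with missing values unsupported: ",
         paste(nonnum, collapse = ", "))
  set.seed(seed)
  # outcome enters the imputation model as event + log(time)
  aug <- data
  if (all(c("time", "event") %in% names(data)))
    aug$.logtime <- log(pmax(data$time, .Machine$double.eps))
  miss_idx <- lapply(targets, function(v) which(is.na(data[[v]])))
  names(miss_idx) <- targets

  one_imputation <- function() {
    cur <- aug
    for (v in targets)  # start from random observed draws
      cur[[v]][miss_idx[[v]]] <- sample(data[[v]][!is.na(data[[v]])],
                                        length(miss_idx[[v]]),
                                        replace = TRUE)
    for (cy in seq_len(cycles)) {
      for (v in targets) {
        mis <- miss_idx[[v]]
        obs <- setdiff(seq_len(nrow(cur)), mis)
        rhs <- setdiff(names(cur), v)
        X <- stats::model.matrix(~ ., data = cur[, rhs, drop = FALSE])
        y <- cur[[v]]
        fit <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
        keep <- !is.na(fit$coefficients)
        Xk <- X[, keep, drop = FALSE]
        bhat <- fit$coefficients[keep]
        res <- fit$residuals
        dfres <- max(length(obs) - sum(keep), 1)
        sig2 <- sum(res^2) / rchisq(1, dfres)
        xtx <- crossprod(Xk[obs, , drop = FALSE])
        R <- chol(xtx + diag(1e-8, ncol(xtx)))
        bdot <- bhat + backsolve(R, rnorm(length(bhat))) * sqrt(sig2)
        pred_obs <- drop(Xk[obs, , drop = FALSE] %*% bhat)
        pred_mis <- drop(Xk[mis, , drop = FALSE] %*% bdot)
        for (i in seq_along(mis)) {
          d <- abs(pred_obs - pred_mis[i])
          donors <- obs[order(d)[seq_len(min(k, length(obs)))]]
          cur[[v]][mis[i]] <- y[donors[sample.int(length(donors), 1)]]
        }
      }
    }
    cur$.logtime <- NULL
    cur[, names(data), drop = FALSE]
  }
  lapply(seq_len(m), function(i) one_imputation())
}
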