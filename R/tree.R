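# CART-style recursive partitioning for right-censored outcomes with
# Harrington-Fleming weighted log-rank split statistics, CART surrogate
# splits for missing-value routing, and per-node risk summaries.
#
# Node ids follow the binary-heap convention (root 1, children of k are
# 2k and 2k+1), so a full depth-3 tree has leaves 8..15.

#' Configuration for survival tree fitting
#'
#' @param rho Harrington-Fleming weighting exponent of the split
#'   statistic; 0 (default) is the plain log-rank test.
#' @param min_node_size minimum number of patients in any node.
#' @param max_depth maximum tree depth (3 gives at most 8 leaves).
#' @param min_split_stat minimum chi-square of the best split for a node
#'   to be split at all; the default 3.84 is the 5% critical value of a
#'   1-df chi-square.
#' @param max_cutpoints cap on candidate cutpoints per continuous
#'   variable; when the variable has more distinct values, evenly spaced
#'   midpoints are scanned (the scan is exhaustive below the cap).
#' @param max_surrogates surrogate splits retained per node.
#' @param max_categories categorical predictors with more levels are
#'   refused.
#' @return a list of class `hd_tree_config`.
#' @export
tree_config <- function(rho = 0, min_node_size = 20, max_depth = 3,
                        min_split_stat = 3.84, max_cutpoints = 100,
                        max_surrogates = 5, max_categories = 8) {
  stopifnot(rho >= 0, min_node_size >= 1, max_depth >= 1,
            min_split_stat >= 0, max_cutpoints >= 2)
  structure(list(rho = rho, min_node_size = min_node_size,
                 max_depth = max_depth, min_split_stat = min_split_stat,
                 max_cutpoints = max_cutpoints,
                 max_surrogates = max_surrogates,
                 max_categories = max_categories),
            class = "hd_tree_config")
}

# candidate cutpoints: midpoints between consecutive distinct values,
# thinned to at most max_cutpoints evenly spaced ones
candidate_cutpoints <- function(x, max_cutpoints) {
  v <- sort(unique(x[!is.na(x)]))
  if (length(v) < 2L) return(numeric(0))
  mids <- (v[-1] + v[-length(v)]) / 2
  if (length(mids) > max_cutpoints)
    mids <- mids[unique(round(seq(1, length(mids),
                                  length.out = max_cutpoints)))]
  mids
}

# all binary partitions of factor levels (complement-symmetric halves)
level_partitions <- function(levels) {
  L <- length(levels)
  out <- list()
  for (m in seq_len(2^(L - 1) - 1)) {
    sel <- as.logical(bitwAnd(m, 2^(seq_len(L) - 1)))
    out[[length(out) + 1L]] <- levels[sel]
  }
  out
}

#' Best single-variable split of a censored sample
#'
#' Scans all admissible cutpoints of one variable and returns the split
#' maximizing the G^rho two-sample statistic between the two children,
#' subject to the minimum node size. Continuous (and logical) variables
#' are split at midpoints between consecutive distinct values; factors
#' and character variables at every binary partition of their observed
#' levels. Ties are broken toward the lowest cutoff / first partition.
#'
#' @param cohort `data.frame` with `time` (months), `event` and the
#'   variable.
#' @param variable column name to split on.
#' @param config a [tree_config()].
#' @return a split-rule list (`variable`, `type`, `cutoff` or
#'   `left_categories`, `statistic`, `n_left`, `n_right`) or `NULL` when
#'   no admissible split exists.
#' @export
best_split <- function(cohort, variable, config = tree_config()) {
  x <- cohort[[variable]]
  if (is.null(x)) stop("variable not in cohort: ", variable)
  ok <- !is.na(x) & !is.na(cohort$time) & !is.na(cohort$event)
  time <- cohort$time[ok]; event <- cohort$event[ok]; x <- x[ok]
  if (length(unique(x)) < 2L || sum(event) == 0) return(NULL)
  pre <- grho_precompute(time, event, rho = config$rho)
  best <- NULL
  consider <- function(grp, rule) {
    nl <- sum(grp); nr <- sum(!grp)
    if (nl < config$min_node_size || nr < config$min_node_size)
      return()
    s <- grho_score(pre, grp)
    if (is.null(best) || s > best$statistic + 1e-12) {
      rule$statistic <- s; rule$n_left <- nl; rule$n_right <- nr
      best <<- rule
    }
  }
  if (is.numeric(x) || is.logical(x)) {
    xv <- as.numeric(x)
    for (cut in candidate_cutpoints(xv, config$max_cutpoints))
      consider(xv <= cut,
               list(variable = variable, type = "continuous",
                    cutoff = cut))
  } else {
    lev <- sort(unique(as.character(x)))
    if (length(lev) > config$max_categories)
      stop("variable '", variable, "' has ", length(lev),
           " levels (max ", config$max_categories, ")")
    for (part in level_partitions(lev))
      consider(as.character(x) %in% part,
               list(variable = variable, type = "categorical",
                    left_categories = part))
  }
  best
}

# TRUE/FALSE/NA: does each row go left under the rule?
rule_goes_left <- function(rule, data) {
  x <- data[[rule$variable]]
  if (is.null(x)) return(rep(NA, nrow(data)))
  if (rule$type == "continuous") {
    out <- as.numeric(x) <= rule$cutoff
  } else {
    out <- as.character(x) %in% rule$left_categories
    out[is.na(x)] <- NA
  }
  out
}

# surrogate search: split of another variable best agreeing with the
# primary left/right assignment (numeric/logical variables only)
find_surrogates <- function(data, primary_left, predictors, primary_var,
                            config) {
  usable <- !is.na(primary_left)
  nl <- sum(primary_left[usable]); nr <- sum(!primary_left[usable])
  baseline <- max(nl, nr) / (nl + nr)
  surr <- list()
  for (w in setdiff(predictors, primary_var)) {
    x <- data[[w]]
    if (!(is.numeric(x) || is.logical(x))) next
    xv <- as.numeric(x)
    ok <- usable & !is.na(xv)
    if (sum(ok) == 0) next
    pl <- primary_left[ok]; xw <- xv[ok]
    best_a <- baseline; best_rule <- NULL
    for (cut in candidate_cutpoints(xw, config$max_cutpoints)) {
      le <- xw <= cut
      a1 <- (sum(le & pl) + sum(!le & !pl)) / length(pl)
      a2 <- 1 - a1  # reversed direction
      if (a1 > best_a + 1e-12) {
        best_a <- a1
        best_rule <- list(variable = w, cutoff = cut,
                          left_if_le = TRUE, agreement = a1)
      }
      if (a2 > best_a + 1e-12) {
        best_a <- a2
        best_rule <- list(variable = w, cutoff = cut,
                          left_if_le = FALSE, agreement = a2)
      }
    }
    if (!is.null(best_rule)) surr[[length(surr) + 1L]] <- best_rule
  }
  if (length(surr) == 0) return(list())
  ag <- vapply(surr, `[[`, numeric(1), "agreement")
  surr <- surr[order(-ag)]
  surr[seq_len(min(length(surr), config$max_surrogates))]
}

# route rows of data through a node's primary rule, falling back on
# surrogates and then on the majority direction
route_node <- function(node, data) {
  left <- rule_goes_left(node$split, data)
  if (any(is.na(left))) {
    for (s in node$surrogates) {
      nas <- which(is.na(left))
      if (!length(nas)) break
      xv <- as.numeric(data[[s$variable]][nas])
      le <- xv <= s$cutoff
      dir <- if (s$left_if_le) le else !le
      left[nas[!is.na(dir)]] <- dir[!is.na(dir)]
    }
    left[is.na(left)] <- node$majority_left
  }
  left
}

#' Fit a survival regression tree
#'
#' Recursively partitions a cohort on the predictors, choosing at each
#' node the variable and cutpoint with the largest G^rho two-sample
#' statistic between the candidate children. Splitting stops at the
#' maximum depth, the minimum node size, or when the best statistic falls
#' below `min_split_stat`. Each internal node stores surrogate splits
#' (used to route patients with missing values and for surrogate-aware
#' importance); each leaf stores its incidence rate per 100
#' patient-years. Leaves are ranked by decreasing incidence rate (ties by
#' larger event count) — the ordinal risk hierarchization.
#'
#' @param cohort `data.frame` with `time` in months, `event` 0/1 and the
#'   predictor columns.
#' @param predictors character vector of predictor column names.
#' @param config a [tree_config()].
#' @return an object of class `hd_tree` with elements `nodes` (list keyed
#'   by node id), `leaf_summary` (per-leaf risk table, riskiest first),
#'   `reference_leaf` (lowest incidence rate), `config`, `predictors`.
#' @export
fit_tree <- function(cohort, predictors, config = tree_config()) {
  miss <- setdiff(predictors, names(cohort))
  if (length(miss))
    stop("predictors not in cohort: ", paste(miss, collapse = ", "))
  n <- nrow(cohort)
  if (n < 2 * config$min_node_size)
    stop("cohort smaller than twice min_node_size")
  if (sum(cohort$event) < 1) stop("cohort contains no events")
  nodes <- list()

  build <- function(idx, id, depth) {
    sub <- cohort[idx, , drop = FALSE]
    node <- list(node_id = id, depth = depth, member_idx = idx,
                 n = length(idx), events = sum(sub$event),
                 person_years = sum(months_to_years(sub$time)),
                 is_leaf = TRUE, split = NULL, surrogates = list(),
                 majority_left = TRUE)
    node$ir <- if (node$person_years > 0)
      incidence_rate(node$events, node$person_years) else NA_real_
    sf <- survfit(Surv(sub$time, sub$event) ~ 1)
    node$km <- data.frame(time = sf$time, surv = sf$surv)
    can_split <- depth < config$max_depth &&
      length(idx) >= 2 * config$min_node_size && node$events > 0
    if (can_split) {
      cands <- lapply(predictors, function(v)
        best_split(sub, v, config))
      stats <- vapply(cands, function(c)
        if (is.null(c)) -Inf else c$statistic, numeric(1))
      if (any(is.finite(stats)) &&
          max(stats) >= config$min_split_stat) {
        rule <- cands[[which.max(stats)]]
        left <- rule_goes_left(rule, sub)
        node$split <- rule
        node$majority_left <-
          sum(left, na.rm = TRUE) >= sum(!left, na.rm = TRUE)
        node$surrogates <- find_surrogates(sub, left, predictors,
                                           rule$variable, config)
        routed <- route_node(node, sub)
        if (sum(routed) >= config$min_node_size &&
            sum(!routed) >= config$min_node_size) {
          node$is_leaf <- FALSE
          nodes[[as.character(id)]] <<- node
          build(idx[routed], 2L * id, depth + 1L)
          build(idx[!routed], 2L * id + 1L, depth + 1L)
          return(invisible())
        }
        node$split <- NULL; node$surrogates <- list()
        node$is_leaf <- TRUE
      }
    }
    nodes[[as.character(id)]] <<- node
    invisible()
  }
  build(seq_len(n), 1L, 0L)
  if (length(nodes) == 1L)
    warning("no admissible root split; returning a single-leaf tree")

  tree <- structure(
    list(nodes = nodes, config = config, predictors = predictors,
         n = n),
    class = "hd_tree")
  leaf_ids <- tree_leaf_ids(tree)
  ls <- do.call(rbind, lapply(leaf_ids, function(id) {
    nd <- nodes[[as.character(id)]]
    data.frame(node_id = id, n = nd$n, events = nd$events,
               person_years = nd$person_years, ir = nd$ir)
  }))
  ls <- ls[order(-ls$ir, -ls$events), , drop = FALSE]
  ls$risk_rank <- seq_len(nrow(ls))
  rownames(ls) <- NULL
  tree$leaf_summary <- ls
  tree$reference_leaf <- ls$node_id[nrow(ls)]
  tree
}

#' @export
print.hd_tree <- function(x, ...) {
  cat("Survival regression tree:", length(tree_leaf_ids(x)),
      "leaves,", x$n, "patients\n")
  ids <- sort(as.integer(names(x$nodes)))
  for (id in ids) {
    nd <- x$nodes[[as.character(id)]]
    pad <- strrep("  ", nd$depth)
    if (nd$is_leaf) {
      cat(sprintf("%s[%d] leaf  n=%d events=%d IR=%.2f\n",
                  pad, id, nd$n, nd$events, nd$ir))
    } else {
      desc <- if (nd$split$type == "continuous")
        sprintf("%s <= %.4g", nd$split$variable, nd$split$cutoff)
      else sprintf("%s in {%s}", nd$split$variable,
                   paste(nd$split$left_categories, collapse = ","))
      cat(sprintf("%s[%d] %s  (chi2=%.2f, surrogates=%d)\n",
                  pad, id, desc, nd$split$statistic,
                  length(nd$surrogates)))
    }
  }
  invisible(x)
}

tree_leaf_ids <- function(tree) {
  ids <- as.integer(names(tree$nodes))
  ids[vapply(tree$nodes, `[[`, logical(1), "is_leaf")]
}

# variables used in primary splits
tree_split_variables <- function(tree) {
  unlist(lapply(tree$nodes, function(nd)
    if (!nd$is_leaf) nd$split$variable else NULL), use.names = FALSE)
}

#' Assign patients to the leaves of a fitted tree
#'
#' Routes each row through the primary splits, using surrogate rules and
#' then the majority direction when a split variable is missing.
#'
#' @param tree an `hd_tree`.
#' @param newdata `data.frame` with the predictor columns.
#' @return integer vector of leaf node ids, one per row.
#' @export
predict_leaf <- function(tree, newdata) {
  out <- integer(nrow(newdata))
  assign_rec <- function(idx, id) {
    nd <- tree$nodes[[as.character(id)]]
    if (nd$is_leaf) { out[idx] <<- id; return(invisible()) }
    left <- route_node(nd, newdata[idx, , drop = FALSE])
    assign_rec(idx[left], 2L * id)
    assign_rec(idx[!left], 2L * id + 1L)
  }
  assign_rec(seq_len(nrow(newdata)), 1L)
  out
}

#' Leaf incidence-rate risk score
#'
#' @param tree an `hd_tree`.
#' @param newdata `data.frame` of patients to score.
#' @return numeric vector: each patient's leaf incidence rate (per 100
#'   patient-years) as estimated on the training data; an ordinal risk
#'   score.
#' @export
predict_risk <- function(tree, newdata) {
  leaf <- predict_leaf(tree, newdata)
  ls <- tree$leaf_summary
  ls$ir[match(leaf, ls$node_id)]
}

#' Per-leaf risk summaries of a fitted tree
#'
#' Computes, for each leaf on the supplied cohort: patient count, events,
#' person-years, incidence rate per 100 patient-years, Kaplan-Meier
#' survival curve, and the Cox hazard ratio (with Wald 95% CI) versus the
#' lowest-incidence leaf.
#'
#' @param tree an `hd_tree`.
#' @param cohort the cohort to summarize on (typically the training
#'   cohort).
#' @return `data.frame` with one row per leaf, riskiest first, and a
#'   `km` attribute: a named list of per-leaf Kaplan-Meier step functions
#'   (`data.frame(time, surv)`, time in months).
#' @export
node_summaries <- function(tree, cohort) {
  leaf <- predict_leaf(tree, cohort)
  ids <- sort(unique(leaf))
  rows <- lapply(ids, function(id) {
    sel <- leaf == id
    py <- sum(months_to_years(cohort$time[sel]))
    if (py <= 0) stop("leaf ", id, " has zero person-time")
    data.frame(node_id = id, n = sum(sel),
               events = sum(cohort$event[sel]), person_years = py,
               ir = incidence_rate(sum(cohort$event[sel]), py))
  })
  tab <- do.call(rbind, rows)
  ref <- tab$node_id[which.min(tab$ir)]
  fac <- factor(leaf, levels = c(ref, setdiff(ids, ref)))
  tab$hr <- 1; tab$hr_low <- NA_real_; tab$hr_high <- NA_real_
  if (length(ids) > 1) {
    fit <- suppressWarnings(
      coxph(Surv(cohort$time, cohort$event) ~ fac, ties = "efron"))
    co <- coef(fit); se <- sqrt(diag(vcov(fit)))
    others <- setdiff(ids, ref)
    tab$hr[match(others, tab$node_id)] <- exp(co)
    tab$hr_low[match(others, tab$node_id)] <- exp(co - qnorm(0.975) * se)
    tab$hr_high[match(others, tab$node_id)] <- exp(co + qnorm(0.975) * se)
  }
  km <- lapply(ids, function(id) {
    sel <- leaf == id
    sf <- survfit(Surv(cohort$time[sel], cohort$event[sel]) ~ 1)
    data.frame(time = sf$time, surv = sf$surv)
  })
  names(km) <- as.character(ids)
  tab <- tab[order(-tab$ir, -tab$events), , drop = FALSE]
  tab$risk_rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "km") <- km
  tab
}
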