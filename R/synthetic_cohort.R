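# Synthetic hemodialysis cohorts with a latent eight-leaf risk-tree
# structure, exponential event times, independent censoring, matched or
# random case/control sampling, and MCAR missingness.

#' Generative risk-tree specification
#'
#' Defines the latent structure a synthetic cohort is drawn from: a full
#' binary tree of depth 3 (seven internal splits, eight leaves numbered
#' 8..15 in binary-heap order), one incidence rate per leaf, marginal
#' covariate distributions, and the censoring/missingness mechanisms.
#'
#' The default tree routes patients as observed in hemodialysis risk
#' stratification: the root splits age at 64 years; the younger branch
#' splits on history of diabetes, then on hsCRP at 3.221 mg/L
#' (non-diabetic side, low-risk leaf 8) or miR-632 at 2.850 log10 units
#' (diabetic side, high-risk leaf 11); the older branch splits on hsCRP at
#' 0.827 mg/L, then on miR-186-5p (low-hsCRP side; the cutoff defaults to
#' that marginal's median) or history of CVD (high-hsCRP side). Default
#' leaf incidence rates are 6.33, 21.17, 23.66, 101.57, 13.21, 25.75,
#' 31.28 and 79.40 events per 100 patient-years for leaves 8..15.
#'
#' @param splits named list of seven split rules (names `"1"`..`"7"`,
#'   binary-heap node ids), each `list(variable =, cutoff =)`. A patient
#'   goes to the right child when `value > cutoff` (numeric) or
#'   `value == TRUE` (binary).
#' @param leaf_ir numeric vector of eight incidence rates (events per 100
#'   patient-years) for leaves 8..15; all positive.
#' @param covariate_dists named list of marginal distributions, each
#'   `list(dist =, ...params)` with `dist` one of `"uniform"`, `"normal"`,
#'   `"lognormal"`, `"bernoulli"`, `"categorical"`.
#' @param admin_censor_time administrative censoring horizon in years.
#' @param dropout_rate per-year hazard of random (exponential) censoring;
#'   the default pair (5 y, 0.19/y) gives a mean follow-up of about 3.2
#'   years in the absence of events.
#' @param missing_rates named MCAR probabilities over a subset of
#'   `ktv`, `bmi`, `albumin`, `hscrp` (applied by [inject_missingness()]).
#' @return an object of class `gen_tree_spec`.
#' @seealso [generate_cohort()], [draw_case_control()],
#'   [inject_missingness()]
#' @export
tree_spec <- function(splits = default_splits(),
                      leaf_ir = c(6.33, 21.17, 23.66, 101.57,
                                  13.21, 25.75, 31.28, 79.40),
                      covariate_dists = default_covariate_dists(),
                      admin_censor_time = 5,
                      dropout_rate = 0.19,
                      missing_rates = c(ktv = 0.05, bmi = 0.03,
                                        albumin = 0.04, hscrp = 0.06)) {
  spec <- structure(
    list(splits = splits, leaf_ir = leaf_ir,
         covariate_dists = covariate_dists,
         admin_censor_time = admin_censor_time,
         dropout_rate = dropout_rate,
         missing_rates = missing_rates),
    class = "gen_tree_spec")
  validate_tree_spec(spec)
  spec
}

#' @rdname tree_spec
#' @export
default_splits <- function() {
  list(
    `1` = list(variable = "age",           cutoff = 64),
    `2` = list(variable = "hist_diabetes", cutoff = NA),
    `3` = list(variable = "hscrp",         cutoff = 0.827),
    `4` = list(variable = "hscrp",         cutoff = 3.221),
    `5` = list(variable = "miR_632",       cutoff = 2.850),
    `6` = list(variable = "miR_186_5p",    cutoff = 4.5),
    `7` = list(variable = "hist_cvd",      cutoff = NA)
  )
}

#' @rdname tree_spec
#' @export
default_covariate_dists <- function() {
  list(
    age          = list(dist = "uniform", min = 50, max = 80),
    sex          = list(dist = "bernoulli", prob = 0.62),
    region       = list(dist = "categorical",
                        levels = c("EU", "NA", "AP"),
                        probs = c(0.55, 0.30, 0.15)),
    bmi          = list(dist = "normal", mean = 25.3, sd = 4.5),
    ktv          = list(dist = "normal", mean = 1.40, sd = 0.22),
    albumin      = list(dist = "normal", mean = 39, sd = 3.5),
    hscrp        = list(dist = "lognormal", meanlog = log(3), sdlog = 1.1),
    hist_cvd     = list(dist = "bernoulli", prob = 0.40),
    hist_diabetes = list(dist = "bernoulli", prob = 0.28),
    statin_arm   = list(dist = "bernoulli", prob = 0.50),
    miR_632      = list(dist = "normal", mean = 2.70, sd = 0.50),
    miR_186_5p   = list(dist = "normal", mean = 4.50, sd = 0.50),
    miR_210_3p   = list(dist = "normal", mean = 2.00, sd = 0.40)
  )
}

dist_support <- function(d) {
  switch(d$dist,
    uniform = c(d$min, d$max),
    normal = c(-Inf, Inf),
    lognormal = c(0, Inf),
    bernoulli = c(0, 1),
    categorical = c(-Inf, Inf),
    stop("unknown distribution: ", d$dist))
}

validate_tree_spec <- function(spec) {
  s <- spec$splits
  if (length(s) != 7L || !identical(sort(names(s)), as.character(1:7)))
    stop("splits must name the seven internal nodes \"1\"..\"7\"")
  if (length(spec$leaf_ir) != 8L)
    stop("leaf_ir must hold exactly 8 leaf incidence rates, got ",
         length(spec$leaf_ir))
  if (any(spec$leaf_ir <= 0))
    stop("leaf_ir: every leaf incidence rate must be > 0")
  for (id in names(s)) {
    v <- s[[id]]$variable
    d <- spec$covariate_dists[[v]]
    if (is.null(d))
      stop("split node ", id, " uses variable '", v,
           "' with no covariate distribution")
    if (d$dist %in% c("bernoulli")) next
    cut <- s[[id]]$cutoff
    sup <- dist_support(d)
    if (!is.finite(cut) || cut <= sup[1] || cut >= sup[2])
      stop("split node ", id, ": cutoff ", cut,
           " lies outside the support of '", v, "'")
  }
  if (spec$admin_censor_time <= 0) stop("admin_censor_time must be > 0")
  if (spec$dropout_rate < 0) stop("dropout_rate must be >= 0")
  bad <- setdiff(names(spec$missing_rates),
                 c("ktv", "bmi", "albumin", "hscrp"))
  if (length(bad))
    stop("missing_rates only allowed for ktv/bmi/albumin/hscrp, not: ",
         paste(bad, collapse = ", "))
  invisible(spec)
}

draw_marginal <- function(d, n) {
  switch(d$dist,
    uniform = runif(n, d$min, d$max),
    normal = rnorm(n, d$mean, d$sd),
    lognormal = rlnorm(n, d$meanlog, d$sdlog),
    bernoulli = rbinom(n, 1, d$prob) == 1,
    categorical = sample(d$levels, n, replace = TRUE, prob = d$probs))
}

# route one cohort through the latent tree; returns leaf ids 8..15
route_tree <- function(data, splits) {
  node <- rep(1L, nrow(data))
  for (depth in 1:3) {
    idx <- node < 8L
    for (id in unique(node[idx])) {
      rule <- splits[[as.character(id)]]
      v <- data[[rule$variable]]
      right <- if (is.logical(v)) v else v > rule$cutoff
      sel <- node == id
      node[sel] <- 2L * id + as.integer(right[sel])
    }
  }
  node
}

#' Generate a synthetic hemodialysis cohort
#'
#' Draws covariates from the specification's marginals, routes each
#' patient through the latent risk tree to one of eight leaves, and draws
#' an exponential event time with hazard `leaf_ir / 100` per patient-year.
#' Censoring is the minimum of the administrative horizon and an
#' exponential dropout time; follow-up is recorded in months.
#'
#' @param spec a [tree_spec()] object.
#' @param n number of patients (>= 16).
#' @param seed integer seed; the same `spec`, `n` and `seed` reproduce the
#'   table exactly.
#' @return a `data.frame` (one row per patient) with identifiers, phase
#'   label, `case_flag` (event occurred), `event`, `time` in months,
#'   clinical covariates, miR-632 / miR-186-5p / miR-210-3p levels on the
#'   log10 scale, and the latent `leaf_id` (8..15).
#' @examples
#' coh <- generate_cohort(tree_spec(), n = 100, seed = 1)
#' table(coh$leaf_id)
#' @export
generate_cohort <- function(spec, n, seed) {
  validate_tree_spec(spec)
  if (!is.numeric(n) || length(n) != 1 || n < 16)
    stop("n must be a single count >= 16, got ", deparse(substitute(n)),
         " = ", n)
  set.seed(seed)
  covs <- lapply(spec$covariate_dists, draw_marginal, n = n)
  data <- as.data.frame(covs, stringsAsFactors = FALSE)
  # miR-210-3p tracks inflammation: add a log-hsCRP component so it can act
  # as a surrogate for hsCRP in fitted trees
  data$miR_210_3p <- data$miR_210_3p +
    0.45 * (log(data$hscrp) - spec$covariate_dists$hscrp$meanlog)
  leaf <- route_tree(data, spec$splits)
  lambda <- spec$leaf_ir[leaf - 7L] / 100          # per patient-year
  t_event <- rexp(n, rate = lambda)
  t_drop <- if (spec$dropout_rate > 0) rexp(n, rate = spec$dropout_rate)
            else rep(Inf, n)
  t_cens <- pmin(spec$admin_censor_time, t_drop)
  time_y <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  out <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    phase = "II",
    pair_id = NA_character_,
    case_flag = event == 1L,
    event = event,
    time = time_y * 12,
    stringsAsFactors = FALSE)
  out <- cbind(out, data)
  out$leaf_id <- leaf
  out
}

#' Draw a case/control subcohort
#'
#' Selects cases (patients with the event) and controls either by greedy
#' nearest-neighbour 1:1 matching on standardized covariates (phase-I
#' style; emits pair identifiers) or by simple random draws (phase-II
#' style).
#'
#' @param cohort a cohort `data.frame` from [generate_cohort()].
#' @param n_cases,n_controls counts to draw; matched sampling requires
#'   `n_cases == n_controls`.
#' @param matched logical; greedy nearest-neighbour matching when `TRUE`.
#' @param matching_vars character vector of numeric covariates used for
#'   the standardized Euclidean matching distance.
#' @param seed integer seed (case order and tie-breaks).
#' @return the selected rows, with `phase` set to `"I"` (matched) or
#'   `"II"` (random) and `pair_id` filled for matched draws.
#' @export
draw_case_control <- function(cohort, n_cases, n_controls,
                              matched = FALSE,
                              matching_vars = c("age", "bmi", "ktv"),
                              seed = 1) {
  cases <- which(cohort$event == 1L)
  ctrls <- which(cohort$event == 0L)
  if (length(cases) < n_cases)
    stop("requested ", n_cases, " cases but only ", length(cases),
         " available")
  if (length(ctrls) < n_controls)
    stop("requested ", n_controls, " controls but only ", length(ctrls),
         " available")
  set.seed(seed)
  if (!matched) {
    sel <- c(sample(cases, n_cases), sample(ctrls, n_controls))
    out <- cohort[sel, , drop = FALSE]
    out$phase <- "II"
    out$pair_id <- NA_character_
    rownames(out) <- NULL
    return(out)
  }
  if (n_cases != n_controls)
    stop("matched sampling is 1:1; n_cases must equal n_controls")
  miss <- setdiff(matching_vars, names(cohort))
  if (length(miss))
    stop("matching_vars not in cohort: ", paste(miss, collapse = ", "))
  x <- as.matrix(cohort[, matching_vars, drop = FALSE])
  x <- scale(x)
  case_pool <- sample(cases, n_cases)      # random case order by seed
  avail <- ctrls
  pairs <- matrix(NA_integer_, nrow = n_cases, ncol = 2)
  for (k in seq_len(n_cases)) {
    ci <- case_pool[k]
    d2 <- colSums((t(x[avail, , drop = FALSE]) - x[ci, ])^2)
    j <- which(d2 == min(d2))
    if (length(j) > 1) j <- sample(j, 1)
    pairs[k, ] <- c(ci, avail[j])
    avail <- avail[-j]
  }
  out <- cohort[as.vector(t(pairs)), , drop = FALSE]
  out$phase <- "I"
  out$pair_id <- rep(sprintf("pair%04d", seq_len(n_cases)), each = 2)
  rownames(out) <- NULL
  out
}

#' Inject missing-completely-at-random values
#'
#' Sets cells of the continuous covariates `ktv`, `bmi`, `albumin` and
#' `hscrp` to `NA` independently with the given per-variable probability.
#' No other column may be targeted.
#'
#' @param cohort a cohort `data.frame`.
#' @param rates named vector of probabilities in `[0, 1)` over a subset of
#'   the four permitted variables.
#' @param seed integer seed.
#' @return the cohort with missing values injected.
#' @export
inject_missingness <- function(cohort, rates, seed = 1) {
  allowed <- c("ktv", "bmi", "albumin", "hscrp")
  bad <- setdiff(names(rates), allowed)
  if (length(bad))
    stop("missingness only permitted in ", paste(allowed, collapse = "/"),
         "; refused: ", paste(bad, collapse = ", "))
  if (any(rates < 0 | rates >= 1)) stop("rates must lie in [0, 1)")
  set.seed(seed)
  for (v in names(rates)) {
    hit <- runif(nrow(cohort)) < rates[[v]]
    cohort[[v]][hit] <- NA
  }
  cohort
}
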