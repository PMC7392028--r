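# Shared fixtures and independent oracles.

# naive hypergeometric weighted log-rank summation: an independent oracle
# for the G^rho statistic (plain loops, no shared code with the package)
naive_grho <- function(time, event, grp, rho = 0) {
  et <- sort(unique(time[event == 1]))
  if (length(et) == 0) return(0)
  num <- 0; den <- 0; surv <- 1
  for (t in et) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & grp)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp)
    w <- surv^rho
    e1 <- d * n1 / n
    v1 <- if (n > 1) d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
          else 0
    num <- num + w * (d1 - e1)
    den <- den + w^2 * v1
    surv <- surv * (1 - d / n)
  }
  if (den <= 0) 0 else num^2 / den
}

# random small censored two-group instance
random_surv_instance <- function(seed, n_max = 30) {
  set.seed(seed)
  n <- sample(6:n_max, 1)
  list(time = round(rexp(n, 0.3), 2) + 0.05,
       event = rbinom(n, 1, 0.7),
       grp = rbinom(n, 1, 0.5) == 1)
}

# cohort with a single strong binary risk factor
simple_risk_cohort <- function(n, seed, hr = 3, cens_rate = 0.1) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5) == 1
  haz <- 0.15 * ifelse(x, hr, 1)
  te <- rexp(n, haz)
  tc <- rexp(n, cens_rate)
  data.frame(time = pmin(te, tc) * 12, event = as.integer(te <= tc),
             x = x)
}

default_predictors <- function() {
  c("age", "albumin", "hscrp", "hist_cvd", "hist_diabetes",
    "miR_632", "miR_186_5p", "miR_210_3p")
}

true_split_variables <- function() {
  c("age", "hist_diabetes", "hscrp", "miR_632", "miR_186_5p",
    "hist_cvd")
}
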