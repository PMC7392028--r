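#' @keywords internal
"_PACKAGE"

#' @importFrom stats median quantile rnorm runif rexp rbinom rlnorm sd
#'   pnorm qnorm wilcox.test fisher.test chisq.test complete.cases
#'   coef vcov as.formula setNames rchisq var qt pt
#' @importFrom survival Surv coxph survfit survdiff
NULL

# months -> years conversion; the single place person-time units change
months_to_years <- function(m) m / 12

#' Incidence rate per 100 patient-years
#'
#' @param events number of events.
#' @param person_years accumulated follow-up in years.
#' @return events / person-years, scaled per 100 patient-years.
#' @examples
#' incidence_rate(2, 4) # 50
#' @export
incidence_rate <- function(events, person_years) {
  stopifnot(person_years > 0)
  100 * events / person_years
}

#' Empirical percentile interval
#'
#' Percentile bounds of a resampled statistic at the (1 - level)/2 and
#' (1 + level)/2 empirical quantiles (type-7 convention).
#'
#' @param values numeric vector of resampled statistics (at least 20).
#' @param level confidence level in (0, 1].
#' @return named numeric vector `c(low, high)`.
#' @examples
#' percentile_ci(1:100)          # 3.475 97.525
#' percentile_ci(rep(2, 25))     # 2 2
#' @export
percentile_ci <- function(values, level = 0.95) {
  values <- values[is.finite(values)]
  if (length(values) < 20)
    stop("percentile_ci() needs at least 20 finite values, got ",
         length(values))
  stopifnot(level > 0, level <= 1)
  probs <- c((1 - level) / 2, (1 + level) / 2)
  q <- quantile(values, probs = probs, type = 7, names = FALSE)
  c(low = q[1], high = q[2])
}

# strict-greater binarization cutoffs share one quantile convention (type 7)
empirical_cutoff <- function(x, scheme) {
  p <- switch(scheme,
    gt_tertile1 = 1 / 3,
    gt_median   = 1 / 2,
    gt_tertile2 = 2 / 3,
    stop("unknown binarization scheme: ", scheme)
  )
  quantile(x, probs = p, type = 7, names = FALSE)
}

# derive a stream of child seeds from one master seed (documented counter
# scheme: child_k = (master * 69069 + k) mod 2^31-1, kept positive)
derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1, is.finite(seed))
  (as.numeric(seed) %% 10000L) * 100003 %% .Machine$integer.max +
    seq_len(n)
}
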