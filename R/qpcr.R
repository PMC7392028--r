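# RT-qPCR preprocessing: delta-Cq normalization against the miR-486-5p
# internal reference, floor-censoring of undetected assays, and the binary
# codings (tertile/median) used downstream.

#' Normalize raw Cq values by the delta-Cq method
#'
#' Computes relative miRNA levels as `2^-(Cq - Cq_ref)` with the internal
#' reference (miR-486-5p) Cq per patient, then log10-transforms:
#' `level = -(cq - reference_cq) * log10(2) + offset`. A sample is flagged
#' detected when its Cq is below the detection threshold (35 cycles by
#' default).
#'
#' @param records long-format `data.frame` with columns `patient_id`,
#'   `mirna_name`, `cq`, `reference_cq` (and optionally `spike_cq`, used
#'   only for quality control elsewhere).
#' @param offset additive offset on the log10 scale reconciling relative
#'   levels with an external "arbitrary units" scale; default 0.
#' @param detect_cq detection threshold in cycles; `cq >= detect_cq` marks
#'   the sample undetected (its provisional level is still computed and is
#'   typically replaced by [floor_censor()]).
#' @return `data.frame` with `patient_id`, `mirna_name`, `level`,
#'   `detected`, `floor_applied` (all `FALSE` here).
#' @examples
#' r <- data.frame(patient_id = "a", mirna_name = "miR-632",
#'                 cq = 30, reference_cq = 28)
#' normalize_dcq(r)$level  # -2 * log10(2) = -0.60206
#' @export
normalize_dcq <- function(records, offset = 0, detect_cq = 35) {
  need <- c("patient_id", "mirna_name", "cq", "reference_cq")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack columns: ", paste(miss, collapse = ", "))
  no_ref <- !is.finite(records$reference_cq)
  if (any(no_ref))
    stop("missing reference Cq for patient(s): ",
         paste(unique(records$patient_id[no_ref]), collapse = ", "))
  dcq <- records$cq - records$reference_cq
  data.frame(
    patient_id = records$patient_id,
    mirna_name = records$mirna_name,
    level = -dcq * log10(2) + offset,
    detected = is.finite(records$cq) & records$cq < detect_cq,
    floor_applied = FALSE,
    stringsAsFactors = FALSE)
}

#' Floor-censor undetected miRNA measurements
#'
#' For each miRNA, replaces the level of every undetected sample by the
#' minimum level observed among that miRNA's detected samples. A miRNA
#' with no detected sample at all cannot be floored and is rejected (such
#' assays are discarded upstream as below the limit of detection).
#'
#' @param levels `data.frame` from [normalize_dcq()].
#' @return the same `data.frame` with undetected levels floored and
#'   `floor_applied` set for them.
#' @export
floor_censor <- function(levels) {
  for (m in unique(levels$mirna_name)) {
    sel <- levels$mirna_name == m
    det <- sel & levels$detected
    if (!any(det))
      stop("miRNA '", m, "' has no detected sample; discard it rather ",
           "than floor-censor")
    floor_level <- min(levels$level[det])
    und <- sel & !levels$detected
    levels$level[und] <- floor_level
    levels$floor_applied[und] <- TRUE
  }
  levels
}

#' Binary coding of a biomarker by empirical quantile cutoff
#'
#' Dichotomizes per-patient values as strictly greater than the first
#' tertile, the median, or the second tertile of the analysis population
#' (type-7 empirical quantiles; ties at the cutoff code low).
#'
#' @param values numeric vector (>= 3 non-missing values).
#' @param scheme one of `"gt_tertile1"`, `"gt_median"`, `"gt_tertile2"`.
#' @return logical vector with attribute `cutoff` holding the cutoff used;
#'   `NA` where the input is missing.
#' @examples
#' binarize(1:6, "gt_median")   # F F F T T T, cutoff 3.5
#' @export
binarize <- function(values, scheme = c("gt_median", "gt_tertile1",
                                        "gt_tertile2")) {
  scheme <- match.arg(scheme)
  ok <- !is.na(values)
  if (sum(ok) < 3)
    stop("binarize() needs at least 3 non-missing values")
  if (length(unique(values[ok])) == 1L)
    stop("all values identical; quantile cutoff is degenerate")
  cut <- empirical_cutoff(values[ok], scheme)
  out <- values > cut
  attr(out, "cutoff") <- cut
  attr(out, "scheme") <- scheme
  out
}

#' Convert long-format levels to a wide per-patient matrix
#'
#' @param levels `data.frame` from [normalize_dcq()]/[floor_censor()].
#' @return `data.frame` with one row per patient and one column per miRNA
#'   (syntactic names, `-` replaced by `_`).
#' @export
levels_to_wide <- function(levels) {
  pts <- unique(levels$patient_id)
  mirs <- unique(levels$mirna_name)
  out <- data.frame(patient_id = pts, stringsAsFactors = FALSE)
  for (m in mirs) {
    sub <- levels[levels$mirna_name == m, ]
    col <- gsub("-", "_", m)
    out[[col]] <- sub$level[match(pts, sub$patient_id)]
  }
  out
}
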