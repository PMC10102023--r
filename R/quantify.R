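#' Compute the N/B and B/N expression ratios
#'
#' The NR1D1/BMAL1 (N/B) and BMAL1/NR1D1 (B/N) ratios amplify the antiphase
#' circadian oscillation of the two genes: N/B peaks in the morning (around
#' 6:00) and B/N in the evening (around 18:00). Because the two genes are
#' measured in the same sample, any common normalization factor (reference
#' gene, RNA input, uniform postmortem degradation) cancels.
#'
#' @param expr_bmal1,expr_nr1d1 Strictly positive relative expression
#'   values. Vectorized.
#' @return A data frame with columns `nb_ratio` and `bn_ratio`;
#'   `nb_ratio * bn_ratio == 1` up to floating-point error.
#' @examples
#' compute_ratios(expr_bmal1 = 2, expr_nr1d1 = 10)  # nb = 5, bn = 0.2
#' @export
compute_ratios <- function(expr_bmal1, expr_nr1d1) {
  if (length(expr_bmal1) != length(expr_nr1d1))
    stop("expression vectors must have equal length", call. = FALSE)
  bad <- !is.finite(expr_bmal1) | !is.finite(expr_nr1d1) |
    expr_bmal1 <= 0 | expr_nr1d1 <= 0
  if (any(bad))
    stop(sprintf("non-positive or missing expression in %d case(s)",
                 sum(bad)), call. = FALSE)
  nb <- expr_nr1d1 / expr_bmal1
  data.frame(nb_ratio = nb, bn_ratio = 1 / nb)
}

#' Compute ratios from Ct values
#'
#' Converts a pair of cycle-threshold values into the N/B and B/N ratios
#' under a shared amplification efficiency for both assays:
#' `nb = (1 + efficiency)^(ct_bmal1 - ct_nr1d1)`.
#'
#' @param ct_bmal1,ct_nr1d1 Ct values in cycles. Vectorized.
#' @param efficiency Shared amplification efficiency in `(0, 1]`.
#' @param ct_ceiling Non-detect ceiling in cycles; a Ct at or above it is
#'   treated as missing (`NA` in the result).
#' @return A data frame with columns `nb_ratio` and `bn_ratio`; rows with a
#'   non-detect Ct carry `NA` ratios.
#' @export
ratios_from_ct <- function(ct_bmal1, ct_nr1d1, efficiency = 1,
                           ct_ceiling = 40) {
  check_efficiency(efficiency)
  if (length(ct_bmal1) != length(ct_nr1d1))
    stop("Ct vectors must have equal length", call. = FALSE)
  nondetect <- !is.finite(ct_bmal1) | !is.finite(ct_nr1d1) |
    ct_bmal1 >= ct_ceiling | ct_nr1d1 >= ct_ceiling
  nb <- (1 + efficiency)^(ct_bmal1 - ct_nr1d1)
  nb[nondetect] <- NA_real_
  data.frame(nb_ratio = nb, bn_ratio = 1 / nb)
}

#' Assign a clock time to one of four time domains
#'
#' Partitions the 24-h clock into the four 6-hour domains used throughout
#' the analysis: morning `[3, 9)`, noon `[9, 15)`, evening `[15, 21)` and
#' night `[21, 24) U [0, 3)`. Intervals are half-open so that every time
#' maps to exactly one domain (e.g. 9:00 is noon, 2:59 is night).
#'
#' @param t Clock time(s) in `[0, 24)`, decimal hours. Vectorized.
#' @return A character vector of labels among
#'   `c("morning", "noon", "evening", "night")`.
#' @examples
#' assign_time_domain(c(6, 12, 18, 0))
#' @export
assign_time_domain <- function(t) {
  if (any(!is.finite(t)) || any(t < 0) || any(t >= 24))
    stop("`t` must be clock time(s) in [0, 24)", call. = FALSE)
  ifelse(t >= 3 & t < 9, "morning",
         ifelse(t >= 9 & t < 15, "noon",
                ifelse(t >= 15 & t < 21, "evening", "night")))
}

#' Time-domain labels in clock order
#' @return `c("morning", "noon", "evening", "night")`
#' @export
time_domains <- function() c("morning", "noon", "evening", "night")

#' Quantify a cohort: ratios and time domains
#'
#' Adds `nb_ratio`, `bn_ratio` and (when `time_of_death` is present)
#' `time_domain` columns to a cohort table. Ratios come from the expression
#' columns when available, otherwise from the Ct columns via
#' [ratios_from_ct()]. Cases with missing, non-positive or non-detect
#' measurements are excluded from the result and reported in the
#' `"excluded"` attribute (a data frame with `case_id` and `reason`), so
#' that excluded + analyzed always equals the input count.
#'
#' @param cohort A cohort data frame (see [generate_cohort()] for the
#'   schema).
#' @param efficiency,ct_ceiling Passed to [ratios_from_ct()] when falling
#'   back to Ct values.
#' @return The quantified cohort with an `"excluded"` attribute.
#' @export
quantify_cohort <- function(cohort, efficiency = 1, ct_ceiling = 40) {
  stopifnot(is.data.frame(cohort))
  n <- nrow(cohort)
  has_expr_cols <- all(c("expr_bmal1", "expr_nr1d1") %in% names(cohort))
  has_ct_cols <- all(c("ct_bmal1", "ct_nr1d1") %in% names(cohort))
  if (!has_expr_cols && !has_ct_cols)
    stop("cohort has neither expression nor Ct columns", call. = FALSE)

  nb <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  if (has_expr_cols) {
    eb <- cohort$expr_bmal1
    en <- cohort$expr_nr1d1
    ok <- is.finite(eb) & is.finite(en) & eb > 0 & en > 0
    nb[ok] <- en[ok] / eb[ok]
    reason[!ok] <- "non-positive or missing expression"
  } else {
    ok <- rep(FALSE, n)
  }
  if (has_ct_cols && any(!ok)) {
    idx <- which(!ok)
    r <- ratios_from_ct(cohort$ct_bmal1[idx], cohort$ct_nr1d1[idx],
                        efficiency = efficiency, ct_ceiling = ct_ceiling)
    rec <- is.finite(r$nb_ratio)
    nb[idx[rec]] <- r$nb_ratio[rec]
    reason[idx[rec]] <- NA_character_
    reason[idx[!rec]] <- "non-detect or missing Ct"
    ok[idx[rec]] <- TRUE
  }

  out <- cohort[ok, , drop = FALSE]
  out$nb_ratio <- nb[ok]
  out$bn_ratio <- 1 / nb[ok]
  if ("time_of_death" %in% names(out))
    out$time_domain <- assign_time_domain(out$time_of_death)
  excluded <- data.frame(
    case_id = if ("case_id" %in% names(cohort))
      cohort$case_id[!ok] else as.character(which(!ok)),
    reason = reason[!ok],
    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  rownames(out) <- NULL
  out
}
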