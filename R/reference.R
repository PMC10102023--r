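#' Composition of the reference forensic case series
#'
#' The default synthetic cohort is calibrated to the published forensic
#' autopsy series of 318 heart samples with known time of death from which
#' the ratio thresholds were derived. This function returns its composition
#' as counts: cause-of-death subcategories within the intrinsic/extrinsic
#' split, the sex split, the acute/chronic course split among head-injury
#' deaths, and the cohort-level mean age and mean postmortem interval.
#'
#' @return A list with components
#'   \describe{
#'     \item{n_total}{total number of cases (318)}
#'     \item{sex}{named counts, male/female}
#'     \item{causes}{data frame of cause subcategories with `cause_class`
#'       and `n`}
#'     \item{head_injury_course}{named counts, acute/chronic, among
#'       head-injury deaths}
#'     \item{mean_age}{mean age, years}
#'     \item{mean_pmi}{mean postmortem interval, hours}
#'     \item{max_pmi}{upper bound on postmortem interval, hours}
#'     \item{age_range}{observed age range, years}
#'   }
#' @examples
#' ref <- reference_case_series()
#' sum(ref$causes$n) == ref$n_total
#' @export
reference_case_series <- function() {
  causes <- data.frame(
    cause_subcategory = c(
      "intoxication", "drowning", "hemorrhagic_traumatic_shock",
      "asphyxia_hanging", "burn", "head_injury", "other_extrinsic",
      "ischemic_heart_failure", "circulation_failure", "other_intrinsic"),
    cause_class = c(rep("extrinsic", 7L), rep("intrinsic", 3L)),
    n = c(14L, 48L, 46L, 29L, 33L, 50L, 25L, 34L, 18L, 21L),
    stringsAsFactors = FALSE
  )
  list(
    n_total = 318L,
    sex = c(male = 224L, female = 94L),
    causes = causes,
    head_injury_course = c(acute = 35L, chronic = 15L),
    mean_age = 58.7,
    mean_pmi = 22.3,
    max_pmi = 96,
    age_range = c(2 / 12, 97)
  )
}

#' Published threshold-exceedance counts of the reference case series
#'
#' Counts of reference-series cases exceeding each default ratio threshold,
#' together with the clock-time window that contained all of their true
#' times of death. These numbers define the default decision rules (see
#' [default_threshold_rules()]); the two low-tier counts together give the
#' method's headline yield (fraction of cases receiving any prediction).
#'
#' @return A data frame with columns `ratio_key`, `threshold`, `tier`,
#'   `window_start`, `window_end`, `n_exceeding`.
#' @examples
#' counts <- reference_threshold_counts()
#' # headline yield: low-tier morning + low-tier evening over all cases
#' low <- counts$n_exceeding[counts$tier == "low"]
#' 100 * sum(low) / reference_case_series()$n_total
#' @export
reference_threshold_counts <- function() {
  data.frame(
    ratio_key = c("nb", "nb", "bn", "bn"),
    threshold = c(25, 40, 1.5, 4),
    tier = c("low", "high", "low", "high"),
    window_start = c(1, 3, 14, 15),
    window_end = c(10, 9, 22, 20),
    n_exceeding = c(40L, 23L, 39L, 11L),
    stringsAsFactors = FALSE
  )
}
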