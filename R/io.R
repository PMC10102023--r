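cohort_columns <- c("case_id", "time_of_death", "sex", "age", "pmi",
                    "cause_class", "cause_subcategory", "brain_injury",
                    "expr_bmal1", "expr_nr1d1", "ct_bmal1", "ct_nr1d1")

mandatory_columns <- c("case_id", "time_of_death", "sex", "age", "pmi",
                       "cause_class", "cause_subcategory", "brain_injury")

#' Write a cohort table to CSV
#'
#' Writes the fixed, documented column order (`case_id`, `time_of_death`,
#' `sex`, `age`, `pmi`, `cause_class`, `cause_subcategory`,
#' `brain_injury`, `expr_bmal1`, `expr_nr1d1`, `ct_bmal1`, `ct_nr1d1`).
#' Missing Ct columns are written as empty fields. Clock times are decimal
#' hours.
#'
#' @param cohort A cohort data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  for (col in setdiff(cohort_columns, names(cohort)))
    cohort[[col]] <- NA_real_
  utils::write.csv(cohort[cohort_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# per-row validity check; returns NA when valid, else a reason string
row_problem <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) {
    reason[is.na(reason) & bad] <<- why
  }
  flag(!is.finite(df$time_of_death) | df$time_of_death < 0 |
         df$time_of_death >= 24, "time_of_death outside [0,24)")
  flag(!(df$sex %in% c("male", "female")), "invalid sex")
  flag(!is.finite(df$age) | df$age < 0, "negative or missing age")
  flag(!is.finite(df$pmi) | df$pmi <= 0 | df$pmi > 96,
       "pmi outside (0,96]")
  flag(!(df$cause_class %in% c("intrinsic", "extrinsic")),
       "invalid cause_class")
  flag(!(df$brain_injury %in% c("none", "acute", "chronic")),
       "invalid brain_injury")
  flag(df$brain_injury %in% c("acute", "chronic") &
         df$cause_subcategory != "head_injury",
       "brain_injury course without head injury")
  has_expr <- is.finite(df$expr_bmal1) & is.finite(df$expr_nr1d1)
  has_ct <- is.finite(df$ct_bmal1) & is.finite(df$ct_nr1d1)
  flag(has_expr & (df$expr_bmal1 <= 0 | df$expr_nr1d1 <= 0),
       "non-positive expression")
  flag(!has_expr & !has_ct, "no usable expression or Ct measurements")
  reason
}

#' Read and validate a cohort table
#'
#' Reads a CSV in the schema written by [write_cohort()]. Missing mandatory
#' columns are fatal; rows violating the per-field constraints (time of
#' death in `[0, 24)`, positive PMI at most 96 h, valid categories,
#' positive expression) are skipped and collected, with their file line
#' numbers, into the `"rejected"` attribute of the result.
#'
#' @param path CSV path.
#' @return A validated cohort data frame with a `"rejected"` attribute
#'   (data frame with `line`, `case_id`, `reason`).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(mandatory_columns, names(df))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!("expr_bmal1" %in% names(df) && "expr_nr1d1" %in% names(df)) &&
      !("ct_bmal1" %in% names(df) && "ct_nr1d1" %in% names(df)))
    stop("cohort must carry expression or Ct columns for both genes",
         call. = FALSE)
  for (col in setdiff(cohort_columns, names(df))) df[[col]] <- NA_real_
  df$case_id <- as.character(df$case_id)
  for (col in c("time_of_death", "age", "pmi", "expr_bmal1", "expr_nr1d1",
                "ct_bmal1", "ct_nr1d1"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  reason <- row_problem(df)
  ok <- is.na(reason)
  rejected <- data.frame(
    line = which(!ok) + 1L,  # header is line 1
    case_id = df$case_id[!ok],
    reason = reason[!ok],
    stringsAsFactors = FALSE)
  out <- df[ok, cohort_columns, drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Serialize a cohort configuration to JSON
#'
#' @param config A [cohort_config()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cohort_config <- function(config, path) {
  config <- validate_cohort_config(config)
  plain <- unclass(config)
  plain$oscillator_nr1d1 <- unclass(plain$oscillator_nr1d1)
  plain$oscillator_bmal1 <- unclass(plain$oscillator_bmal1)
  # named atomic vectors lose their names in JSON; keep them as an object
  plain$composition$sex <- as.list(plain$composition$sex)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a cohort configuration from JSON
#'
#' Validates the structure on load; malformed or inconsistent
#' configurations raise a configuration error.
#'
#' @param path JSON path written by [write_cohort_config()].
#' @return A validated [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("n_cases", "oscillator_nr1d1", "oscillator_bmal1",
                "arrhythmic_fraction", "chronic_brain_injury_attenuation",
                "composition", "tod_distribution", "pmi_decay_rate",
                "ct_efficiency", "seed")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("configuration is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  osc <- function(o) do.call(gene_oscillator, o[c("mesor", "amplitude",
                                                  "acrophase", "noise_sd")])
  comp <- x$composition
  comp$sex <- unlist(comp$sex)
  cohort_config(
    n_cases = x$n_cases,
    oscillator_nr1d1 = osc(x$oscillator_nr1d1),
    oscillator_bmal1 = osc(x$oscillator_bmal1),
    arrhythmic_fraction = x$arrhythmic_fraction,
    chronic_brain_injury_attenuation = x$chronic_brain_injury_attenuation,
    composition = comp,
    tod_distribution = x$tod_distribution,
    pmi_decay_rate = x$pmi_decay_rate,
    ct_efficiency = x$ct_efficiency,
    seed = x$seed)
}
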