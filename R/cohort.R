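#' Configure a synthetic autopsy cohort
#'
#' Builds the full parameterization of the synthetic-cohort generative
#' model. Defaults emulate the reference forensic case series
#' ([reference_case_series()]): 318 cases, sex and cause-of-death
#' composition matching its published counts, age and postmortem-interval
#' (PMI) distributions calibrated so their population means equal the
#' published cohort means (58.7 years, 22.3 hours), antiphase NR1D1/BMAL1
#' oscillators peaking at 6:00 and 18:00, a fraction of "arrhythmic" cases
#' whose personal clock phase is uniform on the 24-h day (shift-worker /
#' irregular-lifestyle mechanism), and complete loss of oscillation in
#' chronic-brain-injury cases.
#'
#' Age is drawn from a normal distribution truncated to the published age
#' range; PMI from a log-normal truncated at `pmi$max` hours. In both cases
#' the location parameter is solved (from the closed-form truncated mean) so
#' that the population mean equals the `mean` element, making the generator
#' self-calibrating against the published cohort summaries.
#'
#' @param n_cases Number of cases to generate.
#' @param oscillator_nr1d1,oscillator_bmal1 [gene_oscillator()] objects for
#'   the two genes. Defaults are antiphase (acrophases 6:00 and 18:00) with
#'   log-amplitude 1.2 each and a NR1D1-over-BMAL1 baseline offset of 1.4
#'   on the log scale, so the noiseless peak N/B ratio is
#'   `exp(1.4 + 2.4) ~ 44.7` (above the upper decision threshold of 40)
#'   while the peak B/N ratio is only `exp(-1.4 + 2.4) ~ 2.7`, reproducing
#'   the strong scale asymmetry between the two ratios that the published
#'   decision thresholds (25 and 40 for N/B versus 1.5 and 4 for B/N)
#'   imply.
#' @param arrhythmic_fraction Probability that a case's personal acrophase
#'   is drawn uniformly on `[0, 24)`. The same personal offset is applied to
#'   both genes, preserving their 12-h antiphase relation.
#' @param chronic_brain_injury_attenuation Multiplier in `[0, 1]` applied to
#'   both amplitudes for chronic-brain-injury cases. The default 0 models
#'   complete loss of the cardiac rhythm after chronic brain injury with
#'   cerebral edema, hernia or hypoxia.
#' @param composition List with elements `sex` (named probabilities),
#'   `causes` (data frame with `cause_subcategory`, `cause_class`, `prob`),
#'   `head_injury_chronic_prob` (probability that a head-injury death is a
#'   protracted, chronic-injury death), `age` (list `mean`, `sd`, `min`,
#'   `max`), and `pmi` (list `mean`, `sdlog`, `max`).
#' @param tod_distribution Distribution of time of death over `[0, 24)`;
#'   only `"uniform"` is supported (no empirical distribution is published).
#' @param pmi_decay_rate Optional common multiplicative RNA decay, per hour
#'   of PMI, applied identically to both genes (so it cancels in the
#'   ratios). Default 0 (off).
#' @param ct_efficiency Amplification efficiency used to derive the Ct
#'   columns from expression.
#' @param seed Integer seed; identical configurations (including the seed)
#'   generate byte-identical cohorts.
#'
#' @return An object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_cases = 100, seed = 1)
#' cohort <- generate_cohort(cfg)
#' @export
cohort_config <- function(n_cases = 318,
                          oscillator_nr1d1 = gene_oscillator(
                            mesor = 1.4, amplitude = 1.2, acrophase = 6,
                            noise_sd = 0.5),
                          oscillator_bmal1 = gene_oscillator(
                            mesor = 0, amplitude = 1.2, acrophase = 18,
                            noise_sd = 0.5),
                          arrhythmic_fraction = 0.15,
                          chronic_brain_injury_attenuation = 0,
                          composition = default_composition(),
                          tod_distribution = "uniform",
                          pmi_decay_rate = 0,
                          ct_efficiency = 1,
                          seed = 1L) {
  cfg <- structure(
    list(n_cases = as.integer(n_cases),
         oscillator_nr1d1 = oscillator_nr1d1,
         oscillator_bmal1 = oscillator_bmal1,
         arrhythmic_fraction = arrhythmic_fraction,
         chronic_brain_injury_attenuation = chronic_brain_injury_attenuation,
         composition = composition,
         tod_distribution = tod_distribution,
         pmi_decay_rate = pmi_decay_rate,
         ct_efficiency = ct_efficiency,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
}

#' Default cohort composition
#'
#' Composition probabilities and distribution parameters derived from the
#' reference case series counts and summaries.
#'
#' @return A composition list as documented in [cohort_config()].
#' @export
default_composition <- function() {
  ref <- reference_case_series()
  causes <- ref$causes
  causes$prob <- causes$n / ref$n_total
  causes$n <- NULL
  list(
    sex = ref$sex / ref$n_total,
    causes = causes,
    head_injury_chronic_prob =
      unname(ref$head_injury_course["chronic"] / sum(ref$head_injury_course)),
    age = list(mean = ref$mean_age, sd = 22,
               min = ref$age_range[1], max = ref$age_range[2]),
    pmi = list(mean = ref$mean_pmi, sdlog = 0.7, max = ref$max_pmi)
  )
}

validate_cohort_config <- function(cfg) {
  if (!inherits(cfg, "cohort_config"))
    stop("not a cohort_config", call. = FALSE)
  if (is.na(cfg$n_cases) || cfg$n_cases < 0)
    stop("`n_cases` must be a non-negative integer", call. = FALSE)
  stopifnot(inherits(cfg$oscillator_nr1d1, "gene_oscillator"),
            inherits(cfg$oscillator_bmal1, "gene_oscillator"))
  for (p in c("arrhythmic_fraction", "chronic_brain_injury_attenuation")) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop(sprintf("`%s` must be a probability in [0, 1]", p), call. = FALSE)
  }
  comp <- cfg$composition
  if (abs(sum(comp$sex) - 1) > 1e-8 || any(comp$sex < 0))
    stop("sex probabilities must be non-negative and sum to 1",
         call. = FALSE)
  if (!setequal(names(comp$sex), c("male", "female")))
    stop("sex probabilities must be named male/female", call. = FALSE)
  if (abs(sum(comp$causes$prob) - 1) > 1e-8 || any(comp$causes$prob < 0))
    stop("cause probabilities must be non-negative and sum to 1",
         call. = FALSE)
  if (!all(comp$causes$cause_class %in% c("intrinsic", "extrinsic")))
    stop("cause_class must be intrinsic or extrinsic", call. = FALSE)
  hp <- comp$head_injury_chronic_prob
  if (!is.numeric(hp) || hp < 0 || hp > 1)
    stop("head_injury_chronic_prob must be a probability", call. = FALSE)
  if (!identical(cfg$tod_distribution, "uniform"))
    stop("only a uniform time-of-death distribution is supported",
         call. = FALSE)
  if (cfg$pmi_decay_rate < 0)
    stop("`pmi_decay_rate` must be non-negative", call. = FALSE)
  check_efficiency(cfg$ct_efficiency)
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> n_cases %d, seed %d\n", x$n_cases, x$seed))
  cat(sprintf("  NR1D1 acrophase %.1f h, BMAL1 acrophase %.1f h, amplitude %.2f / %.2f\n",
              x$oscillator_nr1d1$acrophase, x$oscillator_bmal1$acrophase,
              x$oscillator_nr1d1$amplitude, x$oscillator_bmal1$amplitude))
  cat(sprintf("  arrhythmic fraction %.2f, chronic-injury attenuation %.2f\n",
              x$arrhythmic_fraction, x$chronic_brain_injury_attenuation))
  invisible(x)
}

# Location of a normal truncated to [lower, upper] whose truncated mean
# equals target_mean (closed-form mean + uniroot).
trunc_norm_location <- function(target_mean, sd, lower, upper) {
  tmean <- function(m) {
    a <- (lower - m) / sd
    b <- (upper - m) / sd
    m + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  stats::uniroot(function(m) tmean(m) - target_mean,
                 interval = c(lower - 4 * sd, upper + 4 * sd),
                 tol = 1e-10)$root
}

# meanlog of a log-normal truncated to (0, upper] whose truncated mean
# equals target_mean.
trunc_lnorm_meanlog <- function(target_mean, sdlog, upper) {
  tmean <- function(mu) {
    exp(mu + sdlog^2 / 2) *
      stats::pnorm((log(upper) - mu - sdlog^2) / sdlog) /
      stats::pnorm((log(upper) - mu) / sdlog)
  }
  stats::uniroot(function(mu) tmean(mu) - target_mean,
                 interval = c(log(target_mean) - 5, log(upper)),
                 tol = 1e-10)$root
}

#' Generate a synthetic autopsy cohort
#'
#' Draws `n_cases` case records under the generative model described in
#' [cohort_config()]. The random draws use a single `set.seed(config$seed)`
#' and a fixed column draw order (time of death, sex, age, PMI, cause,
#' injury course, arrhythmic flag, personal phase, two noise vectors), so
#' the same configuration always yields the identical cohort.
#'
#' Chronic-brain-injury cases have both log-amplitudes multiplied by
#' `chronic_brain_injury_attenuation` before expression is drawn.
#' Arrhythmic cases receive one shared personal phase offset applied to
#' both genes, preserving the 12-h antiphase relation.
#'
#' @param config A [cohort_config()].
#' @return A data frame with one row per case and columns `case_id`,
#'   `time_of_death`, `sex`, `age`, `pmi`, `cause_class`,
#'   `cause_subcategory`, `brain_injury`, `expr_bmal1`, `expr_nr1d1`,
#'   `ct_bmal1`, `ct_nr1d1`.
#' @export
generate_cohort <- function(config) {
  config <- validate_cohort_config(config)
  n <- config$n_cases
  cols <- c("case_id", "time_of_death", "sex", "age", "pmi", "cause_class",
            "cause_subcategory", "brain_injury", "expr_bmal1", "expr_nr1d1",
            "ct_bmal1", "ct_nr1d1")
  if (n == 0L) {
    empty <- data.frame(case_id = character(), time_of_death = numeric(),
                        sex = character(), age = numeric(), pmi = numeric(),
                        cause_class = character(),
                        cause_subcategory = character(),
                        brain_injury = character(),
                        expr_bmal1 = numeric(), expr_nr1d1 = numeric(),
                        ct_bmal1 = numeric(), ct_nr1d1 = numeric(),
                        stringsAsFactors = FALSE)
    return(empty[cols])
  }
  comp <- config$composition
  age_loc <- trunc_norm_location(comp$age$mean, comp$age$sd,
                                 comp$age$min, comp$age$max)
  pmi_mu <- trunc_lnorm_meanlog(comp$pmi$mean, comp$pmi$sdlog, comp$pmi$max)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  tod <- stats::runif(n, 0, 24)
  sex <- sample(names(comp$sex), n, replace = TRUE, prob = comp$sex)
  # inverse-CDF sampling of the truncated distributions
  p_lo <- stats::pnorm(comp$age$min, age_loc, comp$age$sd)
  p_hi <- stats::pnorm(comp$age$max, age_loc, comp$age$sd)
  age <- stats::qnorm(p_lo + stats::runif(n) * (p_hi - p_lo),
                      age_loc, comp$age$sd)
  pmi <- stats::qlnorm(stats::runif(n) *
                         stats::plnorm(comp$pmi$max, pmi_mu, comp$pmi$sdlog),
                       pmi_mu, comp$pmi$sdlog)
  cause_idx <- sample.int(nrow(comp$causes), n, replace = TRUE,
                          prob = comp$causes$prob)
  cause_subcategory <- comp$causes$cause_subcategory[cause_idx]
  cause_class <- comp$causes$cause_class[cause_idx]
  chronic_draw <- stats::runif(n)
  brain_injury <- ifelse(
    cause_subcategory == "head_injury",
    ifelse(chronic_draw < comp$head_injury_chronic_prob, "chronic", "acute"),
    "none")
  arrhythmic <- stats::runif(n) < config$arrhythmic_fraction
  personal_phase <- stats::runif(n, 0, 24)
  z_b <- stats::rnorm(n)
  z_n <- stats::rnorm(n)

  shift <- ifelse(arrhythmic, personal_phase, 0)
  atten <- ifelse(brain_injury == "chronic",
                  config$chronic_brain_injury_attenuation, 1)
  decay <- -config$pmi_decay_rate * pmi  # common to both genes

  osc_n <- config$oscillator_nr1d1
  osc_b <- config$oscillator_bmal1
  log_en <- osc_n$mesor +
    atten * osc_n$amplitude *
      cos(2 * pi * (tod - (osc_n$acrophase + shift)) / 24) +
    osc_n$noise_sd * z_n + decay
  log_eb <- osc_b$mesor +
    atten * osc_b$amplitude *
      cos(2 * pi * (tod - (osc_b$acrophase + shift)) / 24) +
    osc_b$noise_sd * z_b + decay
  expr_nr1d1 <- exp(log_en)
  expr_bmal1 <- exp(log_eb)

  data.frame(
    case_id = sprintf("case_%05d", seq_len(n)),
    time_of_death = tod,
    sex = sex,
    age = age,
    pmi = pmi,
    cause_class = cause_class,
    cause_subcategory = cause_subcategory,
    brain_injury = brain_injury,
    expr_bmal1 = expr_bmal1,
    expr_nr1d1 = expr_nr1d1,
    ct_bmal1 = ct_from_expression(expr_bmal1, config$ct_efficiency),
    ct_nr1d1 = ct_from_expression(expr_nr1d1, config$ct_efficiency),
    stringsAsFactors = FALSE
  )
}
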