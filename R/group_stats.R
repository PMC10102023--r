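#' Per-time-domain summary of a ratio
#'
#' Computes the case count, mean and standard error of the mean (SEM,
#' sample standard deviation over the square root of n) of the chosen ratio
#' in each of the four time domains. Domains with no cases are reported
#' with `n = 0` and `NA` mean/SEM; domains with one case have a mean but an
#' `NA` SEM.
#'
#' @param quantified A quantified cohort (see [quantify_cohort()]) with
#'   `time_domain` and ratio columns.
#' @param which Which ratio to summarize: `"nb"` (NR1D1/BMAL1) or `"bn"`.
#' @return A data frame with one row per domain: `domain`, `n`, `mean`,
#'   `sem`.
#' @export
domain_summary <- function(quantified, which = c("nb", "bn")) {
  which <- match.arg(which)
  col <- paste0(which, "_ratio")
  stopifnot(is.data.frame(quantified),
            all(c("time_domain", col) %in% names(quantified)))
  out <- do.call(rbind, lapply(time_domains(), function(d) {
    x <- quantified[[col]][quantified$time_domain == d]
    n <- length(x)
    data.frame(domain = d, n = n,
               mean = if (n >= 1) mean(x) else NA_real_,
               sem = if (n >= 2) stats::sd(x) / sqrt(n) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

significance_label <- function(p) {
  ifelse(p < 0.01, "p<0.01", ifelse(p < 0.05, "p<0.05", "ns"))
}

#' Scheffé pairwise multiple comparisons
#'
#' Post-hoc comparison of all group pairs after a one-way layout, using the
#' classical Scheffé procedure: with k groups and N observations,
#' \deqn{F_s = \frac{(\bar x_i - \bar x_j)^2}{\mathrm{MSW}\,(1/n_i + 1/n_j)},}
#' where MSW is the pooled within-group mean square on `N - k` degrees of
#' freedom, and the p-value is the upper tail of the `F(k-1, N-k)`
#' distribution evaluated at `F_s / (k - 1)`. For `k = 2` this reduces to
#' the one-way ANOVA omnibus test. The procedure controls the familywise
#' error rate over all contrasts.
#'
#' @param groups A named list of numeric vectors, one per group (each with
#'   at least 2 observations).
#' @return A data frame with one row per unordered pair: `group_i`,
#'   `group_j`, `statistic` (the Scheffé F value `F_s`), `p_value`,
#'   `significance` (`ns` / `p<0.05` / `p<0.01`).
#' @examples
#' scheffe_pairwise(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8)))
#' @export
scheffe_pairwise <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || anyNA(names(groups)) ||
      any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2))
    stop("every group must contain at least 2 observations", call. = FALSE)
  k <- length(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  msw <- ssw / (N - k)

  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    d2 <- (means[i] - means[j])^2
    if (msw == 0) {
      # degenerate: all observations equal within groups
      if (d2 == 0) c(stat = 0, p = 1) else {
        warning("zero within-group variance with unequal means; p set to 0",
                call. = FALSE)
        c(stat = Inf, p = 0)
      }
    } else {
      fs <- unname(d2 / (msw * (1 / ns[i] + 1 / ns[j])))
      c(stat = fs,
        p = stats::pf(fs / (k - 1), k - 1, N - k, lower.tail = FALSE))
    }
  })
  out <- data.frame(
    group_i = names(groups)[pairs[1, ]],
    group_j = names(groups)[pairs[2, ]],
    statistic = res["stat", ],
    p_value = res["p", ],
    stringsAsFactors = FALSE)
  out$significance <- significance_label(out$p_value)
  rownames(out) <- NULL
  out
}

#' Unpaired Student t-test
#'
#' Two-sided, equal-variance (pooled) Student t-test between two groups,
#' returned in the same comparison-row format as [scheffe_pairwise()].
#'
#' @param a,b Numeric vectors with at least 2 observations each.
#' @param name_a,name_b Labels for the two groups.
#' @return A one-row data frame: `group_i`, `group_j`, `statistic` (t),
#'   `p_value`, `significance`.
#' @export
t_test_unpaired <- function(a, b, name_a = "a", name_b = "b") {
  if (length(a) < 2 || length(b) < 2)
    stop("both groups need at least 2 observations", call. = FALSE)
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  if (pooled_var == 0) {
    if (mean(a) == mean(b)) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      warning("zero pooled variance with unequal means; p set to 0",
              call. = FALSE)
      tt <- list(statistic = c(t = Inf), p.value = 0)
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = TRUE)
  }
  data.frame(group_i = name_a, group_j = name_b,
             statistic = unname(tt$statistic),
             p_value = tt$p.value,
             significance = significance_label(tt$p.value),
             stringsAsFactors = FALSE)
}

subgroup_factors <- c("sex", "age_group", "pmi_group", "cause_class",
                      "brain_injury_course")

#' Assign subgroup levels for a stratification factor
#'
#' Membership rules: `age_group` splits at 19/20 and 69/70 years
#' (`<=19`, `20-69`, `>=70`); `pmi_group` splits at 30 h (`<30h`, `>=30h`);
#' `brain_injury_course` is `acute` or `chronic` for head-injury deaths and
#' `NA` otherwise (so this factor stratifies the head-injury subcohort
#' only).
#'
#' @param cohort A cohort data frame.
#' @param factor One of `"sex"`, `"age_group"`, `"pmi_group"`,
#'   `"cause_class"`, `"brain_injury_course"`.
#' @return A character vector of level labels (with `NA` for cases outside
#'   the factor's scope).
#' @export
subgroup_levels <- function(cohort, factor = subgroup_factors) {
  factor <- match.arg(factor)
  switch(factor,
    sex = cohort$sex,
    age_group = ifelse(cohort$age <= 19, "<=19",
                       ifelse(cohort$age < 70, "20-69", ">=70")),
    pmi_group = ifelse(cohort$pmi < 30, "<30h", ">=30h"),
    cause_class = cohort$cause_class,
    brain_injury_course = ifelse(cohort$brain_injury %in%
                                   c("acute", "chronic"),
                                 cohort$brain_injury, NA_character_))
}

#' Subgroup analysis of the ratio rhythms
#'
#' For each level of a stratification factor, computes the four-domain
#' summaries and all pairwise Scheffé comparisons for both ratios,
#' mirroring the sex, age-group, PMI-group, cause-of-death and
#' brain-injury analyses of the underlying method. For
#' `factor = "brain_injury_course"` the acute-vs-chronic per-domain
#' unpaired t-tests are additionally returned.
#'
#' Levels in which some domain has fewer than 2 cases are summarized but
#' their Scheffé comparisons are skipped with a warning (`comparisons` is
#' `NULL` for that level), never an error.
#'
#' @param quantified A quantified cohort ([quantify_cohort()]).
#' @param factor Stratification factor; see [subgroup_levels()].
#' @return A list with one element per level, each containing
#'   `summary_nb`, `summary_bn`, `comparisons_nb`, `comparisons_bn`; for
#'   `brain_injury_course`, the list also carries a `between_level_t_tests`
#'   element (per-domain acute-vs-chronic tests for both ratios).
#' @export
subgroup_analysis <- function(quantified, factor = subgroup_factors) {
  factor <- match.arg(factor)
  stopifnot(is.data.frame(quantified),
            "time_domain" %in% names(quantified))
  lev <- subgroup_levels(quantified, factor)
  levels_present <- sort(unique(lev[!is.na(lev)]))
  out <- lapply(levels_present, function(l) {
    sub <- quantified[!is.na(lev) & lev == l, , drop = FALSE]
    res <- list(n = nrow(sub),
                summary_nb = domain_summary(sub, "nb"),
                summary_bn = domain_summary(sub, "bn"))
    groups_nb <- split(sub$nb_ratio, factor(sub$time_domain,
                                            levels = time_domains()))
    if (all(vapply(groups_nb, length, integer(1)) >= 2)) {
      res$comparisons_nb <- scheffe_pairwise(groups_nb)
      res$comparisons_bn <- scheffe_pairwise(
        split(sub$bn_ratio, factor(sub$time_domain,
                                   levels = time_domains())))
    } else {
      warning(sprintf(
        "level '%s': some time domain has fewer than 2 cases; comparisons skipped",
        l), call. = FALSE)
      res$comparisons_nb <- NULL
      res$comparisons_bn <- NULL
    }
    res
  })
  names(out) <- levels_present
  if (factor == "brain_injury_course" &&
      all(c("acute", "chronic") %in% levels_present)) {
    out <- c(out, list(between_level_t_tests =
                         brain_injury_t_tests(quantified, lev)))
  }
  out
}

# per-domain acute-vs-chronic unpaired t-tests, both ratios
brain_injury_t_tests <- function(quantified, lev) {
  do.call(rbind, lapply(time_domains(), function(d) {
    do.call(rbind, lapply(c("nb", "bn"), function(w) {
      col <- paste0(w, "_ratio")
      a <- quantified[[col]][!is.na(lev) & lev == "acute" &
                               quantified$time_domain == d]
      b <- quantified[[col]][!is.na(lev) & lev == "chronic" &
                               quantified$time_domain == d]
      if (length(a) < 2 || length(b) < 2) return(NULL)
      row <- t_test_unpaired(a, b, "acute", "chronic")
      cbind(data.frame(domain = d, ratio = w, stringsAsFactors = FALSE),
            row)
    }))
  }))
}

#' Tidy table of subgroup comparisons
#'
#' Flattens the result of [subgroup_analysis()] into one row per
#' (level, ratio, domain pair), suitable for CSV export.
#'
#' @param analysis Result of [subgroup_analysis()].
#' @param factor The factor label to record in the output.
#' @return A data frame with columns `factor`, `level`, `ratio`,
#'   `group_i`, `group_j`, `statistic`, `p_value`, `significance`.
#' @export
tidy_comparisons <- function(analysis, factor = "factor") {
  levels <- setdiff(names(analysis), "between_level_t_tests")
  out <- do.call(rbind, lapply(levels, function(l) {
    do.call(rbind, lapply(c("nb", "bn"), function(w) {
      cmp <- analysis[[l]][[paste0("comparisons_", w)]]
      if (is.null(cmp)) return(NULL)
      cbind(data.frame(factor = factor, level = l, ratio = w,
                       stringsAsFactors = FALSE), cmp)
    }))
  }))
  if (is.null(out))
    out <- data.frame(factor = character(), level = character(),
                      ratio = character(), group_i = character(),
                      group_j = character(), statistic = numeric(),
                      p_value = numeric(), significance = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
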