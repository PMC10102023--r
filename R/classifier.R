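#' Construct a threshold decision rule
#'
#' One forensic decision rule: if the chosen ratio strictly exceeds
#' `threshold`, the time of death is predicted to lie within the closed
#' clock window `[window_start, window_end]`. Strict `>` at the threshold
#' and closed windows follow the published criteria ("ratio > 25" implying
#' "death between 1:00 and 10:00").
#'
#' @param ratio_key `"nb"` (morning rules) or `"bn"` (evening rules).
#' @param threshold Positive ratio threshold; cases with ratio strictly
#'   greater are covered by the rule.
#' @param window_start,window_end Closed clock window in hours,
#'   `0 <= start < end <= 24` (default rules do not wrap midnight).
#' @param tier `"low"` or `"high"`; high-tier rules have a higher threshold
#'   and a narrower window nested in the low-tier window.
#' @return An object of class `threshold_rule`.
#' @export
threshold_rule <- function(ratio_key = c("nb", "bn"), threshold,
                           window_start, window_end,
                           tier = c("low", "high")) {
  ratio_key <- match.arg(ratio_key)
  tier <- match.arg(tier)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("`threshold` must be a single positive number", call. = FALSE)
  if (!(window_start >= 0 && window_start < window_end && window_end <= 24))
    stop("window must satisfy 0 <= start < end <= 24", call. = FALSE)
  structure(list(ratio_key = ratio_key, threshold = threshold,
                 window_start = window_start, window_end = window_end,
                 tier = tier),
            class = "threshold_rule")
}

#' Default forensic decision rules
#'
#' The four published criteria: N/B > 25 predicts death in `[1:00, 10:00]`,
#' N/B > 40 in `[3:00, 9:00]`, B/N > 1.5 in `[14:00, 22:00]`, and B/N > 4
#' in `[15:00, 20:00]`.
#'
#' @return A validated list of four [threshold_rule()] objects.
#' @export
default_threshold_rules <- function() {
  counts <- reference_threshold_counts()
  rules <- lapply(seq_len(nrow(counts)), function(i) {
    threshold_rule(counts$ratio_key[i], counts$threshold[i],
                   counts$window_start[i], counts$window_end[i],
                   counts$tier[i])
  })
  validate_threshold_rules(rules)
}

#' Check mutual exclusivity of a rule set
#'
#' Since `bn = 1/nb`, a single case can trigger both a morning (`nb`) rule
#' and an evening (`bn`) rule only if some nb threshold `T_n` and bn
#' threshold `T_b` satisfy `T_n * T_b < 1` (then any `nb` in
#' `(T_n, 1/T_b)` exceeds both). The rule set is mutually exclusive iff
#' the product of the smallest nb and bn thresholds is at least 1.
#'
#' @param rules A list of [threshold_rule()] objects.
#' @return `TRUE` iff no ratio value can trigger both a morning and an
#'   evening rule.
#' @export
mutual_exclusivity_check <- function(rules) {
  keys <- vapply(rules, `[[`, character(1), "ratio_key")
  thr <- vapply(rules, `[[`, numeric(1), "threshold")
  if (!any(keys == "nb") || !any(keys == "bn")) return(TRUE)
  min(thr[keys == "nb"]) * min(thr[keys == "bn"]) >= 1
}

validate_threshold_rules <- function(rules) {
  stopifnot(is.list(rules),
            all(vapply(rules, inherits, logical(1), "threshold_rule")))
  for (key in c("nb", "bn")) {
    sub <- Filter(function(r) r$ratio_key == key, rules)
    tiers <- vapply(sub, `[[`, character(1), "tier")
    if (any(duplicated(tiers)))
      stop(sprintf("duplicate %s tier for ratio '%s'",
                   tiers[duplicated(tiers)][1], key), call. = FALSE)
    if (all(c("low", "high") %in% tiers)) {
      lo <- sub[[which(tiers == "low")]]
      hi <- sub[[which(tiers == "high")]]
      if (hi$threshold <= lo$threshold)
        stop(sprintf("high-tier threshold must exceed low-tier for '%s'",
                     key), call. = FALSE)
      if (hi$window_start < lo$window_start ||
          hi$window_end > lo$window_end)
        stop(sprintf("high-tier window must nest in low-tier window for '%s'",
                     key), call. = FALSE)
    }
  }
  if (!mutual_exclusivity_check(rules))
    stop(paste("rules are not mutually exclusive: a single case could",
               "receive both a morning and an evening prediction"),
         call. = FALSE)
  rules
}

# tier label combining rule tier and reading direction
tier_label <- function(ratio_key, tier) {
  paste0(tier, "_", ifelse(ratio_key == "nb", "morning", "evening"))
}

#' Predict a time-of-death window from ratio values
#'
#' Applies a rule set to N/B and B/N ratio values; among applicable rules
#' the highest tier wins (high over low). Cases below every threshold get
#' tier `"none"` and no window — an explicit "no statement", not an
#' exclusion of morning or evening death.
#'
#' @param nb_ratio,bn_ratio Numeric vectors of ratio values.
#' @param rules A validated rule list, default [default_threshold_rules()].
#' @return A data frame with columns `tier` (`none`, `low_morning`,
#'   `high_morning`, `low_evening`, `high_evening`), `window_start`,
#'   `window_end` (`NA` when tier is `none`).
#' @examples
#' predict_window(nb_ratio = c(50, 30, 10, 25), bn_ratio = c(0.02, 1/30, 0.1, 0.04))
#' @export
predict_window <- function(nb_ratio, bn_ratio,
                           rules = default_threshold_rules()) {
  rules <- validate_threshold_rules(rules)
  n <- length(nb_ratio)
  stopifnot(length(bn_ratio) == n)
  tier <- rep("none", n)
  ws <- rep(NA_real_, n)
  we <- rep(NA_real_, n)
  # apply low tiers first, then let high tiers overwrite
  ord <- order(vapply(rules, function(r) match(r$tier, c("low", "high")),
                      integer(1)))
  for (r in rules[ord]) {
    val <- if (r$ratio_key == "nb") nb_ratio else bn_ratio
    hit <- is.finite(val) & val > r$threshold
    tier[hit] <- tier_label(r$ratio_key, r$tier)
    ws[hit] <- r$window_start
    we[hit] <- r$window_end
  }
  data.frame(tier = tier, window_start = ws, window_end = we,
             stringsAsFactors = FALSE)
}

# closed-interval membership on the circular clock (windows may wrap)
in_window <- function(t, start, end) {
  ifelse(start <= end, t >= start & t <= end, t >= start | t <= end)
}

#' Evaluate predictions against known times of death
#'
#' Applies the rule set to a quantified cohort with known `time_of_death`
#' and reports, per tier and overall, how many cases received a prediction
#' (the yield) and how often the true time of death fell inside the
#' predicted window (the coverage, closed-interval membership).
#'
#' @param quantified A quantified cohort ([quantify_cohort()]) with
#'   `nb_ratio`, `bn_ratio` and `time_of_death` columns.
#' @param rules A validated rule list.
#' @return A list: `n_total`, `tier_counts` (named integer vector including
#'   `none`), `n_predicted`, `predicted_fraction`, `coverage` (`NA` when no
#'   case is predicted), `per_tier` (data frame with per-tier n and
#'   coverage), and `predictions` (the per-case prediction table).
#' @export
evaluate_predictions <- function(quantified,
                                 rules = default_threshold_rules()) {
  stopifnot(is.data.frame(quantified),
            all(c("nb_ratio", "bn_ratio", "time_of_death") %in%
                  names(quantified)))
  if (nrow(quantified) == 0) stop("empty cohort", call. = FALSE)
  pred <- predict_window(quantified$nb_ratio, quantified$bn_ratio, rules)
  pred$case_id <- if ("case_id" %in% names(quantified))
    quantified$case_id else as.character(seq_len(nrow(quantified)))
  predicted <- pred$tier != "none"
  pred$covered <- NA
  pred$covered[predicted] <- in_window(
    quantified$time_of_death[predicted],
    pred$window_start[predicted], pred$window_end[predicted])
  tiers <- c("none", "low_morning", "high_morning", "low_evening",
             "high_evening")
  tier_counts <- vapply(tiers, function(tt) sum(pred$tier == tt),
                        integer(1))
  per_tier <- do.call(rbind, lapply(setdiff(tiers, "none"), function(tt) {
    idx <- pred$tier == tt
    data.frame(tier = tt, n = sum(idx),
               coverage = if (any(idx)) mean(pred$covered[idx]) else
                 NA_real_,
               stringsAsFactors = FALSE)
  }))
  n_pred <- sum(predicted)
  list(
    n_total = nrow(quantified),
    tier_counts = tier_counts,
    n_predicted = n_pred,
    predicted_fraction = n_pred / nrow(quantified),
    coverage = if (n_pred > 0) mean(pred$covered[predicted]) else NA_real_,
    per_tier = per_tier,
    predictions = pred[c("case_id", "tier", "window_start", "window_end",
                         "covered")]
  )
}

#' Tightest clock window containing threshold-exceeding deaths
#'
#' Reconstructs a decision window empirically: among cases whose chosen
#' ratio strictly exceeds `threshold`, finds the minimal-length arc of the
#' circular 24-h clock containing all their true times of death. The
#' minimal covering arc is the complement of the largest gap between
#' circularly sorted time points, so the window may wrap midnight.
#'
#' @param quantified A quantified cohort with `time_of_death` and ratio
#'   columns.
#' @param ratio_key `"nb"` or `"bn"`.
#' @param threshold Positive threshold (strict `>`).
#' @return A list `start`, `end` (clock hours; `start > end` indicates a
#'   window wrapping midnight) and `length` (arc length in hours).
#' @examples
#' toy <- data.frame(time_of_death = c(23, 1, 2), nb_ratio = c(30, 30, 30),
#'                   bn_ratio = 1 / c(30, 30, 30))
#' tightest_window(toy, "nb", 25)  # [23, 2], 3 h
#' @export
tightest_window <- function(quantified, ratio_key = c("nb", "bn"),
                            threshold) {
  ratio_key <- match.arg(ratio_key)
  col <- paste0(ratio_key, "_ratio")
  stopifnot(is.data.frame(quantified),
            all(c("time_of_death", col) %in% names(quantified)))
  t <- quantified$time_of_death[is.finite(quantified[[col]]) &
                                  quantified[[col]] > threshold]
  if (length(t) == 0)
    stop("no case exceeds the threshold", call. = FALSE)
  t <- sort(t %% 24)
  if (length(t) == 1) return(list(start = t, end = t, length = 0))
  gaps <- c(diff(t), t[1] + 24 - t[length(t)])
  g <- which.max(gaps)
  # the arc is everything except the largest gap
  start <- if (g == length(t)) t[1] else t[g + 1]
  end <- t[g]
  list(start = start, end = end,
       length = (end - start) %% 24)
}
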