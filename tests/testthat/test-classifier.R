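test_that("default rules map ratios to the published tiers and windows", {
  pred <- predict_window(nb_ratio = c(50, 30, 10, 25, 1, 1),
                         bn_ratio = c(1 / 50, 1 / 30, 0.1, 0.04, 2, 5))
  expect_equal(pred$tier, c("high_morning", "low_morning", "none", "none",
                            "low_evening", "high_evening"))
  expect_equal(pred$window_start, c(3, 1, NA, NA, 14, 15))
  expect_equal(pred$window_end, c(9, 10, NA, NA, 22, 20))
  # strict threshold: exactly 40 stays low tier, exactly 25 stays none
  at <- predict_window(nb_ratio = c(40, 25), bn_ratio = c(1 / 40, 1 / 25))
  expect_equal(at$tier, c("low_morning", "none"))
})

test_that("default rules are nested and mutually exclusive", {
  rules <- default_threshold_rules()
  expect_true(mutual_exclusivity_check(rules))
  for (key in c("nb", "bn")) {
    sub <- Filter(function(r) r$ratio_key == key, rules)
    tiers <- vapply(sub, `[[`, character(1), "tier")
    lo <- sub[[which(tiers == "low")]]
    hi <- sub[[which(tiers == "high")]]
    expect_gt(hi$threshold, lo$threshold)
    expect_gte(hi$window_start, lo$window_start)
    expect_lte(hi$window_end, lo$window_end)
  }
  # every high-tier case also exceeds the low-tier threshold
  set.seed(16)
  nb <- exp(stats::runif(2000, -5, 5))
  pred <- predict_window(nb, 1 / nb)
  expect_true(all(nb[pred$tier == "high_morning"] > 25))
  expect_true(all((1 / nb)[pred$tier == "high_evening"] > 1.5))
  # no case gets both a morning and an evening call (reciprocity)
  expect_false(any(grepl("morning", pred$tier) & grepl("evening", pred$tier)))
})

test_that("inconsistent rule sets are rejected at load time", {
  bad_nest <- list(
    threshold_rule("nb", 25, 1, 10, "low"),
    threshold_rule("nb", 40, 0.5, 9, "high"))  # high window escapes low
  expect_error(predict_window(1, 1, bad_nest), "nest")
  not_exclusive <- list(
    threshold_rule("nb", 0.5, 1, 10, "low"),
    threshold_rule("bn", 0.5, 14, 22, "low"))
  expect_error(predict_window(1, 1, not_exclusive), "mutually exclusive")
  expect_false(mutual_exclusivity_check(not_exclusive))
  expect_error(threshold_rule("nb", -1, 1, 10, "low"), "positive")
  expect_error(threshold_rule("nb", 25, 10, 1, "low"), "start < end")
})

test_that("threshold products determine mutual exclusivity exactly", {
  # numeric scan: a rule pair is co-triggerable iff T_nb * T_bn < 1
  for (t_nb in c(0.2, 0.5, 1, 2, 25)) {
    for (t_bn in c(0.2, 0.5, 1, 1.5, 4)) {
      rules <- list(threshold_rule("nb", t_nb, 1, 10, "low"),
                    threshold_rule("bn", t_bn, 14, 22, "low"))
      nb_grid <- exp(seq(-8, 8, length.out = 4001))
      both <- any(nb_grid > t_nb & 1 / nb_grid > t_bn)
      expect_equal(mutual_exclusivity_check(rules), !both)
    }
  }
})

test_that("prediction evaluation reports yield and coverage", {
  q <- data.frame(case_id = letters[1:4],
                  time_of_death = c(6, 12, 18, 23),
                  nb_ratio = c(50, 2, 1, 3),
                  bn_ratio = c(1 / 50, 0.5, 1, 1 / 3))
  ev <- evaluate_predictions(q)
  expect_equal(ev$n_predicted, 1)
  expect_equal(ev$predicted_fraction, 0.25)
  expect_equal(ev$coverage, 1)
  expect_equal(unname(ev$tier_counts["high_morning"]), 1L)

  none <- transform(q, nb_ratio = 1, bn_ratio = 1)
  ev0 <- evaluate_predictions(none)
  expect_equal(ev0$predicted_fraction, 0)
  expect_true(is.na(ev0$coverage))
  expect_error(evaluate_predictions(q[0, ]), "empty")

  # coverage uses closed windows: death at exactly 10:00 is covered by [1,10]
  edge <- data.frame(case_id = "e", time_of_death = 10,
                     nb_ratio = 30, bn_ratio = 1 / 30)
  expect_equal(evaluate_predictions(edge)$coverage, 1)
})

test_that("tightest windows equal the brute-force minimal circular arc", {
  mk <- function(times, nb = 30) {
    data.frame(time_of_death = times, nb_ratio = rep(nb, length(times)),
               bn_ratio = 1 / rep(nb, length(times)))
  }
  w <- tightest_window(mk(c(4, 5, 6)), "nb", 25)
  expect_equal(w[c("start", "end", "length")],
               list(start = 4, end = 6, length = 2))
  # wrapping across midnight
  w <- tightest_window(mk(c(23, 1, 2)), "nb", 25)
  expect_equal(w[c("start", "end", "length")],
               list(start = 23, end = 2, length = 3))
  # a single exceeding case gives a degenerate arc
  w <- tightest_window(mk(5.5), "nb", 25)
  expect_equal(w$length, 0)
  expect_error(tightest_window(mk(numeric(0)), "nb", 25), "no case")

  set.seed(17)
  for (i in 1:50) {
    times <- stats::runif(sample(2:12, 1), 0, 24)
    w <- tightest_window(mk(times), "nb", 25)
    bf <- brute_force_arc(times)
    expect_equal(w$length, bf$length)
    # all exceeding times lie inside the reported arc
    inside <- if (w$start <= w$end)
      times >= w$start & times <= w$end
    else times >= w$start | times <= w$end
    expect_true(all(inside))
  }
})

test_that("raising a threshold never widens the window or adds predictions", {
  q <- quantify_cohort(generate_cohort(small_config(n = 2000, seed = 18)))
  thresholds <- c(5, 10, 25, 40)
  n_above <- vapply(thresholds, function(th) sum(q$nb_ratio > th),
                    numeric(1))
  expect_true(all(diff(n_above) <= 0))
  lens <- vapply(thresholds, function(th)
    tightest_window(q, "nb", th)$length, numeric(1))
  expect_true(all(diff(lens) <= 1e-9))
})
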