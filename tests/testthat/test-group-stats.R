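make_quantified <- function(values, domains) {
  data.frame(time_domain = domains, nb_ratio = values,
             bn_ratio = 1 / values, stringsAsFactors = FALSE)
}

test_that("domain summaries report n, mean and SEM per domain", {
  q <- make_quantified(c(2, 4, 7, 7, 7), c("morning", "morning", "noon",
                                           "noon", "evening"))
  s <- domain_summary(q, "nb")
  expect_equal(s$domain, time_domains())
  expect_equal(s$n, c(2L, 2L, 1L, 0L))
  expect_equal(s$mean[1], 3)
  expect_equal(s$sem[1], 1)              # sd(c(2,4))/sqrt(2) = 1
  expect_equal(s$sem[2], 0)              # identical values
  expect_true(is.na(s$sem[3]))           # single case: no SEM
  expect_true(is.na(s$mean[4]) && is.na(s$sem[4]))  # empty domain flagged
})

test_that("Scheffé pairwise comparisons match an independent oracle", {
  res <- scheffe_pairwise(list(a = c(1, 2, 3), b = c(2, 3, 4),
                               c = c(6, 7, 8)))
  # oracle: MSW = 6/6 = 1; F_s = diff^2 / (MSW * 2/3); p from F(2, 6)
  # at F_s/2, evaluated through the beta representation of the F CDF
  expect_equal(res$statistic, c(1.5, 37.5, 24))
  expect_equal(res$p_value, c(0.512, 0.00262413383083, 0.008),
               tolerance = 1e-10)
  expect_equal(res$significance, c("ns", "p<0.01", "p<0.01"))
})

test_that("Scheffé with two groups reduces to the one-way ANOVA omnibus test", {
  a <- c(1.2, 3.4, 2.2, 5.1)
  b <- c(2.0, 4.4, 6.1)
  res <- scheffe_pairwise(list(a = a, b = b))
  expect_equal(res$p_value, 0.435237966451, tolerance = 1e-10)
  # cross-check against stats::aov on randomly drawn groups
  set.seed(11)
  for (i in 1:5) {
    x <- stats::rnorm(6 + i)
    y <- stats::rnorm(9, mean = 0.5)
    p_scheffe <- scheffe_pairwise(list(x = x, y = y))$p_value
    fit <- summary(stats::aov(v ~ g, data.frame(
      v = c(x, y), g = rep(c("x", "y"), c(length(x), length(y))))))
    expect_equal(p_scheffe, fit[[1]]$`Pr(>F)`[1])
  }
})

test_that("Scheffé p-values are invariant to relabeling and location shifts", {
  set.seed(12)
  groups <- list(a = stats::rnorm(8), b = stats::rnorm(5, 1),
                 c = stats::rnorm(7, 2), d = stats::rnorm(6))
  res <- scheffe_pairwise(groups)
  shifted <- scheffe_pairwise(lapply(groups, function(x) x + 100))
  expect_equal(res$p_value, shifted$p_value)
  perm <- scheffe_pairwise(groups[c("c", "a", "d", "b")])
  key <- function(d) {
    pair <- apply(cbind(d$group_i, d$group_j), 1,
                  function(r) paste(sort(r), collapse = "-"))
    stats::setNames(d$p_value, pair)[order(pair)]
  }
  expect_equal(key(res), key(perm))
})

test_that("degenerate zero-variance groups are handled explicitly", {
  res <- scheffe_pairwise(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_true(all(res$p_value == 1))
  expect_warning(
    res2 <- scheffe_pairwise(list(a = c(2, 2), b = c(5, 5))),
    "zero within-group variance")
  expect_equal(res2$p_value, 0)
  expect_error(scheffe_pairwise(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("the unpaired Student t-test matches a closed-form oracle", {
  res <- t_test_unpaired(c(1, 2, 3, 4), c(3, 4, 5, 6))
  # pooled var = 5/3, t = -2 / sqrt(5/6), p = 2 P(T_6 < t)
  expect_equal(res$statistic, -2 / sqrt(5 / 6))
  expect_equal(res$p_value, 0.070987654321, tolerance = 1e-10)
  # symmetry in the group order
  swapped <- t_test_unpaired(c(3, 4, 5, 6), c(1, 2, 3, 4))
  expect_equal(swapped$p_value, res$p_value)
  expect_equal(swapped$statistic, -res$statistic)
  # equal groups
  same <- t_test_unpaired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_warning(zed <- t_test_unpaired(c(1, 1), c(2, 2)), "zero pooled")
  expect_equal(zed$p_value, 0)
})

test_that("subgroup analysis restricted to one sex equals the whole-cohort analysis", {
  q <- quantify_cohort(generate_cohort(small_config(n = 2000, seed = 13)))
  males <- q[q$sex == "male", ]
  by_sex <- subgroup_analysis(males, "sex")
  expect_named(by_sex, "male")
  expect_equal(by_sex$male$summary_nb, domain_summary(males, "nb"))
  groups <- split(males$nb_ratio,
                  factor(males$time_domain, levels = time_domains()))
  expect_equal(by_sex$male$comparisons_nb$p_value,
               scheffe_pairwise(groups)$p_value)
})

test_that("subgroup levels partition the cohort and small levels warn", {
  q <- quantify_cohort(generate_cohort(small_config(n = 3000, seed = 14)))
  for (f in c("sex", "age_group", "pmi_group", "cause_class")) {
    lev <- subgroup_levels(q, f)
    expect_false(anyNA(lev))
    expect_equal(sum(table(lev)), nrow(q))
  }
  # brain-injury course covers only head-injury deaths
  lev <- subgroup_levels(q, "brain_injury_course")
  expect_equal(sum(!is.na(lev)), sum(q$cause_subcategory == "head_injury"))

  # a level whose domains are too thin is skipped with a warning
  thin <- q[c(which(q$sex == "male")[1:3], which(q$sex == "female")[1:60]), ]
  expect_warning(res <- subgroup_analysis(thin, "sex"),
                 "fewer than 2 cases")
  expect_null(res$male$comparisons_nb)
  expect_equal(res$male$summary_nb$n[1] + res$male$summary_nb$n[2] +
                 res$male$summary_nb$n[3] + res$male$summary_nb$n[4], 3)
})

test_that("acute-vs-chronic brain-injury t-tests are produced per domain", {
  cfg <- small_config(n = 4000, seed = 15,
                      composition = local({
                        comp <- default_composition()
                        comp$causes$prob <-
                          ifelse(comp$causes$cause_subcategory ==
                                   "head_injury", 1, 0)
                        comp$head_injury_chronic_prob <- 0.5
                        comp
                      }))
  q <- quantify_cohort(generate_cohort(cfg))
  res <- subgroup_analysis(q, "brain_injury_course")
  expect_setequal(setdiff(names(res), "between_level_t_tests"),
                  c("acute", "chronic"))
  tt <- res$between_level_t_tests
  expect_equal(nrow(tt), 8)  # 4 domains x 2 ratios
  expect_true(all(tt$p_value >= 0 & tt$p_value <= 1))
  # oracle for one cell
  a <- q$nb_ratio[q$brain_injury == "acute" & q$time_domain == "morning"]
  b <- q$nb_ratio[q$brain_injury == "chronic" & q$time_domain == "morning"]
  expect_equal(tt$p_value[tt$domain == "morning" & tt$ratio == "nb"],
               t_test_unpaired(a, b)$p_value)
})
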