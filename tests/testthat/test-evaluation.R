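pred_records <- function(age, predicted, sex = "female", model = "m") {
  data.frame(sample_id = sprintf("S%d", seq_along(age)), sex = sex,
             age = age, model = model, predicted_age = predicted,
             delta_age = predicted - age,
             age_group = assign_age_group(age),
             stringsAsFactors = FALSE)
}

test_that("age-group boundaries follow completed years", {
  expect_equal(assign_age_group(c(17, 18, 80, 81, 101)),
               c("young", "adult", "adult", "old", "old"))
  expect_equal(assign_age_group(17.9), "young")   # 17 completed years
  expect_equal(assign_age_group(80.99), "adult")
  expect_equal(assign_age_group(120), "old")      # beyond last hi -> last
  expect_equal(assign_age_group(0), "young")
  expect_error(assign_age_group(-0.5), "validation")
})

test_that("schemes must be contiguous, ordered and zero-based", {
  expect_error(age_group_scheme(c("a", "b"), c(0, 17), c(17, 40)),
               "contiguous")
  expect_error(age_group_scheme(c("a", "b"), c(0, 19), c(17, 40)),
               "contiguous")
  expect_error(age_group_scheme(c("a", "b"), c(5, 18), c(17, 40)),
               "start at age 0")
  expect_error(age_group_scheme(c("a", "a"), c(0, 18), c(17, 40)),
               "duplicate")
  custom <- age_group_scheme(c("child", "rest"), c(0, 13), c(12, 101))
  expect_equal(assign_age_group(12.5, custom), "child")
})

test_that("single-stratum cohorts collapse to identical marginal metrics", {
  set.seed(41)
  rec <- pred_records(runif(12, 20, 60), runif(12, 20, 60), sex = "female")
  rep_ <- evaluate_strata(rec)
  expect_setequal(
    paste(rep_$age_group, rep_$sex),
    c("adult female", "adult all", "all female", "all all")
  )
  expect_equal(length(unique(rep_$mad)), 1)
  expect_equal(length(unique(rep_$r2)), 1)
  expect_equal(length(unique(rep_$pcp_5)), 1)
  expect_true(all(rep_$n == 12))
})

test_that("perfect predictions score perfectly in every stratum", {
  set.seed(42)
  age <- runif(40, 0, 101)
  rec <- pred_records(age, age, sex = sample(c("female", "male"), 40, TRUE))
  rep_ <- evaluate_strata(rec)
  expect_true(all(rep_$mad == 0))
  expect_true(all(rep_$see[rep_$n >= 3] == 0))
  expect_true(all(rep_$pcp_5 == 100))
  expect_true(all(rep_$pcp_7.5 == 100))
  expect_true(all(rep_$pcp_10 == 100))
  expect_true(all(abs(rep_$r2[!is.na(rep_$r2)] - 1) < 1e-12))
})

test_that("per-group MADs equal hand-computed means", {
  age <- c(5, 10, 15, 30, 40, 50)
  pred <- age + c(1, -2, 3, -4, 5, -6)
  rec <- pred_records(age, pred)
  rep_ <- evaluate_strata(rec)
  get <- function(g) rep_$mad[rep_$age_group == g & rep_$sex == "all"]
  expect_equal(get("young"), 2)
  expect_equal(get("adult"), 5)
  expect_equal(get("all"), 3.5)
})

test_that("small or degenerate strata omit SEE and R2 with NA", {
  rec <- pred_records(c(5, 6, 30, 40, 50), c(6, 7, 31, 41, 51))
  rep_ <- evaluate_strata(rec)
  young <- rep_[rep_$age_group == "young" & rep_$sex == "all", ]
  expect_equal(young$n, 2)
  expect_true(is.na(young$see))   # n < 3: SEE denominator undefined
  expect_false(is.na(young$mad))
  expect_error(evaluate_strata(rec[0, ]), "degenerate")
})

test_that("stratum counts satisfy the marginal summation invariants", {
  set.seed(43)
  coh <- simulate_cohort(cohort_config(n = 200, seed = 17))
  coh$sex[1:5] <- "unknown"
  pr <- predict_age(matched_clock(attr(coh, "config")), coh)
  rep_ <- evaluate_strata(pr)

  for (sx in c("female", "male", "all")) {
    per_group <- rep_$n[rep_$age_group != "all" & rep_$sex == sx]
    total <- rep_$n[rep_$age_group == "all" & rep_$sex == sx]
    expect_equal(sum(per_group), total)
  }
  for (g in unique(rep_$age_group)) {
    sexed <- sum(rep_$n[rep_$age_group == g & rep_$sex %in%
                          c("female", "male")])
    expect_lte(sexed, rep_$n[rep_$age_group == g & rep_$sex == "all"])
  }
  # unknown-sex records are counted in pooled strata only
  expect_equal(rep_$n[rep_$age_group == "all" & rep_$sex == "all"],
               nrow(pr))
})

test_that("rank-sum comparison: exchangeable groups give p near 1", {
  d <- c(-3.2, -1.1, 0.4, 0.9, 2.2, 3.3, -0.5, 1.7, -2.8, 0.1)
  cmp <- compare_delta_age(d, d, "adult", "old")
  expect_gte(cmp$p_value, 0.95)
  expect_equal(cmp$n_a, 10)
})

test_that("rank-sum comparison matches exhaustive enumeration when exact", {
  a <- c(1, 2, 3)
  b <- c(101, 102, 103)
  cmp <- compare_delta_age(a, b)
  expect_equal(cmp$p_value, oracle_ranksum_p(a, b), tolerance = 1e-12)
  expect_equal(cmp$p_value, 0.1)  # 2 / choose(6, 3)
  expect_equal(cmp$statistic, 0)  # minimal U for the first group

  set.seed(44)
  for (rep in 1:20) {
    a <- rnorm(sample(3:8, 1))
    b <- rnorm(sample(3:8, 1), mean = runif(1, -2, 2))
    expect_equal(compare_delta_age(a, b)$p_value, oracle_ranksum_p(a, b),
                 tolerance = 1e-10)
  }
  expect_error(compare_delta_age(numeric(0), 1:3), "non-empty")
})

test_that("dynamics curves are cumulative and consistent with the metrics", {
  # constant |error| -> flat MAD curve
  age <- seq(1, 60, by = 1)
  rec <- pred_records(age, age + 3)
  cv <- metric_dynamics(rec, "mad")
  expect_true(all(abs(cv$value - 3) < 1e-12))
  expect_true(all(diff(cv$n) >= 0))

  # zero error below 80, -20 above: flat at 0 then strictly increasing
  age2 <- c(seq(5, 80, by = 5), 85, 90, 95, 100)
  err2 <- ifelse(age2 > 80, -20, 0)
  rec2 <- pred_records(age2, age2 + err2)
  cv2 <- metric_dynamics(rec2, "mad", step = 5)
  expect_true(all(cv2$value[cv2$t <= 80] == 0))
  after <- cv2$value[cv2$t > 80]
  expect_true(all(diff(after) > 0))
  expect_gt(after[1], 0)

  # final point equals the global metric exactly
  set.seed(45)
  coh <- simulate_cohort(cohort_config(n = 120, seed = 6))
  pr <- predict_age(matched_clock(attr(coh, "config")), coh)
  for (m in c("mad", "see")) {
    cv3 <- metric_dynamics(pr, m)
    fun <- if (m == "mad") mad_error else see_error
    expect_equal(cv3$value[nrow(cv3)], fun(pr$age, pr$predicted_age),
                 tolerance = 1e-12)
    expect_equal(cv3$t[nrow(cv3)], max(pr$age))
  }

  # early SEE points with n < 3 are flagged null
  rec3 <- pred_records(c(1, 10, 20, 30), c(2, 11, 21, 31))
  cv4 <- metric_dynamics(rec3, "see", step = 9)
  expect_true(is.na(cv4$value[1]))
  expect_false(is.na(cv4$value[nrow(cv4)]))
})

test_that("type-I error of the adult-vs-old comparison is controlled", {
  sites <- default_site_models()  # no attenuation, no sex effect
  reject <- logical(120)
  for (r in seq_along(reject)) {
    adult <- simulate_cohort(cohort_config(
      n = 50, seed = 60000 + r, sites = sites,
      age_sampler = uniform_age_sampler(18, 80)))
    old <- simulate_cohort(cohort_config(
      n = 50, seed = 70000 + r, sites = sites,
      age_sampler = uniform_age_sampler(81, 101)))
    ck <- matched_clock(attr(adult, "config"))
    pa <- predict_age(ck, adult)
    po <- predict_age(ck, old)
    reject[r] <- compare_delta_age(pa, po)$p_value < 0.05
  }
  expect_gte(mean(reject), 0.005)
  expect_lte(mean(reject), 0.12)
})
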