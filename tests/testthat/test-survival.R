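# Cohort filtering, KM median splits, proportional-hazards reports,
# interaction and delta subgroups.

make_cohort_df <- function(n = 300, seed = 1, ...) {
  ch <- generate_cohort(cohort_sim_params(n_cases = n, seed = seed, ...))
  d <- ch$cases
  d$si <- d$true_si
  d$si_core1 <- quantize_si(d$si_core1_true)
  d$si_core2 <- quantize_si(d$si_core2_true)
  d$delta <- delta_value(d$si_core1, d$si_core2)
  d$pdl1_stratum <- pdl1_stratum(d$pdl1)
  d
}

test_that("the cohort filter removes short survivors and nothing else", {
  d <- data.frame(time_months = c(0.5, 1, 2, 14), event = c(1, 0, 1, 1))
  expect_message(f <- filter_cohort(d), "excluded 1")
  expect_identical(nrow(f), 3L)
  expect_identical(attr(f, "n_removed"), 1L)
  expect_true(all(f$time_months >= 1))
  # conservation and the no-op case
  d2 <- data.frame(time_months = c(3, 5), event = c(1, 0))
  expect_message(f2 <- filter_cohort(d2), "excluded 0")
  expect_identical(f2$time_months, d2$time_months)
  expect_error(suppressMessages(filter_cohort(data.frame(time_months = 0.2, event = 1))),
               "no cases")
})

test_that("the KM estimator matches the hand-computed product-limit form", {
  # five cases, one group: deaths at 2 and 5, censoring at 3, deaths at 7, 9
  d <- data.frame(time_months = c(2, 3, 5, 7, 9), event = c(1, 0, 1, 1, 1),
                  si = c(0.1, 0.1, 0.2, 0.6, 0.7))
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1, data = d)
  s <- summary(fit, times = c(2, 5, 7, 9))$surv
  expect_equal(s, c(4/5, 4/5 * 2/3, 4/5 * 2/3 * 1/2, 0))
})

test_that("the median SI split follows the tie rule and reports group sizes", {
  set.seed(5)
  d <- make_cohort_df(400, seed = 7, log_hr_si = -5)
  km <- km_by_median_si(d)
  med <- stats::median(d$si)
  expect_identical(unname(km$group_sizes["high"]), sum(d$si > med))
  expect_identical(unname(km$group_sizes["low"]), sum(d$si <= med))
  expect_identical(sum(km$group_sizes), nrow(d))
  # strongly protective SI: the high-SI curve dominates
  cv <- km_curves(km)
  lo <- cv[cv$group == "low", ]; hi <- cv[cv$group == "high", ]
  grid_t <- seq(5, 60, by = 5)
  s_at <- function(curve, t) {
    i <- findInterval(t, curve$time)
    ifelse(i == 0, 1, curve$survival[pmax(i, 1)])
  }
  expect_true(all(s_at(hi, grid_t) >= s_at(lo, grid_t)))
  expect_lt(km$logrank_p, 0.01)
  expect_error(km_by_median_si(data.frame(time_months = 1:6, event = 1,
                                          si = rep(0.2, 6))), "equal")
})

test_that("log-rank p is roughly uniform when SI is permuted against survival", {
  set.seed(11)
  d <- make_cohort_df(300, seed = 13, log_hr_si = 0)
  ps <- replicate(40, {
    d$si <- sample(d$si)
    km_by_median_si(d)$logrank_p
  })
  expect_gt(mean(ps < 0.5), 0.25)
  expect_lt(mean(ps < 0.05), 0.25)
})

test_that("univariate reports carry HR, CI and p with the right structure", {
  d <- make_cohort_df(400, seed = 17)
  rep <- cph_univariate(d, "si")
  expect_s3_class(rep, "si_model_report")
  expect_true(rep$ci_lower <= rep$hr & rep$hr <= rep$ci_upper)
  expect_gt(rep$hr, 0)
  expect_lt(rep$hr, 1)  # simulated protective effect
  expect_error(cph_univariate(transform(d, si = 0.3), "si"), "constant")
  # null covariate: CI covers 1 most of the time
  set.seed(23)
  cover <- replicate(30, {
    d$noise <- rnorm(nrow(d))
    r <- cph_univariate(d, "noise")
    r$ci_lower <= 1 && r$ci_upper >= 1
  })
  expect_gte(mean(cover), 0.85)
})

test_that("the multivariate model recovers joint effects with correct signs", {
  d <- make_cohort_df(500, seed = 29)
  rep <- cph_multivariate(d)
  expect_identical(attr(rep, "n_complete"), nrow(d))
  expect_false(is.unsorted(rep$p))           # ordered by p-value
  expect_lt(rep$hr[rep$variable == "si"], 1)      # protective
  expect_gt(rep$hr[rep$variable == "stage"], 1)   # adverse
  expect_true(all(rep$ci_lower <= rep$hr & rep$hr <= rep$ci_upper))
  # a pure-noise covariate barely moves the SI estimate
  set.seed(31)
  d$noise <- rnorm(nrow(d))
  rep2 <- cph_multivariate(d, c("stage", "age", "vascular_invasion", "si",
                                "pleural_invasion", "grade", "noise"))
  expect_lt(abs(log(rep2$hr[rep2$variable == "si"]) -
                  log(rep$hr[rep$variable == "si"])), 0.25)
  # complete-case accounting
  d$age[1:20] <- NA
  rep3 <- cph_multivariate(d[, setdiff(names(d), "noise")])
  expect_identical(attr(rep3, "n_complete"), nrow(d) - 20L)
})

test_that("the interaction model has the exact product-term structure", {
  d <- make_cohort_df(500, seed = 37, log_hr_si = -3, log_hr_interaction = 3)
  res <- interaction_model(d)
  expect_s3_class(res, "si_interaction")
  expect_setequal(res$model$variable, c("si", "pdl1_high", "si:pdl1_high"))
  expect_true(res$interaction_p >= 0 && res$interaction_p <= 1)
  # the design matrix product term is exactly si * indicator
  dd <- d[!is.na(d$si) & !is.na(d$pdl1_stratum), ]
  mm <- stats::model.matrix(~ si * I(pdl1_stratum == "high"), dd)
  expect_equal(unname(mm[, 4]), dd$si * (dd$pdl1_stratum == "high"))
  # canceled effect: SI prognostic in the low stratum, attenuated in high
  expect_lt(res$stratum_km$low$logrank_p, 0.05)
  expect_gt(res$stratum_km$high$logrank_p, res$stratum_km$low$logrank_p)
})

test_that("the null interaction p-value is roughly uniform", {
  set.seed(41)
  ps <- vapply(1:25, function(r) {
    d <- make_cohort_df(250, seed = 400 + r, log_hr_interaction = 0)
    interaction_model(d)$interaction_p
  }, numeric(1))
  expect_gt(mean(ps > 0.1), 0.6)
  expect_lt(mean(ps < 0.05), 0.3)
})

test_that("delta subgroups partition the cohort and expose heterogeneity", {
  d <- make_cohort_df(500, seed = 43, log_hr_si = -3)
  sub <- subgroup_analysis(d)
  expect_identical(sub$subgroup, c("low", "high"))
  expect_identical(sum(sub$n), sum(!is.na(d$delta)))
  # homogeneous SI effect: subgroup CIs overlap
  expect_true(max(sub$ci_lower) <= min(sub$ci_upper))
  # by construction the delta-low subgroup has the higher paired-core rho
  expect_gt(sub$paired_core_rho[1], sub$paired_core_rho[2])
  # near-zero heterogeneity: delta-low paired-core rho close to 1
  d2 <- make_cohort_df(300, seed = 47, core_heterogeneity_sd = 0.02)
  sub2 <- subgroup_analysis(d2)
  expect_gt(sub2$paired_core_rho[1], 0.8)
})
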