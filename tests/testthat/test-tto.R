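# Time-to-onset intervals, reliability accounting, the Weibull fit and
# its hazard classification, and the cumulative-incidence curve.

onset_cohort <- function(start_dt, event_dt) {
  n <- length(start_dt)
  ids <- as.character(seq_len(n))
  store <- make_store(
    demo = data.frame(primaryid = ids, caseid = ids, fda_dt = "20240601",
                      event_dt = event_dt),
    drug = data.frame(primaryid = ids, drug_seq = "1", role_cod = "PS",
                      drugname = "REGADENOSON", prod_ai = "REGADENOSON"),
    reac = data.frame(primaryid = ids, pt = "E1"),
    ther = data.frame(primaryid = ids, dsg_drug_seq = "1",
                      start_dt = start_dt, end_dt = start_dt))
  select_primary_suspect(store)
}

test_that("onset intervals and unreliability reasons are assigned correctly", {
  cohort <- onset_cohort(
    start_dt = c("20240105", "20240110", "202401", NA, "20240101"),
    event_dt = c("20240105", "20240105", "20240110", "20240110", "202402"))
  ons <- compute_onset(cohort)
  rec <- ons$records[order(as.integer(ons$records$primaryid)), ]
  expect_equal(rec$onset_days[1], 0L)                      # same day
  expect_equal(rec$reason[2], "negative interval")
  expect_equal(rec$reason[3], "partial date")              # partial start
  expect_equal(rec$reason[4], "missing date")
  expect_equal(rec$reason[5], "partial date")              # partial event
  # no silent drops: reliable + unreliable = linked records
  expect_equal(sum(rec$reliable) + sum(!rec$reliable), nrow(rec))
  expect_equal(ons$n_reliable, 1L)
})

test_that("the earliest linked therapy start date is used", {
  cohort <- onset_cohort("20240110", "20240115")
  cohort$ther <- rbind(cohort$ther,
                       data.frame(primaryid = "1", dsg_drug_seq = "1",
                                  start_dt = "20240105", end_dt = "20240105"))
  ons <- compute_onset(cohort)
  expect_equal(ons$records$onset_days, 10L)
  # therapy rows not linked to the target drug sequence are ignored
  cohort$ther <- rbind(cohort$ther,
                       data.frame(primaryid = "1", dsg_drug_seq = "2",
                                  start_dt = "20240101", end_dt = "20240101"))
  expect_equal(compute_onset(cohort)$records$onset_days, 10L)
})

test_that("a day-0-dominated sample reports zero median and IQR", {
  days <- c(rep(0L, 1943), rep(60L, 3), 180L, rep(365L, 12))
  start <- rep("20230101", length(days))
  event <- format(as.Date("2023-01-01") + days, "%Y%m%d")
  ons <- compute_onset(onset_cohort(start, event))
  expect_equal(ons$n_reliable, 1959L)
  expect_equal(ons$median, 0)
  expect_equal(ons$iqr, c(0, 0))
  tl <- ons$timeline
  expect_equal(tl$count[tl$bin == "0 days"], 1943L)
  expect_equal(tl$pct[tl$bin == "0 days"], 99.18)
  expect_equal(tl$count[tl$bin == "1-2 months"], 3L)
  expect_equal(tl$count[tl$bin == "2-6 months"], 1L)
  expect_equal(tl$count[tl$bin == "6-12 months"], 12L)
})

test_that("summary quantiles agree with a naive sort-based oracle", {
  set.seed(12)
  days <- sample(0:400, 151, replace = TRUE)
  ons <- compute_onset(onset_cohort(
    rep("20230101", length(days)),
    format(as.Date("2023-01-01") + days, "%Y%m%d")))
  sorted <- sort(days)
  naive_median <- if (length(sorted) %% 2 == 1) {
    sorted[(length(sorted) + 1) / 2]
  } else mean(sorted[length(sorted) / 2 + 0:1])
  expect_equal(ons$median, naive_median)
  expect_equal(ons$iqr, unname(stats::quantile(days, c(.25, .75))))
})

test_that("Weibull fit recovers simulated shape and classifies the hazard", {
  set.seed(42)
  draws <- stats::rweibull(2000, shape = 0.6, scale = 5)
  fit <- weibull_fit(draws, offset = 0)
  expect_gt(fit$shape, 0.55)
  expect_lt(fit$shape, 0.65)
  expect_equal(fit$classification, "early-failure")
  expect_lt(fit$shape_ci[2], 1)
  # independent route: fitdistrplus MLE on the same data
  ref <- fitdistrplus::fitdist(draws, "weibull")
  expect_equal(fit$shape, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(fit$scale, unname(ref$estimate["scale"]), tolerance = 1e-3)
  # likelihood dominance over the generating parameters
  true_ll <- sum(stats::dweibull(draws, 0.6, 5, log = TRUE))
  expect_gte(fit$loglik, true_ll - 2)

  # exponential data: the shape interval covers 1, hazard is "random"
  set.seed(43)
  expo <- stats::rexp(2000, rate = 1 / 5)
  fit_e <- weibull_fit(expo, offset = 0)
  expect_true(fit_e$shape_ci[1] < 1 && fit_e$shape_ci[2] > 1)
  expect_equal(fit_e$classification, "random")

  # increasing hazard is classified wear-out
  set.seed(44)
  fit_w <- weibull_fit(stats::rweibull(2000, shape = 2.5, scale = 10),
                       offset = 0)
  expect_equal(fit_w$classification, "wear-out")
})

test_that("degenerate onset data yields an indeterminate fit with a reason", {
  expect_equal(weibull_fit(rep(3, 50))$classification, "indeterminate")
  expect_match(weibull_fit(rep(3, 50))$reason, "identical")
  expect_equal(weibull_fit(c(1, 2, 3))$classification, "indeterminate")
  expect_match(weibull_fit(c(1, 2, 3))$reason, "fewer than 10")
})

test_that("cumulative incidence is a proper empirical CDF", {
  curve <- cumulative_incidence(c(0, 0, 10))
  expect_equal(curve$day, c(0, 10))
  expect_equal(curve$cum_fraction, c(2/3, 1))
  all0 <- cumulative_incidence(rep(0, 5))
  expect_equal(all0$cum_fraction, 1)
  # monotone, ends at exactly 1
  set.seed(8)
  x <- sample(0:50, 300, replace = TRUE)
  cc <- cumulative_incidence(x)
  expect_true(all(diff(cc$cum_fraction) >= 0))
  expect_identical(cc$cum_fraction[nrow(cc)], 1)
  # sup-distance to the generating CDF inside the 99% Kolmogorov band
  set.seed(9)
  n <- 2000
  t <- stats::rweibull(n, shape = 0.6, scale = 30)
  cdf <- cumulative_incidence(t)
  sup <- max(abs(cdf$cum_fraction - stats::pweibull(cdf$day, 0.6, 30)))
  expect_lt(sup, 1.63 / sqrt(n))
  expect_error(cumulative_incidence(numeric(0)), "no reliable")
})
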