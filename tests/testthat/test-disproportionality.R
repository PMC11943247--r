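# Contingency construction and the four signal statistics, each checked
# against an independent oracle: hand-evaluated closed forms and
# stats::chisq.test for ROR/PRR/chi-squared, Monte-Carlo posterior
# sampling for the information component and the shrinker, and simulation
# with known truth for the prior fit.

toy_store <- function() {
  make_store(
    demo = data.frame(primaryid = c("r1", "r2", "r3", "r4"),
                      caseid = c("1", "2", "3", "4"),
                      fda_dt = rep("20240101", 4)),
    drug = data.frame(primaryid = c("r1", "r2", "r3", "r4"), drug_seq = "1",
                      role_cod = "PS",
                      drugname = c("REGADENOSON", "REGADENOSON", "OTHER", "OTHER"),
                      prod_ai = c("REGADENOSON", "REGADENOSON", "OTHER", "OTHER")),
    reac = data.frame(primaryid = c("r1", "r2", "r2", "r3", "r4"),
                      pt = c("E1", "E1", "E2", "E1", "E2")))
}

test_that("contingency tables count distinct (report, term) pairs", {
  store <- toy_store()
  cohort <- select_primary_suspect(store)
  tabs <- build_tables(cohort, store, level = "PT")
  e1 <- tabs[tabs$term == "E1", ]
  expect_equal(c(e1$a, e1$b, e1$c, e1$d), c(2, 1, 1, 1))
  e2 <- tabs[tabs$term == "E2", ]
  expect_equal(c(e2$a, e2$b, e2$c, e2$d), c(1, 2, 1, 1))
  # conservation: a-cells sum to the cohort's distinct pair count
  expect_equal(sum(tabs$a), 3)
  expect_equal(unique(tabs$a + tabs$b), 3)  # margins consistent across terms
  # repeated PT mentions within a report count once
  store$reac <- rbind(store$reac,
                      data.frame(primaryid = "r2", pt = "E1"))
  tabs2 <- build_tables(select_primary_suspect(store), store, level = "PT")
  expect_equal(tabs2[tabs2$term == "E1", c("a", "b", "c", "d")],
               e1[, c("a", "b", "c", "d")], ignore_attr = TRUE)
  # term absent from the cohort is not emitted
  store$reac <- rbind(store$reac, data.frame(primaryid = "r3", pt = "E9"))
  expect_false("E9" %in% build_tables(select_primary_suspect(store), store,
                                      level = "PT")$term)
})

test_that("ROR, PRR and Yates chi-squared match hand-evaluated oracles", {
  # enumerated small tables; oracle recomputed in place from first principles
  grid <- expand.grid(a = c(1, 3, 10), b = c(5, 90), c = c(4, 100),
                      d = c(50, 9900))
  for (i in seq_len(nrow(grid))) {
    a <- grid$a[i]; b <- grid$b[i]; c <- grid$c[i]; d <- grid$d[i]
    n <- a + b + c + d
    r <- ror_stat(a, b, c, d)
    expect_equal(r$ror, a * d / (b * c))
    expect_equal(r$ror_lo95,
                 exp(log(a * d / (b * c)) - 1.96 * sqrt(1/a + 1/b + 1/c + 1/d)))
    p <- prr_chi2(a, b, c, d)
    expect_equal(p$prr, (a / (a + b)) / (c / (c + d)))
    expect_equal(p$prr_hi95,
                 exp(log(p$prr) + 1.96 * sqrt(1/a - 1/(a + b) + 1/c - 1/(c + d))))
    # independent chi-squared route
    expect_equal(p$chi2,
                 unname(suppressWarnings(stats::chisq.test(
                   matrix(c(a, b, c, d), 2, byrow = TRUE),
                   correct = TRUE))$statistic))
  }
  # canonical worked example
  expect_equal(ror_stat(10, 90, 100, 9900)$ror, 11)
  expect_equal(prr_chi2(10, 90, 100, 9900)$prr, 10)
  expect_equal(prr_chi2(10, 90, 100, 9900)$chi2, 66.327, tolerance = 1e-4)
})

test_that("ROR/PRR symmetries and degenerate cells behave as required", {
  r <- ror_stat(10, 10, 10, 10)
  expect_equal(r$ror, 1)
  expect_true(r$ror_lo95 < 1 && r$ror_hi95 > 1)
  # doubling all cells preserves the estimate and narrows the interval
  r1 <- ror_stat(10, 90, 100, 9900); r2 <- ror_stat(20, 180, 200, 19800)
  expect_equal(r1$ror, r2$ror)
  expect_lt(r2$ror_hi95 - r2$ror_lo95, r1$ror_hi95 - r1$ror_lo95)
  # equal row proportions give the exact null
  expect_equal(prr_chi2(10, 90, 20, 180)$prr, 1)
  # swapping the rows inverts the PRR
  expect_equal(prr_chi2(20, 180, 10, 90)$prr, 1 / prr_chi2(10, 90, 20, 180)$prr)
  # Yates floor: tiny deviation from independence floors chi2 at 0
  expect_equal(prr_chi2(5, 5, 5, 5)$chi2, 0)
  # zero cells: undefined with reason unless the Haldane correction is on
  z <- ror_stat(3, 0, 5, 10)
  expect_false(z$defined)
  expect_match(z$reason, "zero")
  zh <- ror_stat(3, 0, 5, 10, haldane = TRUE)
  expect_true(zh$defined && is.finite(zh$ror))
  # sign agreement for all-positive tables
  set.seed(4)
  for (k in 1:20) {
    cells <- sample(1:50, 4, replace = TRUE)
    rr <- ror_stat(cells[1], cells[2], cells[3], cells[4])$ror
    pp <- prr_chi2(cells[1], cells[2], cells[3], cells[4])$prr
    s <- sign(cells[1] * cells[4] - cells[2] * cells[3])
    expect_equal(sign(rr - 1), s)
    expect_equal(sign(pp - 1), s)
  }
})

test_that("information component matches its Monte-Carlo posterior oracle", {
  # oracle: sample the model's posterior (independent Betas for the joint
  # cell and the two margins, with the closed form's prior weights) and
  # average the log2 ratio
  mc_ic <- function(a, b, c, d, ndraw = 1e5) {
    n <- a + b + c + d; n11 <- a; n1 <- a + b; m1 <- a + c
    g <- (n + 2)^2 / ((n1 + 1) * (m1 + 1))
    p11 <- stats::rbeta(ndraw, n11 + 1, n - n11 + g - 1)
    p1 <- stats::rbeta(ndraw, n1 + 1, n - n1 + 1)
    q1 <- stats::rbeta(ndraw, m1 + 1, n - m1 + 1)
    x <- log2(p11 / (p1 * q1))
    c(mean = mean(x), sd = stats::sd(x))
  }
  set.seed(31)
  tables <- list(c(10, 90, 100, 9900), c(50, 950, 400, 18600),
                 c(25, 475, 60, 4440))
  for (tb in tables) {
    ic <- bcpnn_ic(tb[1], tb[2], tb[3], tb[4])
    mc <- mc_ic(tb[1], tb[2], tb[3], tb[4])
    expect_lt(abs(ic$ic - mc["mean"]), 0.15)
    # lower bound consistent with the sampled spread (2-sd convention)
    expect_lt(abs((ic$ic - ic$ic025) - 2 * mc["sd"]), 0.25)
  }
})

test_that("information component limits: independence and empty joint cell", {
  # exact independence at large N
  ic0 <- bcpnn_ic(10, 990, 9990, 989010)  # a = (a+b)(a+c)/N
  expect_lt(abs(ic0$ic), 0.01)
  # a = 0 stays finite and negative through the prior
  ic_empty <- bcpnn_ic(0, 5, 3, 12)
  expect_true(is.finite(ic_empty$ic) && ic_empty$ic < 0)
  expect_true(is.finite(ic_empty$ic025))
  expect_lt(ic_empty$ic025, ic_empty$ic)
})

test_that("shrinker prior fit recovers pure-Poisson data and dominates truth", {
  set.seed(71)
  n_cells <- 5000
  E <- exp(stats::runif(n_cells, log(2), log(50)))
  # lambda = 1 everywhere: fitted mixture mean must come back ~1
  n1 <- stats::rpois(n_cells, E)
  fit1 <- fit_gps_prior(n1, E)
  mean1 <- fit1$pi * fit1$alpha1 / fit1$beta1 +
    (1 - fit1$pi) * fit1$alpha2 / fit1$beta2
  expect_equal(mean1, 1, tolerance = 0.1)

  # data drawn from the default prior itself: fitted marginal loglik must
  # match or beat the likelihood at the generating parameters
  true_par <- list(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4, pi = 1/3)
  comp <- stats::runif(n_cells) < true_par$pi
  lam <- ifelse(comp,
                stats::rgamma(n_cells, true_par$alpha1, true_par$beta1),
                stats::rgamma(n_cells, true_par$alpha2, true_par$beta2))
  n2 <- stats::rpois(n_cells, lam * E)
  fit2 <- fit_gps_prior(n2, E)
  loglik_at <- function(p) {
    sum(log(p$pi * stats::dnbinom(n2, size = p$alpha1,
                                  prob = p$beta1 / (p$beta1 + E)) +
              (1 - p$pi) * stats::dnbinom(n2, size = p$alpha2,
                                          prob = p$beta2 / (p$beta2 + E))))
  }
  expect_gte(fit2$loglik, loglik_at(true_par) - 1.0)

  # single-component data: the far component's weight collapses
  lam3 <- stats::rgamma(n_cells, shape = 0.2, rate = 0.1)
  n3 <- stats::rpois(n_cells, lam3 * E)
  fit3 <- fit_gps_prior(n3, E)
  # weight concentrates on one component (mean near the truth of 2)
  expect_gt(max(fit3$pi, 1 - fit3$pi), 0.9)
  mean3 <- fit3$pi * fit3$alpha1 / fit3$beta1 +
    (1 - fit3$pi) * fit3$alpha2 / fit3$beta2
  expect_equal(mean3, 2, tolerance = 0.25)

  expect_error(fit_gps_prior(c(1), c(2)), "at least 2")
})

test_that("shrinker posterior matches Monte-Carlo sampling and shrinks", {
  prior <- structure(list(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4,
                          pi = 1/3, loglik = NA, truncated = FALSE,
                          n_cells = NA),
                     class = "gps_prior")
  # Monte-Carlo oracle for one cell: sample the posterior mixture directly
  set.seed(17)
  mc_post <- function(a, E, ndraw = 1e6) {
    f1 <- prior$pi * stats::dnbinom(a, size = prior$alpha1,
                                    prob = prior$beta1 / (prior$beta1 + E))
    f2 <- (1 - prior$pi) * stats::dnbinom(a, size = prior$alpha2,
                                          prob = prior$beta2 / (prior$beta2 + E))
    q <- f1 / (f1 + f2)
    comp <- stats::runif(ndraw) < q
    lam <- ifelse(comp,
                  stats::rgamma(ndraw, prior$alpha1 + a, prior$beta1 + E),
                  stats::rgamma(ndraw, prior$alpha2 + a, prior$beta2 + E))
    c(geo = exp(mean(log(lam))), q05 = unname(stats::quantile(lam, 0.05)))
  }
  for (cell in list(c(a = 1, E = 1), c(a = 8, E = 2), c(a = 3, E = 10))) {
    sc <- ebgm_scores(cell["a"], cell["E"], prior)
    mc <- mc_post(cell["a"], cell["E"])
    expect_equal(sc$ebgm, unname(mc["geo"]), tolerance = 0.01)
    expect_equal(sc$ebgm05, unname(mc["q05"]), tolerance = 0.02)
  }
  # a = 1, E = 1: ordering bounds from the posterior-mixture structure
  prior_mean <- 1/3 * 2 + 2/3 * 0.5
  sc <- ebgm_scores(1, 1, prior)
  expect_true(0 < sc$ebgm05 && sc$ebgm05 < sc$ebgm)
  expect_lt(sc$ebgm, 1 / 1 + prior_mean)

  # shrinkage toward the prior mean vanishes asymptotically: a/E = 5
  sc_big <- ebgm_scores(1000, 200, prior)
  expect_equal(sc_big$ebgm, 5, tolerance = 0.02)
  # shrinkage on simulated elevated cells: the posterior geometric mean
  # sits between the prior mean and the observed ratio (EBGM is a
  # geometric-scale mean, so only the elevated side admits a sharp bound)
  set.seed(23)
  for (k in 1:25) {
    a <- sample(3:40, 1); E <- stats::runif(1, 0.5, 10)
    sc <- ebgm_scores(a, E, prior)
    if (a / E >= 2 * prior_mean) {
      expect_gte(sc$ebgm, prior_mean)
      expect_lte(sc$ebgm, a / E)
    }
    expect_lt(sc$ebgm05, sc$ebgm)
  }
  # zero expectation is undefined with a reason
  z <- ebgm_scores(2, 0, prior)
  expect_false(z$defined)
})

test_that("positivity flags implement the four published thresholds", {
  th <- signal_thresholds()
  mk <- function(a, b, c, d, prior = NULL) {
    tabs <- data.frame(term = "X", level = "PT", a = a, b = b, c = c, d = d,
                       n_total = a + b + c + d,
                       expected = (a + b) * (a + c) / (a + b + c + d),
                       stringsAsFactors = FALSE)
    signal_stats(tabs, prior = prior, thresholds = th)
  }
  # minimum-count rule: huge ROR with a = 2 does not flag
  s <- mk(2, 1, 1, 1000)
  expect_false(s$flag_ror)
  # the canonical table flags on the MHRA combined criterion
  s <- mk(10, 90, 100, 9900)
  expect_true(s$flag_prr)
  expect_true(s$positive)
  # exact null flags nothing
  s <- mk(10, 90, 100, 900)  # prr = ror = 1
  expect_equal(s$prr, 1)
  expect_false(s$positive)
  # positive is the OR over the four per-method flags
  fx <- fixture_null()
  cohort <- select_primary_suspect(fx$store)
  tabs <- build_tables(cohort, fx$store, level = "PT")
  prior <- fit_gps_prior(tabs$a, tabs$expected)
  st <- signal_stats(tabs, prior = prior)
  expect_equal(st$positive,
               st$flag_ror | st$flag_prr | st$flag_bcpnn | st$flag_mgps)
  expect_true(all(st$ebgm05 < st$ebgm))
  # interval ordering invariants
  expect_true(all(st$ror_lo95 <= st$ror & st$ror <= st$ror_hi95, na.rm = TRUE))
  expect_true(all(st$ic025 <= st$ic))
})

test_that("ranked reports sort stably by the chosen key", {
  store <- toy_store()
  cohort <- select_primary_suspect(store)
  tabs <- build_tables(cohort, store, level = "PT")
  st <- signal_stats(tabs)
  top1 <- rank_report(st, by = "frequency", top_n = 1)
  expect_equal(top1$term, "E1")
  expect_equal(rank_report(st, by = "frequency", top_n = 10)$term, c("E1", "E2"))
  expect_equal(nrow(rank_report(st, top_n = 1)), 1L)
  # lexicographic tie-break
  st2 <- st
  st2$a <- c(5L, 5L)
  expect_equal(rank_report(st2, by = "frequency")$term, c("E1", "E2"))
})
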