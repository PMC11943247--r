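# Disproportionality analysis: 2x2 contingency tables for one drug against
# the rest of the database, and four signal-detection statistics with their
# interval bounds (ROR, PRR with the MHRA combined criterion, the BCPNN
# information component, and the multi-item gamma Poisson shrinker).
#
# Counting unit throughout: distinct (report, term) pairs. A report
# mentioning the same PT twice contributes one pair; the table margins are
# pair totals, so the a-cells over all terms sum to the cohort's pair
# count.

#' Build drug-event contingency tables
#'
#' For each term mentioned by the cohort, counts a = cohort pairs with the
#' term, b = other cohort pairs, c = non-cohort pairs with the term, d =
#' remaining pairs; N = all distinct (report, term) pairs in the database.
#' At SOC level, terms are the primary SOCs of the (recoded) PTs.
#'
#' @param cohort A `faers_cohort` (the target drug's reports).
#' @param store The full `faers_case_store` the cohort was selected from.
#' @param level `"PT"` or `"SOC"`.
#' @param map A [meddra_map()]; required for `level = "SOC"`, and applied
#'   at PT level (when given) to recode obsolete names before counting.
#' @return Data frame with one row per term (`a >= 1`): `term`, `level`,
#'   `a`, `b`, `c`, `d`, `n_total`, and the independence expectation
#'   `expected = (a+b)(a+c)/N`.
#' @export
build_tables <- function(cohort, store, level = c("PT", "SOC"), map = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(cohort, "faers_cohort"), inherits(store, "faers_case_store"))
  if (length(cohort$ids) == 0) {
    warning("empty cohort: no contingency tables", call. = FALSE)
    return(data.frame(term = character(0), level = character(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), n_total = integer(0),
                      expected = numeric(0), stringsAsFactors = FALSE))
  }
  reac <- store$reac
  term <- reac$pt
  if (!is.null(map)) term <- recode_pt(term, map)
  if (level == "SOC") {
    if (is.null(map)) stop("SOC-level tables require a dictionary map", call. = FALSE)
    term <- soc_of(reac$pt, map)
  }
  pairs <- unique(data.frame(primaryid = reac$primaryid, term = as.character(term),
                             stringsAsFactors = FALSE))
  pairs <- pairs[!is.na(pairs$term), , drop = FALSE]
  n_total <- nrow(pairs)
  in_cohort <- pairs$primaryid %in% cohort$ids
  drug_margin <- sum(in_cohort)

  a_tab <- table(pairs$term[in_cohort])
  all_tab <- table(pairs$term)
  terms <- names(a_tab)
  a <- as.integer(a_tab)
  event_margin <- as.integer(all_tab[terms])
  b <- drug_margin - a
  c_ <- event_margin - a
  d <- n_total - drug_margin - c_
  out <- data.frame(term = terms, level = level, a = a, b = b, c = c_, d = d,
                    n_total = n_total,
                    expected = drug_margin * event_margin / n_total,
                    stringsAsFactors = FALSE)
  out[order(-out$a, out$term), , drop = FALSE]
}

undefined_stat <- function(reason) {
  list(defined = FALSE, reason = reason)
}

#' Reporting odds ratio with Wald 95% interval
#'
#' `ROR = ad / bc`; the interval is `exp(log ROR -+ 1.96 *
#' sqrt(1/a + 1/b + 1/c + 1/d))`. With any zero cell the statistic is
#' undefined by default; `haldane = TRUE` adds 0.5 to every cell instead.
#'
#' @param a,b,c,d Cell counts (vectorised).
#' @param haldane Apply the Haldane-Anscombe 0.5 correction to zero-cell
#'   tables.
#' @return Data frame with `ror`, `ror_lo95`, `ror_hi95`, `defined`,
#'   `reason`.
#' @export
ror_stat <- function(a, b, c, d, haldane = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  if (haldane) {
    a <- a + 0.5 * zero; b <- b + 0.5 * zero
    c <- c + 0.5 * zero; d <- d + 0.5 * zero
    zero <- rep(FALSE, length(a))
  }
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  lo <- exp(log(est) - 1.96 * se)
  hi <- exp(log(est) + 1.96 * se)
  est[zero] <- lo[zero] <- hi[zero] <- NA_real_
  data.frame(ror = est, ror_lo95 = lo, ror_hi95 = hi,
             defined = !zero,
             reason = ifelse(zero, "zero cell", NA_character_),
             stringsAsFactors = FALSE)
}

#' Proportional reporting ratio, 95% interval, and Yates chi-squared
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; interval `exp(log PRR -+ 1.96 *
#' sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`. The chi-squared statistic uses
#' the Yates continuity correction `N(|ad - bc| - N/2)^2 /
#' [(a+b)(c+d)(a+c)(b+d)]`, floored at 0 when `|ad - bc| <= N/2`;
#' `yates = FALSE` disables the correction.
#'
#' @param a,b,c,d Cell counts (vectorised).
#' @param yates Use the continuity correction (default `TRUE`).
#' @return Data frame with `prr`, `prr_lo95`, `prr_hi95`, `chi2`,
#'   `defined`, `reason`.
#' @export
prr_chi2 <- function(a, b, c, d, yates = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  bad <- (a + b) == 0 | (c + d) == 0 | c == 0 | a == 0
  est <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  lo <- exp(log(est) - 1.96 * se)
  hi <- exp(log(est) + 1.96 * se)
  dev <- abs(a * d - b * c)
  if (yates) dev <- pmax(dev - n / 2, 0)
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(denom > 0, n * dev^2 / denom, NA_real_)
  est[bad] <- lo[bad] <- hi[bad] <- NA_real_
  data.frame(prr = est, prr_lo95 = lo, prr_hi95 = hi, chi2 = chi2,
             defined = !bad,
             reason = ifelse(bad, "zero margin or zero cell", NA_character_),
             stringsAsFactors = FALSE)
}

#' BCPNN information component with its lower bound
#'
#' Closed-form posterior moments of the information component
#' `IC = log2 P(drug, event) / [P(drug) P(event)]` under the standard
#' Beta-prior model (joint-cell prior weight 1, margin priors Beta(1, 1));
#' `IC025 = IC - 2 sd`. Defined for every non-negative table, including
#' `a = 0`.
#'
#' @param a,b,c,d Cell counts (vectorised).
#' @return Data frame with `ic` and `ic025`.
#' @export
bcpnn_ic <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n11 <- a
  n1. <- a + b
  n.1 <- a + c
  alpha1 <- 1; beta1 <- 1; alpha <- 2; beta <- 2; gamma11 <- 1
  gamma <- gamma11 * (n + alpha) * (n + beta) / ((n1. + alpha1) * (n.1 + beta1))
  ic <- log2((n11 + gamma11) * (n + alpha) * (n + beta) /
               ((n + gamma) * (n1. + alpha1) * (n.1 + beta1)))
  v <- (1 / log(2)^2) * (
    (n - n11 + gamma - gamma11) / ((n11 + gamma11) * (1 + n + gamma)) +
      (n - n1. + alpha - alpha1) / ((n1. + alpha1) * (1 + n + alpha)) +
      (n - n.1 + beta - beta1) / ((n.1 + beta1) * (1 + n + beta)))
  data.frame(ic = ic, ic025 = ic - 2 * sqrt(v))
}

# ---- multi-item gamma Poisson shrinker -------------------------------------

# marginal log-density of one cell count under the 2-component
# gamma-Poisson (negative-binomial) mixture, via log-sum-exp
gps_marginal_loglik <- function(n, E, alpha1, beta1, alpha2, beta2, pi) {
  l1 <- log(pi) + stats::dnbinom(n, size = alpha1,
                                 prob = beta1 / (beta1 + E), log = TRUE)
  l2 <- log1p(-pi) + stats::dnbinom(n, size = alpha2,
                                    prob = beta2 / (beta2 + E), log = TRUE)
  m <- pmax(l1, l2)
  m + log(exp(l1 - m) + exp(l2 - m))
}

#' Fit the empirical-Bayes gamma-mixture prior of the gamma Poisson shrinker
#'
#' Maximises the marginal likelihood of the observed cell counts `n` given
#' their independence expectations `E` under the two-component gamma prior
#' on the relative report rate: each count is negative-binomial with size
#' `alpha` and probability `beta / (beta + E)` (mean `alpha E / beta`).
#' Optimisation is quasi-Newton on log-transformed shape/rate parameters
#' and logit-transformed mixture weight.
#'
#' @param n Integer vector of observed cell counts (cells with `n >= 1`).
#' @param E Positive expectations, same length as `n`.
#' @param init Starting values `(alpha1, beta1, alpha2, beta2, pi)`;
#'   default `c(0.2, 0.1, 2, 4, 1/3)`.
#' @param truncated Use the zero-truncated likelihood (conditioning each
#'   cell on `n >= 1`); default `FALSE`.
#' @return Object of class `gps_prior`: the five fitted parameters and the
#'   fitted marginal log-likelihood.
#' @export
fit_gps_prior <- function(n, E, init = c(0.2, 0.1, 2.0, 4.0, 1 / 3),
                          truncated = FALSE) {
  stopifnot(length(n) == length(E), all(E > 0), all(n >= 0))
  if (length(unique(paste(n, signif(E, 10)))) < 2) {
    stop("need at least 2 distinct (n, E) cells to fit the prior", call. = FALSE)
  }
  negll <- function(theta) {
    a1 <- exp(theta[1]); b1 <- exp(theta[2])
    a2 <- exp(theta[3]); b2 <- exp(theta[4])
    p <- stats::plogis(theta[5])
    val <- suppressWarnings({
      ll <- gps_marginal_loglik(n, E, a1, b1, a2, b2, p)
      if (truncated) {
        l0 <- gps_marginal_loglik(0L, E, a1, b1, a2, b2, p)
        ll <- ll - log1p(-exp(l0))
      }
      -sum(ll)
    })
    if (!is.finite(val)) val <- .Machine$double.xmax / 1e6
    val
  }
  theta0 <- c(log(init[1]), log(init[2]), log(init[3]), log(init[4]),
              stats::qlogis(init[5]))
  fit <- stats::optim(theta0, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  if (fit$convergence != 0) {
    # one Nelder-Mead polish before giving up
    fit2 <- stats::optim(fit$par, negll, method = "Nelder-Mead",
                         control = list(maxit = 2000))
    if (fit2$value <= fit$value) fit <- fit2
    if (fit$convergence != 0) {
      stop("gamma Poisson shrinker prior fit did not converge (optim status ",
           fit$convergence, ")", call. = FALSE)
    }
  }
  th <- fit$par
  prior <- list(alpha1 = exp(th[1]), beta1 = exp(th[2]),
                alpha2 = exp(th[3]), beta2 = exp(th[4]),
                pi = stats::plogis(th[5]),
                loglik = -fit$value, truncated = truncated,
                n_cells = length(n))
  class(prior) <- "gps_prior"
  prior
}

#' @export
print.gps_prior <- function(x, ...) {
  cat(sprintf(paste0("Gamma-Poisson shrinker prior (fit on %d cells, ",
                     "loglik %.2f)\n"), x$n_cells, x$loglik))
  cat(sprintf("  component 1: Gamma(shape %.4g, rate %.4g), weight %.3f\n",
              x$alpha1, x$beta1, x$pi))
  cat(sprintf("  component 2: Gamma(shape %.4g, rate %.4g), weight %.3f\n",
              x$alpha2, x$beta2, 1 - x$pi))
  invisible(x)
}

# mixture mean of the prior relative report rate
gps_prior_mean <- function(prior) {
  prior$pi * prior$alpha1 / prior$beta1 +
    (1 - prior$pi) * prior$alpha2 / prior$beta2
}

#' Empirical-Bayes geometric mean and 5th percentile of the report rate
#'
#' Posterior of the relative report rate for a cell with count `a` and
#' expectation `E` is the two-component gamma mixture `Q Gamma(alpha1 + a,
#' beta1 + E) + (1 - Q) Gamma(alpha2 + a, beta2 + E)` with `Q` the
#' posterior component probability from the marginal masses. `EBGM =
#' 2^E[log2 rate]` via the digamma identity; `EBGM05` is the posterior 5th
#' percentile found by monotone root-finding on the mixture CDF.
#'
#' @param a Observed counts (vectorised).
#' @param E Independence expectations.
#' @param prior A fitted [fit_gps_prior()] object.
#' @return Data frame with `ebgm`, `ebgm05`, `defined`, `reason`.
#' @export
ebgm_scores <- function(a, E, prior) {
  stopifnot(inherits(prior, "gps_prior"), length(a) == length(E))
  bad <- !(E > 0)
  Efix <- ifelse(bad, 1, E)
  l1 <- log(prior$pi) + stats::dnbinom(a, size = prior$alpha1,
                                       prob = prior$beta1 / (prior$beta1 + Efix),
                                       log = TRUE)
  l2 <- log1p(-prior$pi) + stats::dnbinom(a, size = prior$alpha2,
                                          prob = prior$beta2 / (prior$beta2 + Efix),
                                          log = TRUE)
  Q <- 1 / (1 + exp(l2 - l1))
  s1 <- prior$alpha1 + a; r1 <- prior$beta1 + Efix
  s2 <- prior$alpha2 + a; r2 <- prior$beta2 + Efix
  elog <- Q * (digamma(s1) - log(r1)) + (1 - Q) * (digamma(s2) - log(r2))
  ebgm <- exp(elog)
  ebgm05 <- vapply(seq_along(a), function(i) {
    post_cdf <- function(x) {
      Q[i] * stats::pgamma(x, shape = s1[i], rate = r1[i]) +
        (1 - Q[i]) * stats::pgamma(x, shape = s2[i], rate = r2[i]) - 0.05
    }
    lo <- min(stats::qgamma(0.05, shape = s1[i], rate = r1[i]),
              stats::qgamma(0.05, shape = s2[i], rate = r2[i]))
    hi <- max(stats::qgamma(0.05, shape = s1[i], rate = r1[i]),
              stats::qgamma(0.05, shape = s2[i], rate = r2[i]))
    if (post_cdf(lo) > 0) return(lo)
    if (post_cdf(hi) < 0) return(hi)
    stats::uniroot(post_cdf, lower = lo, upper = hi, tol = 1e-8)$root
  }, 0.0)
  ebgm[bad] <- ebgm05[bad] <- NA_real_
  data.frame(ebgm = ebgm, ebgm05 = ebgm05, defined = !bad,
             reason = ifelse(bad, "zero expectation", NA_character_),
             stringsAsFactors = FALSE)
}

#' Default positivity thresholds for the four methods
#'
#' ROR: at least 3 cases and lower 95% bound above 1. PRR (MHRA combined
#' criterion): at least 3 cases, PRR at least 2, chi-squared at least 4.
#' BCPNN: IC025 above 0. Gamma Poisson shrinker: EBGM05 at least 2.
#'
#' @param ror_min_a,ror_lo Minimum count and lower-bound cut for ROR.
#' @param prr_min_a,prr_min,chi2_min MHRA combined criterion for PRR.
#' @param ic025_min Lower-bound cut for the information component.
#' @param ebgm05_min Cut on the posterior 5th percentile.
#' @return Named list of thresholds.
#' @export
signal_thresholds <- function(ror_min_a = 3, ror_lo = 1,
                              prr_min_a = 3, prr_min = 2, chi2_min = 4,
                              ic025_min = 0, ebgm05_min = 2) {
  list(ror_min_a = ror_min_a, ror_lo = ror_lo,
       prr_min_a = prr_min_a, prr_min = prr_min, chi2_min = chi2_min,
       ic025_min = ic025_min, ebgm05_min = ebgm05_min)
}

#' Apply positivity thresholds to computed statistics
#'
#' Adds the four per-method flags and the combined `positive` column (a
#' term is a potential adverse-reaction signal when at least one method
#' exceeds its threshold). Undefined statistics flag `FALSE`.
#'
#' @param stats Data frame as produced by [signal_stats()] (columns `a`,
#'   `ror_lo95`, `prr`, `chi2`, `ic025`, `ebgm05` at minimum).
#' @param thresholds A [signal_thresholds()] list.
#' @return `stats` with logical columns `flag_ror`, `flag_prr`,
#'   `flag_bcpnn`, `flag_mgps`, `positive`.
#' @export
evaluate_signal <- function(stats, thresholds = signal_thresholds()) {
  th <- thresholds
  flag <- function(x) !is.na(x) & x
  stats$flag_ror <- flag(stats$a >= th$ror_min_a & stats$ror_lo95 > th$ror_lo)
  stats$flag_prr <- flag(stats$a >= th$prr_min_a & stats$prr >= th$prr_min &
                           stats$chi2 >= th$chi2_min)
  stats$flag_bcpnn <- flag(stats$ic025 > th$ic025_min)
  if ("ebgm05" %in% names(stats)) {
    stats$flag_mgps <- flag(stats$ebgm05 >= th$ebgm05_min)
  } else {
    stats$flag_mgps <- FALSE
  }
  stats$positive <- stats$flag_ror | stats$flag_prr | stats$flag_bcpnn |
    stats$flag_mgps
  stats
}

#' Compute all four statistics for a set of contingency tables
#'
#' @param tables Output of [build_tables()].
#' @param prior Optional fitted [fit_gps_prior()]; when `NULL` the shrinker
#'   columns are omitted and its flag is `FALSE`.
#' @param thresholds A [signal_thresholds()] list.
#' @param haldane,yates Passed to [ror_stat()] and [prr_chi2()].
#' @return Data frame (one row per term) with counts, the four statistics
#'   with their bounds, per-method flags, and `positive`.
#' @export
signal_stats <- function(tables, prior = NULL, thresholds = signal_thresholds(),
                         haldane = FALSE, yates = TRUE) {
  out <- tables[c("term", "level", "a", "b", "c", "d", "n_total", "expected")]
  r <- ror_stat(tables$a, tables$b, tables$c, tables$d, haldane = haldane)
  p <- prr_chi2(tables$a, tables$b, tables$c, tables$d, yates = yates)
  b <- bcpnn_ic(tables$a, tables$b, tables$c, tables$d)
  out <- cbind(out, r[c("ror", "ror_lo95", "ror_hi95")],
               p[c("prr", "prr_lo95", "prr_hi95", "chi2")], b)
  if (!is.null(prior)) {
    e <- ebgm_scores(tables$a, tables$expected, prior)
    out <- cbind(out, e[c("ebgm", "ebgm05")])
  }
  evaluate_signal(out, thresholds)
}

#' Rank a signal table for reporting
#'
#' Stable descending sort by the chosen key, ties broken by term
#' (lexicographic), truncated to `top_n` rows.
#'
#' @param stats A [signal_stats()] data frame.
#' @param by `"frequency"` (the a-cell count), `"ebgm"`, or `"ror"`.
#' @param top_n Number of rows to keep (default 50).
#' @return The ranked, truncated data frame.
#' @export
rank_report <- function(stats, by = c("frequency", "ebgm", "ror"), top_n = 50L) {
  by <- match.arg(by)
  key <- switch(by, frequency = stats$a, ebgm = stats$ebgm, ror = stats$ror)
  if (is.null(key)) stop("ranking key not present in the statistics table",
                         call. = FALSE)
  key[is.na(key)] <- -Inf
  out <- stats[order(-key, stats$term), , drop = FALSE]
  utils::head(out, top_n)
}
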