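# Time-to-onset: days from the start of target-drug therapy (THER file,
# earliest start when several rows link to the drug) to the reported event
# date (DEMO file), with a Weibull model of the hazard over time.

onset_bins <- function(days) {
  cut(days, breaks = c(-0.5, 0.5, 30.5, 60.5, 182.5, 365.5, Inf),
      labels = c("0 days", "<=1 month", "1-2 months", "2-6 months",
                 "6-12 months", ">12 months"))
}

#' Compute time-to-onset records for a cohort
#'
#' Onset is the whole-day difference between the DEMO event date and the
#' earliest THER start date linked to the target drug's sequence number.
#' Records with a missing or partial (YYYYMM / YYYY) event or start date,
#' or a negative difference, are marked unreliable with exactly one reason
#' and excluded from the summary; nothing is dropped silently.
#'
#' @param cohort A `faers_cohort` from [select_primary_suspect()].
#' @return List of class `onset_summary`: `records` (one row per linked
#'   report: `primaryid`, `onset_days`, `reliable`, `reason`), `n_reliable`,
#'   `median`, `iqr`, and `timeline` (counts per onset bin).
#' @export
compute_onset <- function(cohort) {
  stopifnot(inherits(cohort, "faers_cohort"))
  ther <- cohort$ther
  tseq <- cohort$target_drug_seq
  if (nrow(ther) == 0 || nrow(tseq) == 0) {
    warning("cohort has no therapy records for the target drug", call. = FALSE)
    out <- list(records = data.frame(primaryid = character(0),
                                     onset_days = integer(0),
                                     reliable = logical(0),
                                     reason = character(0),
                                     stringsAsFactors = FALSE),
                n_reliable = 0L, median = NA_real_,
                iqr = c(NA_real_, NA_real_), timeline = NULL)
    class(out) <- "onset_summary"
    return(out)
  }
  key <- paste(ther$primaryid, ther$dsg_drug_seq)
  tkey <- paste(tseq$primaryid, tseq$drug_seq)
  linked <- ther[key %in% tkey, , drop = FALSE]

  ids <- unique(linked$primaryid)
  demo <- cohort$demo
  event_dt <- demo$event_dt[match(ids, demo$primaryid)]

  # earliest full start date per report; remember whether any start field
  # was present but partial / all missing
  rec <- data.frame(primaryid = ids, onset_days = NA_integer_,
                    reliable = FALSE, reason = NA_character_,
                    stringsAsFactors = FALSE)
  starts_by_id <- split(linked$start_dt, factor(linked$primaryid, levels = ids))
  for (i in seq_along(ids)) {
    starts <- starts_by_id[[i]]
    full <- starts[is_full_date(starts)]
    ev <- event_dt[i]
    if (length(full) == 0) {
      rec$reason[i] <- if (any(is_partial_date(starts))) "partial date" else "missing date"
      next
    }
    if (is.na(ev)) {
      rec$reason[i] <- "missing date"
      next
    }
    if (!is_full_date(ev)) {
      rec$reason[i] <- "partial date"
      next
    }
    d <- as.integer(ymd_to_date(ev) - min(ymd_to_date(full)))
    if (d < 0) {
      rec$reason[i] <- "negative interval"
      next
    }
    rec$onset_days[i] <- d
    rec$reliable[i] <- TRUE
  }
  rel <- rec$onset_days[rec$reliable]
  timeline <- if (length(rel)) {
    tab <- table(onset_bins(rel))
    data.frame(bin = names(tab), count = as.integer(tab),
               pct = report_percentage(as.integer(tab), length(rel)),
               stringsAsFactors = FALSE)
  } else NULL
  out <- list(records = rec,
              n_reliable = length(rel),
              median = if (length(rel)) stats::median(rel) else NA_real_,
              iqr = if (length(rel)) {
                unname(stats::quantile(rel, c(0.25, 0.75), type = 7))
              } else c(NA_real_, NA_real_),
              timeline = timeline)
  class(out) <- "onset_summary"
  out
}

#' @export
print.onset_summary <- function(x, ...) {
  cat(sprintf("Time-to-onset: %d reliable of %d linked reports\n",
              x$n_reliable, nrow(x$records)))
  if (x$n_reliable > 0) {
    cat(sprintf("  median %.0f days (IQR %.2f-%.2f)\n", x$median,
                x$iqr[1], x$iqr[2]))
    for (i in seq_len(nrow(x$timeline))) {
      cat(sprintf("  %-12s %6d  %6.2f%%\n", x$timeline$bin[i],
                  x$timeline$count[i], x$timeline$pct[i]))
    }
  }
  invisible(x)
}

#' Maximum-likelihood Weibull fit of onset times
#'
#' Fits the Weibull density `f(t) = (shape/scale) (t/scale)^(shape-1)
#' exp(-(t/scale)^shape)` to the adjusted times `t = onset + offset` (the
#' half-day default places day-0 observations inside the support).
#' Confidence intervals come from the observed-information normal
#' approximation on the log parameters. The hazard profile is classified
#' from the shape interval: early-failure when the upper bound is below 1
#' (decreasing hazard), wear-out when the lower bound exceeds 1, random
#' when the interval contains 1.
#'
#' @param onsets Non-negative onset times (days).
#' @param offset Added to every time before fitting (default 0.5 days; set
#'   0 for continuous positive data).
#' @param conf Confidence level (default 0.95).
#' @return Object of class `weibull_fit`: `shape`, `shape_ci`, `scale`,
#'   `scale_ci`, `loglik`, `n_used`, `classification` (and `reason` when
#'   indeterminate).
#' @export
weibull_fit <- function(onsets, offset = 0.5, conf = 0.95) {
  onsets <- onsets[!is.na(onsets)]
  t <- onsets + offset
  indeterminate <- function(reason) {
    structure(list(shape = NA_real_, shape_ci = c(NA_real_, NA_real_),
                   scale = NA_real_, scale_ci = c(NA_real_, NA_real_),
                   loglik = NA_real_, n_used = length(t),
                   classification = "indeterminate", reason = reason,
                   offset = offset),
              class = "weibull_fit")
  }
  if (length(t) < 10) return(indeterminate("fewer than 10 records"))
  if (length(unique(t)) == 1) return(indeterminate("all onset times identical"))
  if (any(t <= 0)) return(indeterminate("non-positive adjusted times"))

  negll <- function(theta) {
    val <- suppressWarnings(
      -sum(stats::dweibull(t, shape = exp(theta[1]), scale = exp(theta[2]),
                           log = TRUE)))
    if (!is.finite(val)) val <- .Machine$double.xmax / 1e6
    val
  }
  # moment-style start: exponential scale, unit shape
  theta0 <- c(0, log(mean(t)))
  fit <- stats::optim(theta0, negll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  if (fit$convergence != 0) return(indeterminate("optimizer did not converge"))
  vc <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  if (is.null(vc) || any(diag(vc) <= 0)) {
    return(indeterminate("singular observed information"))
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(diag(vc))
  shape <- exp(fit$par[1]); scale <- exp(fit$par[2])
  shape_ci <- exp(fit$par[1] + c(-1, 1) * z * se[1])
  scale_ci <- exp(fit$par[2] + c(-1, 1) * z * se[2])
  classification <- if (shape_ci[2] < 1) "early-failure"
    else if (shape_ci[1] > 1) "wear-out" else "random"
  structure(list(shape = shape, shape_ci = shape_ci,
                 scale = scale, scale_ci = scale_ci,
                 loglik = -fit$value, n_used = length(t),
                 classification = classification, reason = NA_character_,
                 offset = offset),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  if (x$classification == "indeterminate") {
    cat("Weibull fit: indeterminate (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("Weibull fit on %d records (offset %.2g days)\n", x$n_used,
              x$offset))
  cat(sprintf("  shape %.3f (95%% CI %.3f-%.3f)\n", x$shape, x$shape_ci[1],
              x$shape_ci[2]))
  cat(sprintf("  scale %.2f days (95%% CI %.2f-%.2f)\n", x$scale,
              x$scale_ci[1], x$scale_ci[2]))
  cat("  hazard profile:", x$classification, "\n")
  invisible(x)
}

#' Empirical cumulative incidence of onset times
#'
#' @param onsets Non-negative onset times (days).
#' @return Data frame (`day`, `cum_fraction`): the empirical CDF evaluated
#'   at each distinct onset day; monotone non-decreasing with final value
#'   exactly 1.
#' @export
cumulative_incidence <- function(onsets) {
  onsets <- onsets[!is.na(onsets)]
  if (length(onsets) == 0) stop("no reliable onset records", call. = FALSE)
  days <- sort(unique(onsets))
  data.frame(day = days,
             cum_fraction = cumsum(as.integer(table(factor(onsets, levels = days)))) /
               length(onsets))
}
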