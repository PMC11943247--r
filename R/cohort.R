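# Primary-suspect cohort selection and descriptive summaries.

# Age-unit conversion to years. FAERS codes: DEC decades, YR years, MON
# months, WK weeks, DY days, HR hours.
AGE_UNIT_TO_YEARS <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.14,
                       DY = 1 / 365.25, HR = 1 / 8765.8)

#' Convert FAERS age values to years
#'
#' @param age Numeric (or numeric-as-character) age values.
#' @param unit Age unit codes (`DEC`, `YR`, `MON`, `WK`, `DY`, `HR`).
#' @return Numeric vector of ages in years; `NA` where the value or unit is
#'   missing or unrecognised.
#' @export
age_in_years <- function(age, unit) {
  val <- suppressWarnings(as.numeric(age))
  fac <- AGE_UNIT_TO_YEARS[toupper(as.character(unit))]
  unname(val * fac)
}

normalize_drugname <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- gsub("[[:punct:]]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Select reports with the target drug as primary suspect
#'
#' A report enters the cohort when at least one of its drug rows has role
#' code `PS` and a drug name or active ingredient matching one of the
#' supplied synonyms, case-insensitively after trimming and punctuation
#' normalisation. Matching is exact after normalisation by default;
#' `match = "substring"` accepts names containing a synonym.
#'
#' @param store A `faers_case_store` from [ingest_faers()].
#' @param drug_synonyms Non-empty character vector of names the drug is
#'   reported under.
#' @param match `"exact"` (default) or `"substring"`.
#' @return Object of class `faers_cohort`: the store's tables filtered to
#'   the cohort, the cohort's PRIMARYIDs, and the target drug-sequence
#'   numbers per report (used to link therapy dates).
#' @export
select_primary_suspect <- function(store, drug_synonyms = c("REGADENOSON", "LEXISCAN"),
                                   match = c("exact", "substring")) {
  match <- match.arg(match)
  if (length(drug_synonyms) == 0) {
    stop("drug_synonyms must be non-empty", call. = FALSE)
  }
  stopifnot(inherits(store, "faers_case_store"))
  syn <- normalize_drugname(drug_synonyms)
  drug <- store$drug
  nm <- normalize_drugname(drug$drugname)
  ai <- if ("prod_ai" %in% names(drug)) normalize_drugname(drug$prod_ai) else nm
  if (match == "exact") {
    name_hit <- nm %in% syn | ai %in% syn
  } else {
    pat <- paste(vapply(syn, function(s) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s), ""),
                 collapse = "|")
    name_hit <- grepl(pat, nm) | grepl(pat, ai)
  }
  hit <- name_hit & toupper(drug$role_cod) == "PS" & !is.na(drug$role_cod)
  ids <- unique(drug$primaryid[hit])
  # a case report must carry at least one reaction
  ids <- ids[ids %in% store$reac$primaryid]
  target_seq <- unique(drug[hit & drug$primaryid %in% ids,
                            c("primaryid", "drug_seq")])
  cohort <- list(
    ids = sort(ids),
    demo = store$demo[store$demo$primaryid %in% ids, , drop = FALSE],
    drug = store$drug[store$drug$primaryid %in% ids, , drop = FALSE],
    reac = store$reac[store$reac$primaryid %in% ids, , drop = FALSE],
    ther = store$ther[store$ther$primaryid %in% ids, , drop = FALSE],
    outc = store$outc[store$outc$primaryid %in% ids, , drop = FALSE],
    target_drug_seq = target_seq,
    synonyms = drug_synonyms)
  class(cohort) <- "faers_cohort"
  cohort
}

#' Severity of one case from its outcome codes
#'
#' A case is severe when any outcome code is among the FDA serious-outcome
#' codes DE (death), LT (life-threatening), HO (hospitalisation), DS
#' (disability), CA (congenital anomaly), RI (required intervention);
#' otherwise (including no outcome rows) non-severe.
#'
#' @param outcomes Character vector of outcome codes for one case.
#' @return `"severe"` or `"non-severe"`.
#' @export
severity_flag <- function(outcomes) {
  if (any(toupper(outcomes) %in% SERIOUS_OUTCOMES)) "severe" else "non-severe"
}

# vectorised severity for a set of reports
severity_by_report <- function(ids, outc) {
  sev_ids <- unique(outc$primaryid[toupper(outc$outc_cod) %in% SERIOUS_OUTCOMES])
  ifelse(ids %in% sev_ids, "severe", "non-severe")
}

count_table <- function(categories, levels, total) {
  counts <- vapply(levels, function(l) sum(categories == l, na.rm = TRUE), 0L)
  data.frame(category = levels, count = unname(counts),
             pct = report_percentage(unname(counts), total),
             stringsAsFactors = FALSE)
}

#' Descriptive summary of a cohort
#'
#' Counts and percentages (rounded half-up to two decimals) by sex, age
#' band, reporter occupation, severity, reporting year (from the retained
#' report's FDA receipt date), and top reporting countries, plus the age
#' median and interquartile range in years. Ages are converted to years
#' from their unit codes before banding; unconvertible ages fall into
#' "not specified".
#'
#' @param cohort A `faers_cohort`.
#' @param top_countries Number of countries to list (default 5).
#' @return Object of class `demographics_summary` (a list of small data
#'   frames plus totals); `NULL`-totalled sentinel when the cohort is
#'   empty.
#' @export
summarize_demographics <- function(cohort, top_countries = 5L) {
  stopifnot(inherits(cohort, "faers_cohort"))
  demo <- cohort$demo
  total <- nrow(demo)
  if (total == 0) {
    out <- list(total = 0L, empty = TRUE)
    class(out) <- "demographics_summary"
    warning("empty cohort: returning empty summary", call. = FALSE)
    return(out)
  }

  sex <- toupper(ifelse(is.na(demo$sex), "NOT_SPECIFIED", demo$sex))
  sex[!sex %in% c("M", "F")] <- "NOT_SPECIFIED"
  sex_tab <- count_table(sex, c("F", "M", "NOT_SPECIFIED"), total)
  sex_tab$category <- c("Female", "Male", "Not specified")

  age_yr <- age_in_years(demo$age, demo$age_cod)
  band <- cut(age_yr, breaks = c(-Inf, 18, 45, 65, Inf), right = FALSE,
              labels = c("<18", "18-44", "45-64", ">=65"))
  band <- as.character(band)
  band[is.na(band)] <- "Not specified"
  age_tab <- count_table(band, c("<18", "18-44", "45-64", ">=65", "Not specified"),
                         total)
  known_age <- age_yr[!is.na(age_yr)]
  age_median <- if (length(known_age)) stats::median(known_age) else NA_real_
  age_iqr <- if (length(known_age)) {
    unname(stats::quantile(known_age, c(0.25, 0.75), type = 7))
  } else c(NA_real_, NA_real_)

  occ <- toupper(ifelse(is.na(demo$occp_cod), "NOT_SPECIFIED", demo$occp_cod))
  occ[!occ %in% c("CN", "MD", "PH", "HP")] <- "NOT_SPECIFIED"
  rep_tab <- count_table(occ, c("CN", "HP", "PH", "MD", "NOT_SPECIFIED"), total)
  rep_tab$category <- c("Consumer", "Other health professionals", "Pharmacist",
                        "Physician", "Not specified")

  sev <- severity_by_report(demo$primaryid, cohort$outc)
  sev_tab <- count_table(sev, c("severe", "non-severe"), total)
  sev_tab$category <- c("Severe", "Non-severe")

  year <- substr(pad_partial_date(demo$fda_dt), 1, 4)
  yr_levels <- sort(unique(year))
  year_tab <- count_table(year, yr_levels, total)

  country <- ifelse(is.na(demo$reporter_country), "Not specified",
                    demo$reporter_country)
  ctab <- sort(table(country), decreasing = TRUE)
  k <- min(top_countries, length(ctab))
  country_tab <- data.frame(category = names(ctab)[seq_len(k)],
                            count = as.integer(ctab[seq_len(k)]),
                            pct = report_percentage(as.integer(ctab[seq_len(k)]),
                                                    total),
                            stringsAsFactors = FALSE)

  n_events <- nrow(unique(cohort$reac[, c("primaryid", "pt")]))

  out <- list(total = total, n_events = n_events,
              sex = sex_tab, age = age_tab,
              age_median = age_median, age_iqr = age_iqr,
              reporter = rep_tab, severity = sev_tab,
              year = year_tab, countries = country_tab, empty = FALSE)
  class(out) <- "demographics_summary"
  out
}

#' @export
print.demographics_summary <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("Empty cohort summary\n")
    return(invisible(x))
  }
  cat(sprintf("Cohort: %d reports, %d (report, PT) adverse-event pairs\n",
              x$total, x$n_events))
  cat(sprintf("Age: median %.0f years (IQR %.0f-%.0f)\n",
              x$age_median, x$age_iqr[1], x$age_iqr[2]))
  for (nm in c("sex", "age", "reporter", "severity")) {
    cat(nm, ":\n", sep = "")
    tab <- x[[nm]]
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("  %-28s %6d  %6.2f%%\n", tab$category[i], tab$count[i],
                  tab$pct[i]))
    }
  }
  invisible(x)
}
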