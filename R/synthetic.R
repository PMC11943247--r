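# Synthetic FAERS-style data with known ground truth.
#
# The generator emulates the structural features of the public quarterly
# ASCII packages that matter to a signal-detection pipeline: "$"-delimited
# DEMO/DRUG/REAC/THER/OUTC tables, case re-reporting across quarters (same
# CASEID, new PRIMARYID, later FDA_DT), quarterly deletion lists from 2019Q1
# on, role-coded drug entries, partial and missing dates, and a
# day-0-dominated time-to-onset distribution. Drug-event counts follow a
# gamma-Poisson mixture with a configurable set of planted elevated-risk
# pairs, so recovery of the planted pairs is a ground-truth test for the
# whole pipeline.

# The 27 MedDRA system organ classes (primary SOC assignment cycles
# through these).
MEDDRA_SOCS <- c(
  "Nervous system disorders",
  "General disorders and administration site conditions",
  "Gastrointestinal disorders",
  "Cardiac disorders",
  "Investigations",
  "Respiratory, thoracic and mediastinal disorders",
  "Vascular disorders",
  "Musculoskeletal and connective tissue disorders",
  "Injury, poisoning and procedural complications",
  "Skin and subcutaneous tissue disorders",
  "Psychiatric disorders",
  "Product issues",
  "Eye disorders",
  "Immune system disorders",
  "Renal and urinary disorders",
  "Infections and infestations",
  "Metabolism and nutrition disorders",
  "Surgical and medical procedures",
  "Social circumstances",
  "Reproductive system and breast disorders",
  "Ear and labyrinth disorders",
  "Blood and lymphatic system disorders",
  "Hepatobiliary disorders",
  "Congenital, familial and genetic disorders",
  "Neoplasms benign, malignant and unspecified (incl cysts and polyps)",
  "Endocrine disorders",
  "Pregnancy, puerperium and perinatal conditions"
)

#' Configuration for the synthetic FAERS generator
#'
#' Defines the study conditions a generated package emulates. The default
#' values describe a 20,000-report snapshot over three recent quarters with
#' a primary-suspect drug of interest (drug index 1, reported under two
#' trade/generic synonyms), five planted elevated-risk drug-event pairs, a
#' two-component gamma mixture of background relative risks, 10% case
#' re-reporting, 2% deletion-list retraction, and a time-to-onset
#' distribution with 99% of events on the day of administration and a
#' Weibull(shape 0.6, scale 30 days) tail.
#'
#' @param n_drugs Number of drugs in the vocabulary; drug 1 is the target.
#' @param n_events Number of preferred terms (PTs) in the vocabulary.
#' @param n_reports Expected number of reports (the realised count is the
#'   Poisson total over all drug-event cells).
#' @param quarters Ordered character vector of quarter labels, e.g.
#'   `"2024Q1"`.
#' @param planted_signals Data frame with columns `drug`, `event`, `rr`
#'   giving vocabulary indices and true relative risks (> 1) of planted
#'   elevated-risk pairs.
#' @param background_prior List with `alpha1`, `beta1`, `alpha2`, `beta2`,
#'   `pi`: the two-component gamma mixture the background (non-planted)
#'   relative risks are drawn from. `NULL` fixes all background relative
#'   risks at exactly 1 (pure independence nulls).
#' @param duplication_rate Probability that a case is re-reported with a new
#'   PRIMARYID and later FDA_DT.
#' @param deletion_rate Probability that a case is retracted via a quarterly
#'   deletion list (applies only when some quarter is 2019Q1 or later).
#' @param onset_shape,onset_scale Weibull parameters (days) of the non-zero
#'   time-to-onset tail.
#' @param day0_mass Probability an onset time is exactly 0 days.
#' @param missingness Named list of per-field missing-data probabilities
#'   (`event_dt`, `start_dt`, `age`, `sex`, `occp_cod`).
#' @param partial_date_rate Fraction of emitted dates truncated to YYYYMM or
#'   YYYY to exercise partial-date handling.
#' @param synonym_rate Fraction of reaction rows written under an obsolete
#'   PT name that the shipped dictionary maps to the current PT.
#' @param concomitant_rate Probability a report carries one additional
#'   concomitant (role C) drug row.
#' @param severe_rate Probability a report carries a serious outcome code.
#' @param target_synonyms Character vector of names the target drug is
#'   reported under.
#' @param seed Integer seed; every random draw in the generator flows from
#'   it.
#' @return An object of class `faers_sim_config`.
#' @export
faers_sim_config <- function(n_drugs = 25L,
                             n_events = 80L,
                             n_reports = 20000L,
                             quarters = c("2024Q1", "2024Q2", "2024Q3"),
                             planted_signals = data.frame(
                               drug = 1L, event = 1:5,
                               rr = c(5, 6, 8, 10, 12)),
                             background_prior = list(
                               alpha1 = 0.2, beta1 = 0.1,
                               alpha2 = 2.0, beta2 = 4.0, pi = 1 / 3),
                             duplication_rate = 0.10,
                             deletion_rate = 0.02,
                             onset_shape = 0.6,
                             onset_scale = 30,
                             day0_mass = 0.99,
                             missingness = list(
                               event_dt = 0.35, start_dt = 0.30,
                               age = 0.25, sex = 0.15, occp_cod = 0.05),
                             partial_date_rate = 0.05,
                             synonym_rate = 0.02,
                             concomitant_rate = 0.30,
                             severe_rate = 0.5635,
                             target_synonyms = c("REGADENOSON", "LEXISCAN"),
                             seed = 1L) {
  cfg <- list(
    n_drugs = as.integer(n_drugs), n_events = as.integer(n_events),
    n_reports = as.integer(n_reports), quarters = as.character(quarters),
    planted_signals = planted_signals, background_prior = background_prior,
    duplication_rate = duplication_rate, deletion_rate = deletion_rate,
    onset_shape = onset_shape, onset_scale = onset_scale,
    day0_mass = day0_mass, missingness = missingness,
    partial_date_rate = partial_date_rate, synonym_rate = synonym_rate,
    concomitant_rate = concomitant_rate, severe_rate = severe_rate,
    target_synonyms = toupper(target_synonyms), seed = as.integer(seed))
  class(cfg) <- "faers_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_drugs >= 1L, cfg$n_events >= 1L, cfg$n_reports >= 1L,
            length(cfg$quarters) >= 1L)
  validate_quarter(cfg$quarters)
  probs <- c(cfg$duplication_rate, cfg$deletion_rate, cfg$day0_mass,
             cfg$partial_date_rate, cfg$synonym_rate, cfg$concomitant_rate,
             cfg$severe_rate, unlist(cfg$missingness))
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$onset_shape <= 0 || cfg$onset_scale <= 0) {
    stop("onset_shape and onset_scale must be positive", call. = FALSE)
  }
  ps <- cfg$planted_signals
  if (nrow(ps) > 0) {
    stopifnot(all(c("drug", "event", "rr") %in% names(ps)))
    if (any(ps$rr <= 0)) stop("planted relative risks must be > 0", call. = FALSE)
    if (any(ps$drug < 1 | ps$drug > cfg$n_drugs) ||
        any(ps$event < 1 | ps$event > cfg$n_events)) {
      stop("planted signal indices outside vocabulary bounds", call. = FALSE)
    }
    if (anyDuplicated(ps[c("drug", "event")])) {
      stop("duplicated planted (drug, event) pair", call. = FALSE)
    }
  }
  bp <- cfg$background_prior
  if (!is.null(bp)) {
    stopifnot(all(c("alpha1", "beta1", "alpha2", "beta2", "pi") %in% names(bp)))
    if (any(unlist(bp[c("alpha1", "beta1", "alpha2", "beta2")]) <= 0) ||
        bp$pi <= 0 || bp$pi >= 1) {
      stop("background_prior parameters must be positive with pi in (0,1)",
           call. = FALSE)
    }
  }
  if (length(cfg$target_synonyms) < 1L) {
    stop("target_synonyms must be non-empty", call. = FALSE)
  }
  invisible(cfg)
}

sim_drug_names <- function(n) {
  c("REGADENOSON", sprintf("DRUG_%04d", seq_len(n))[-1])
}

sim_event_names <- function(n) {
  sprintf("EVENT_%04d", seq_len(n))
}

# marginal report probabilities: mild power laws so cell expectations span
# a realistic range without any cell being vanishingly rare
sim_drug_probs <- function(n) {
  w <- seq_len(n)^(-0.7)
  w / sum(w)
}

sim_event_probs <- function(n) {
  w <- seq_len(n)^(-0.5)
  w / sum(w)
}

random_date_in <- function(n, from, to) {
  span <- as.integer(to - from)
  from + sample.int(span + 1L, n, replace = TRUE) - 1L
}

# truncate a fraction of YYYYMMDD strings to YYYYMM or YYYY
truncate_dates <- function(x, rate) {
  n <- length(x)
  hit <- !is.na(x) & stats::runif(n) < rate
  kind <- stats::runif(n) < 0.5
  x[hit & kind] <- substr(x[hit & kind], 1, 6)
  x[hit & !kind] <- substr(x[hit & !kind], 1, 4)
  x
}

#' Generate a synthetic FAERS-style quarterly package
#'
#' Writes per-quarter DEMO/DRUG/REAC/THER/OUTC files in the FAERS ASCII
#' dialect (plus deletion lists for quarters from 2019Q1 on and a PT-to-SOC
#' dictionary TSV) and returns the generation ground truth. Each drug-event
#' cell count is drawn as Poisson with mean E * lambda, where E is the
#' independence expectation implied by the configured marginals and lambda
#' the cell's true relative risk (planted, mixture-drawn, or 1).
#'
#' @param config A [faers_sim_config()] object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, an object of class `faers_ground_truth`: the planted
#'   pairs, the full expectation and relative-risk matrices, the duplicate
#'   map, the deleted case ids, per-report true onset times, and the set of
#'   report ids a correct ingest must retain. Also serialised to
#'   `ground_truth.json` in `dir`.
#' @export
generate_faers_package <- function(config, dir) {
  validate_sim_config(config)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  }
  if (file.access(dir, mode = 2) != 0) {
    stop("output directory is not writable: ", dir, call. = FALSE)
  }
  set.seed(config$seed)

  nd <- config$n_drugs
  ne <- config$n_events
  drug_names <- sim_drug_names(nd)
  event_pts <- sim_event_names(ne)
  p_drug <- sim_drug_probs(nd)
  q_event <- sim_event_probs(ne)

  E <- config$n_reports * outer(p_drug, q_event)
  lambda <- matrix(1, nd, ne)
  bp <- config$background_prior
  if (!is.null(bp)) {
    comp <- stats::runif(nd * ne) < bp$pi
    lam <- numeric(nd * ne)
    lam[comp] <- stats::rgamma(sum(comp), shape = bp$alpha1, rate = bp$beta1)
    lam[!comp] <- stats::rgamma(sum(!comp), shape = bp$alpha2, rate = bp$beta2)
    lambda <- matrix(lam, nd, ne)
  }
  ps <- config$planted_signals
  if (nrow(ps) > 0) {
    lambda[cbind(ps$drug, ps$event)] <- ps$rr
  }

  counts <- matrix(stats::rpois(nd * ne, E * lambda), nd, ne)
  n_cases <- sum(counts)
  if (n_cases == 0L) stop("configuration produced zero reports", call. = FALSE)

  # one report per (drug, event) instance
  idx <- which(counts > 0, arr.ind = TRUE)
  drug_i <- rep(idx[, 1], counts[idx])
  event_j <- rep(idx[, 2], counts[idx])
  ord <- sample.int(n_cases)         # shuffle so case ids carry no signal
  drug_i <- drug_i[ord]
  event_j <- event_j[ord]

  caseid <- 10000000L + seq_len(n_cases)
  primaryid <- caseid * 10L + 1L

  quarters <- config$quarters
  qi <- sample.int(length(quarters), n_cases, replace = TRUE)
  qs <- quarter_start(quarters)[qi]
  qe <- as.Date(vapply(quarters, function(q) as.character(quarter_end(q)), ""))[qi]
  fda_date <- qs + floor(stats::runif(n_cases) * (as.integer(qe - qs) + 1L))

  # onset: point mass at day 0 plus a Weibull tail (floored to whole days);
  # event date and therapy start are derived backwards from the receipt date
  # so that start <= event <= fda receipt always holds
  onset_days <- ifelse(stats::runif(n_cases) < config$day0_mass, 0L,
                       as.integer(floor(stats::rweibull(
                         n_cases, shape = config$onset_shape,
                         scale = config$onset_scale))))
  report_delay <- sample.int(21L, n_cases, replace = TRUE) - 1L
  event_date <- fda_date - report_delay
  start_date <- event_date - onset_days

  miss <- config$missingness
  event_dt <- date_to_ymd(event_date)
  start_dt <- date_to_ymd(start_date)
  event_missing <- stats::runif(n_cases) < miss$event_dt
  start_missing <- stats::runif(n_cases) < miss$start_dt
  event_dt[event_missing] <- NA
  start_dt[start_missing] <- NA
  event_dt <- truncate_dates(event_dt, config$partial_date_rate)
  start_dt <- truncate_dates(start_dt, config$partial_date_rate)
  onset_reliable <- !event_missing & !start_missing &
    is_full_date(event_dt) & is_full_date(start_dt)

  # demographics
  age_years <- pmin(pmax(round(stats::rnorm(n_cases, 66, 15)), 1), 100)
  age_cod <- sample(c("YR", "DEC", "MON"), n_cases, replace = TRUE,
                    prob = c(0.92, 0.05, 0.03))
  age_val <- ifelse(age_cod == "YR", age_years,
                    ifelse(age_cod == "DEC", round(age_years / 10),
                           age_years * 12))
  age_miss <- stats::runif(n_cases) < miss$age
  age_val[age_miss] <- NA
  age_cod[age_miss] <- NA
  sex <- sample(c("F", "M"), n_cases, replace = TRUE, prob = c(0.55, 0.45))
  sex[stats::runif(n_cases) < miss$sex] <- NA
  occp <- sample(c("CN", "MD", "PH", "HP"), n_cases, replace = TRUE,
                 prob = c(0.52, 0.19, 0.24, 0.05))
  occp[stats::runif(n_cases) < miss$occp_cod] <- NA
  country <- sample(c("US", "GB", "DE", "SE", "FR"), n_cases, replace = TRUE,
                    prob = c(0.98, 0.0064, 0.0018, 0.0011, 0.0107 - 0.0093))

  demo <- data.frame(
    primaryid = as.character(primaryid),
    caseid = as.character(caseid),
    caseversion = "1",
    fda_dt = date_to_ymd(fda_date),
    init_fda_dt = date_to_ymd(fda_date),
    event_dt = event_dt,
    age = ifelse(is.na(age_val), NA, as.character(age_val)),
    age_cod = age_cod,
    sex = sex,
    occp_cod = occp,
    reporter_country = country,
    quarter = quarters[qi],
    stringsAsFactors = FALSE)

  # drug table: the instance drug as primary suspect, optional concomitant
  target_name <- sample(config$target_synonyms, n_cases, replace = TRUE,
                        prob = c(0.7, rep(0.3 / max(1, length(config$target_synonyms) - 1),
                                          length(config$target_synonyms) - 1))[
                                            seq_along(config$target_synonyms)])
  drugname <- ifelse(drug_i == 1L, target_name, drug_names[drug_i])
  drug <- data.frame(
    primaryid = as.character(primaryid),
    caseid = as.character(caseid),
    drug_seq = "1",
    role_cod = "PS",
    drugname = drugname,
    prod_ai = drug_names[drug_i],
    stringsAsFactors = FALSE)
  has_con <- stats::runif(n_cases) < config$concomitant_rate
  if (any(has_con)) {
    con_drug <- sample(2:max(2L, nd), sum(has_con), replace = TRUE)
    drug <- rbind(drug, data.frame(
      primaryid = as.character(primaryid[has_con]),
      caseid = as.character(caseid[has_con]),
      drug_seq = "2",
      role_cod = "C",
      drugname = drug_names[con_drug],
      prod_ai = drug_names[con_drug],
      stringsAsFactors = FALSE))
  }

  # reaction table: one PT per report, occasionally under an obsolete name
  pt_out <- event_pts[event_j]
  old_hit <- stats::runif(n_cases) < config$synonym_rate
  pt_out[old_hit] <- sub("^EVENT_", "OLD_EVENT_", pt_out[old_hit])
  reac <- data.frame(
    primaryid = as.character(primaryid),
    caseid = as.character(caseid),
    pt = pt_out,
    stringsAsFactors = FALSE)

  ther <- data.frame(
    primaryid = as.character(primaryid),
    caseid = as.character(caseid),
    dsg_drug_seq = "1",
    start_dt = start_dt,
    end_dt = start_dt,
    stringsAsFactors = FALSE)

  severe <- stats::runif(n_cases) < config$severe_rate
  outc_code <- character(n_cases)
  outc_code[severe] <- sample(c("DE", "LT", "HO", "DS", "CA", "RI"),
                              sum(severe), replace = TRUE,
                              prob = c(0.05, 0.05, 0.55, 0.10, 0.05, 0.20))
  nonsev_row <- !severe & stats::runif(n_cases) < 0.5
  outc_code[nonsev_row] <- "OT"
  has_outc <- outc_code != ""
  outc <- data.frame(
    primaryid = as.character(primaryid[has_outc]),
    caseid = as.character(caseid[has_outc]),
    outc_cod = outc_code[has_outc],
    stringsAsFactors = FALSE)

  # duplicates: re-report with new primaryid, later fda_dt, same or later
  # quarter; the duplicate is the version a correct dedup retains
  dup <- stats::runif(n_cases) < config$duplication_rate
  dup_ids <- which(dup)
  duplicate_map <- data.frame(caseid = character(0), primaryid_first = character(0),
                              primaryid_latest = character(0),
                              stringsAsFactors = FALSE)
  if (length(dup_ids) > 0) {
    nq <- length(quarters)
    dq <- pmin(qi[dup_ids] + sample(0:1, length(dup_ids), replace = TRUE), nq)
    dqs <- quarter_start(quarters)[dq]
    dqe <- as.Date(vapply(quarters, function(q) as.character(quarter_end(q)), ""))[dq]
    # strictly later receipt date when room allows; ties exercise the
    # largest-PRIMARYID rule
    lo <- pmax(dqs, fda_date[dup_ids])
    fda2 <- lo + floor(stats::runif(length(dup_ids)) * (as.integer(dqe - lo) + 1L))
    pid2 <- caseid[dup_ids] * 10L + 2L
    demo2 <- demo[dup_ids, ]
    demo2$primaryid <- as.character(pid2)
    demo2$caseversion <- "2"
    demo2$fda_dt <- date_to_ymd(fda2)
    demo2$quarter <- quarters[dq]
    demo <- rbind(demo, demo2)
    dup_tab <- function(tab) {
      sel <- tab$primaryid %in% as.character(primaryid[dup_ids])
      t2 <- tab[sel, ]
      t2$primaryid <- as.character(as.numeric(t2$caseid) * 10 + 2)
      rbind(tab, t2)
    }
    drug <- dup_tab(drug)
    reac <- dup_tab(reac)
    ther <- dup_tab(ther)
    outc <- dup_tab(outc)
    duplicate_map <- data.frame(
      caseid = as.character(caseid[dup_ids]),
      primaryid_first = as.character(primaryid[dup_ids]),
      primaryid_latest = as.character(pid2),
      stringsAsFactors = FALSE)
  }

  # deletion lists (quarters >= 2019Q1 only)
  del_quarters <- quarters[has_deletion_list(quarters)]
  deleted_caseids <- character(0)
  deletions <- stats::setNames(
    rep(list(character(0)), length(del_quarters)), del_quarters)
  if (length(del_quarters) > 0 && config$deletion_rate > 0) {
    del <- stats::runif(n_cases) < config$deletion_rate
    deleted_caseids <- as.character(caseid[del])
    if (length(deleted_caseids) > 0) {
      dq <- sample(del_quarters, length(deleted_caseids), replace = TRUE)
      deletions <- lapply(stats::setNames(del_quarters, del_quarters),
                          function(q) deleted_caseids[dq == q])
    }
  }

  retained_primaryid <- as.character(primaryid)
  if (nrow(duplicate_map) > 0) {
    m <- match(duplicate_map$caseid, as.character(caseid))
    retained_primaryid[m] <- duplicate_map$primaryid_latest
  }
  kept <- !(as.character(caseid) %in% deleted_caseids)

  # write quarterly files
  write_dialect <- function(tab, name, q) {
    sub <- tab[tab$primaryid %in% demo$primaryid[demo$quarter == q], ,
               drop = FALSE]
    sub$quarter <- NULL
    path <- file.path(dir, paste0(name, quarter_suffix(q), ".txt"))
    write_faers_table(sub, path)
    path
  }
  demo_out <- demo
  for (q in quarters) {
    dsub <- demo_out[demo_out$quarter == q, setdiff(names(demo_out), "quarter"),
                     drop = FALSE]
    write_faers_table(dsub, file.path(dir, paste0("DEMO", quarter_suffix(q), ".txt")))
    write_dialect(drug, "DRUG", q)
    write_dialect(reac, "REAC", q)
    write_dialect(ther, "THER", q)
    write_dialect(outc, "OUTC", q)
  }
  for (q in del_quarters) {
    writeLines(deletions[[q]],
               file.path(dir, paste0("DELETED", quarter_suffix(q), ".txt")))
  }

  # dictionary: every PT to its primary SOC, obsolete names as synonyms
  soc_idx <- ((seq_len(ne) - 1L) %% length(MEDDRA_SOCS)) + 1L
  dict <- data.frame(pt = event_pts, soc = MEDDRA_SOCS[soc_idx],
                     old_pt = sub("^EVENT_", "OLD_EVENT_", event_pts),
                     stringsAsFactors = FALSE)
  utils::write.table(dict, file.path(dir, "meddra.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  truth <- list(
    config = config,
    dir = dir,
    drug_names = drug_names,
    event_pts = event_pts,
    soc = stats::setNames(MEDDRA_SOCS[soc_idx], event_pts),
    E = E,
    lambda = lambda,
    counts = counts,
    planted_signals = ps,
    n_cases = n_cases,
    n_raw_reports = nrow(demo),
    duplicate_map = duplicate_map,
    deleted_caseids = deleted_caseids,
    retained_primaryids = sort(retained_primaryid[kept]),
    onset = data.frame(
      primaryid = retained_primaryid,
      caseid = as.character(caseid),
      onset_days = onset_days,
      reliable = onset_reliable,
      stringsAsFactors = FALSE)[kept, ],
    target_case_primaryids = sort(retained_primaryid[kept & drug_i == 1L]))
  class(truth) <- "faers_ground_truth"

  json <- truth[c("drug_names", "event_pts", "planted_signals", "n_cases",
                  "n_raw_reports", "deleted_caseids")]
  json$retained_n <- length(truth$retained_primaryids)
  jsonlite::write_json(json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(truth)
}

#' Planted signal pairs of a generated package
#'
#' @param truth A `faers_ground_truth` object from [generate_faers_package()].
#' @return Data frame with one row per planted pair: vocabulary indices,
#'   drug name, PT, and true relative risk.
#' @export
ground_truth_signal_set <- function(truth) {
  stopifnot(inherits(truth, "faers_ground_truth"))
  ps <- truth$planted_signals
  if (nrow(ps) == 0) {
    return(data.frame(drug = integer(0), event = integer(0), rr = numeric(0),
                      drugname = character(0), pt = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(drug = ps$drug, event = ps$event, rr = ps$rr,
             drugname = truth$drug_names[ps$drug],
             pt = truth$event_pts[ps$event],
             stringsAsFactors = FALSE)
}

# write one table in the "$"-delimited dialect (header line, NA as empty)
write_faers_table <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(tab), collapse = "$"), con)
  if (nrow(tab) > 0) {
    m <- as.matrix(tab)
    m[is.na(m)] <- ""
    writeLines(apply(m, 1, paste, collapse = "$"), con)
  }
  invisible(path)
}
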