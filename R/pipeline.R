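# One-call orchestration: ingest -> code -> cohort -> signals -> onset,
# with a run manifest mirroring the filtering funnel.

#' Configuration for a full pipeline run
#'
#' @param package_dir Directory holding the quarterly ASCII files.
#' @param quarters Quarter labels to analyse.
#' @param drug_synonyms Names the target drug is reported under.
#' @param dictionary Path to the PT-to-SOC dictionary TSV.
#' @param thresholds A [signal_thresholds()] list.
#' @param levels Signal levels to compute (`"PT"`, `"SOC"`).
#' @param top_n Rows kept in the ranked report tables.
#' @param tto_offset Day offset for the Weibull fit (see [weibull_fit()]).
#' @param seed Integer seed recorded in the manifest (the analysis itself
#'   is deterministic).
#' @param out_dir Output directory for report files.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(package_dir, quarters,
                       drug_synonyms = c("REGADENOSON", "LEXISCAN"),
                       dictionary = file.path(package_dir, "meddra.tsv"),
                       thresholds = signal_thresholds(),
                       levels = c("PT", "SOC"),
                       top_n = 50L, tto_offset = 0.5,
                       seed = 1L, out_dir = tempfile("faersignal_run")) {
  if (!dir.exists(package_dir)) {
    stop("package_dir does not exist: ", package_dir, call. = FALSE)
  }
  validate_quarter(quarters)
  for (q in quarters) {
    probe <- file.path(package_dir, paste0("DEMO", quarter_suffix(q), ".txt"))
    if (!file.exists(probe)) {
      stop("unknown quarter (no DEMO file found): ", q, call. = FALSE)
    }
  }
  if (!file.exists(dictionary)) {
    stop("dictionary file not found: ", dictionary, call. = FALSE)
  }
  cfg <- list(package_dir = package_dir, quarters = quarters,
              drug_synonyms = drug_synonyms, dictionary = dictionary,
              thresholds = thresholds, levels = match.arg(levels, several.ok = TRUE),
              top_n = as.integer(top_n), tto_offset = tto_offset,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

# fixed-precision TSV so identical runs are byte-identical
format_stats_tsv <- function(stats) {
  num <- vapply(stats, is.numeric, TRUE)
  for (cc in names(stats)[num]) {
    if (cc %in% c("a", "b", "c", "d", "n_total")) next
    stats[[cc]] <- sprintf("%.4f", stats[[cc]])
    stats[[cc]][stats[[cc]] == "NA"] <- ""
  }
  stats
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

#' Run the full analysis pipeline
#'
#' Executes ingest, dictionary coding, cohort selection, demographic
#' summary, PT- and SOC-level signal detection (all four methods, with the
#' gamma-Poisson-shrinker prior fitted on the full database's PT cells),
#' and the time-to-onset analysis. Writes `demographics.json`,
#' `signals_PT.tsv` / `signals_SOC.tsv`, `onset.json`, `onset_cdf.tsv`,
#' and `manifest.json` (input checksums, configuration echo, package
#' version, and record counts at every filtering step) to the output
#' directory. Any stage error aborts with the stage name; outputs of the
#' completed stages are preserved.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`store`, `cohort`,
#'   `demographics`, `signals`, `onset`, `weibull`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  store <- stage("ingest", ingest_faers(config$package_dir, config$quarters))
  map <- stage("coding", read_meddra(config$dictionary))
  cohort <- stage("cohort", select_primary_suspect(store, config$drug_synonyms))
  demographics <- stage("demographics", summarize_demographics(cohort))
  jsonlite::write_json(unclass(demographics),
                       file.path(config$out_dir, "demographics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  prior <- NULL
  signals <- list()
  for (lv in config$levels) {
    tabs <- stage(paste0("tables_", lv),
                  build_tables(cohort, store, level = lv, map = map))
    if (lv == "PT" && is.null(prior) && nrow(tabs) >= 2) {
      prior <- stage("gps_prior", fit_gps_prior(tabs$a, tabs$expected))
      jsonlite::write_json(unclass(prior),
                           file.path(config$out_dir, "gps_prior.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    st <- stage(paste0("signals_", lv),
                signal_stats(tabs, prior = prior, thresholds = config$thresholds))
    ranked <- rank_report(st, by = "frequency", top_n = config$top_n)
    write_tsv(format_stats_tsv(ranked),
              file.path(config$out_dir, paste0("signals_", lv, ".tsv")))
    signals[[lv]] <- st
  }

  onset <- stage("tto", compute_onset(cohort))
  wfit <- stage("weibull",
                weibull_fit(onset$records$onset_days[onset$records$reliable],
                            offset = config$tto_offset))
  jsonlite::write_json(
    list(n_linked = nrow(onset$records), n_reliable = onset$n_reliable,
         median = onset$median, iqr = onset$iqr, timeline = onset$timeline,
         weibull = unclass(wfit)),
    file.path(config$out_dir, "onset.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (onset$n_reliable > 0) {
    cdf <- cumulative_incidence(onset$records$onset_days[onset$records$reliable])
    cdf$cum_fraction <- sprintf("%.6f", cdf$cum_fraction)
    write_tsv(cdf, file.path(config$out_dir, "onset_cdf.tsv"))
  }

  inputs <- list.files(config$package_dir, pattern = "\\.(txt|tsv)$",
                       full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("faersignal")),
    seed = config$seed,
    config = list(package_dir = config$package_dir, quarters = config$quarters,
                  drug_synonyms = config$drug_synonyms,
                  dictionary = config$dictionary, levels = config$levels,
                  top_n = config$top_n, tto_offset = config$tto_offset,
                  thresholds = config$thresholds),
    input_checksums = as.list(tools::md5sum(inputs)),
    counts = list(
      raw_reports = unname(store$counts["raw_reports"]),
      unique_cases = unname(store$counts["unique_cases"]),
      removed_by_deletion = unname(store$counts["removed_by_deletion"]),
      retained_reports = unname(store$counts["retained_reports"]),
      cohort_reports = length(cohort$ids),
      cohort_event_pairs = demographics$n_events,
      onset_linked = nrow(onset$records),
      onset_reliable = onset$n_reliable))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(store = store, cohort = cohort, demographics = demographics,
                 signals = signals, prior = prior, onset = onset,
                 weibull = wfit, manifest = manifest))
}
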