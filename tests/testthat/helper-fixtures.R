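# Shared fixtures, generated once per test run.
#
# Two synthetic packages are reused across test files:
#  * fixture_null():    independence background (all non-planted relative
#                       risks exactly 1), 20,000 reports — the condition the
#                       planted-signal recovery properties are defined on.
#  * fixture_mixture(): gamma-mixture background, 5,000 reports — used for
#                       round-trip and pipeline checks.
# Seeds are fixed once; everything downstream is deterministic.

.fixture_env <- new.env(parent = emptyenv())

.make_fixture <- function(key, cfg) {
  if (is.null(.fixture_env[[key]])) {
    dir <- file.path(tempdir(), paste0("faersignal_fixture_", key))
    unlink(dir, recursive = TRUE)
    truth <- generate_faers_package(cfg, dir)
    store <- ingest_faers(dir, cfg$quarters)
    .fixture_env[[key]] <- list(cfg = cfg, dir = dir, truth = truth,
                                store = store)
  }
  .fixture_env[[key]]
}

fixture_null <- function() {
  .make_fixture("null", faers_sim_config(background_prior = NULL, seed = 101L))
}

fixture_mixture <- function() {
  .make_fixture("mixture", faers_sim_config(n_reports = 5000L, seed = 202L))
}

# hand-built case store from minimal table fragments; missing columns are
# filled so tests can state only what they are about
make_store <- function(demo = NULL, drug = NULL, reac = NULL,
                       ther = NULL, outc = NULL) {
  fill <- function(tab, cols) {
    if (is.null(tab)) {
      tab <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                           cols), stringsAsFactors = FALSE)
      return(tab)
    }
    for (cc in setdiff(cols, names(tab))) tab[[cc]] <- NA_character_
    for (cc in names(tab)) tab[[cc]] <- as.character(tab[[cc]])
    tab
  }
  store <- list(
    demo = fill(demo, c("primaryid", "caseid", "fda_dt", "event_dt", "age",
                        "age_cod", "sex", "occp_cod", "reporter_country")),
    drug = fill(drug, c("primaryid", "drug_seq", "role_cod", "drugname",
                        "prod_ai")),
    reac = fill(reac, c("primaryid", "pt")),
    ther = fill(ther, c("primaryid", "dsg_drug_seq", "start_dt", "end_dt")),
    outc = fill(outc, c("primaryid", "outc_cod")),
    counts = c(raw_reports = NA, unique_cases = NA, removed_by_deletion = NA,
               retained_reports = if (is.null(demo)) 0L else nrow(demo)))
  class(store) <- "faers_case_store"
  store
}

# a store of n single-PT reports for the target drug plus arbitrary demo
# overrides; convenient for descriptive-summary tests
make_target_store <- function(demo_fields) {
  n <- length(demo_fields$primaryid)
  demo <- data.frame(primaryid = demo_fields$primaryid,
                     caseid = demo_fields$primaryid,
                     fda_dt = demo_fields$fda_dt %||% rep("20240101", n),
                     stringsAsFactors = FALSE)
  for (nm in setdiff(names(demo_fields), c(names(demo), "ther", "outc"))) {
    demo[[nm]] <- demo_fields[[nm]]
  }
  drug <- data.frame(primaryid = demo$primaryid, drug_seq = "1",
                     role_cod = "PS", drugname = "REGADENOSON",
                     prod_ai = "REGADENOSON", stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = demo$primaryid, pt = "EVENT_0001",
                     stringsAsFactors = FALSE)
  make_store(demo = demo, drug = drug, reac = reac,
             ther = demo_fields$ther, outc = demo_fields$outc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# toy PT dictionary used across coding tests
toy_map <- function() {
  meddra_map(data.frame(
    pt = c("Nausea", "Vomiting", "Headache", "Dizziness", "Dyspnoea",
           "Chest pain", "Flushing", "Palpitations", "Seizure", "Bradycardia"),
    soc = c("Gastrointestinal disorders", "Gastrointestinal disorders",
            "Nervous system disorders", "Nervous system disorders",
            "Respiratory, thoracic and mediastinal disorders",
            "Cardiac disorders", "Vascular disorders", "Cardiac disorders",
            "Nervous system disorders", "Cardiac disorders"),
    old_pt = c("Feeling sick", NA, NA, NA, "Dyspnea", NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE), version = "toy-1")
}
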