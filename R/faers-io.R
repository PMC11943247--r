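# Reading FAERS-style quarterly ASCII packages and the FDA-recommended
# case deduplication.

FAERS_TABLES <- c("DEMO", "DRUG", "REAC", "THER", "OUTC")

# mandatory columns per table (matching is case-insensitive and tolerant of
# column order; extra columns are carried through)
faers_required_columns <- list(
  DEMO = c("primaryid", "caseid", "fda_dt"),
  DRUG = c("primaryid", "drug_seq", "role_cod", "drugname"),
  REAC = c("primaryid", "pt"),
  THER = c("primaryid", "dsg_drug_seq", "start_dt"),
  OUTC = c("primaryid", "outc_cod")
)

ROLE_CODES <- c("PS", "SS", "C", "I")
OUTCOME_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
SERIOUS_OUTCOMES <- c("DE", "LT", "HO", "DS", "CA", "RI")

#' Parse one FAERS-style quarterly ASCII file
#'
#' Reads a "$"-delimited table (first line a header of column names). Empty
#' fields become `NA`; no rows are dropped silently — lines whose field
#' count disagrees with the header are skipped, counted, and reported via
#' the `"malformed"` attribute.
#'
#' @param path Path to the file.
#' @param table_name One of `"DEMO"`, `"DRUG"`, `"REAC"`, `"THER"`,
#'   `"OUTC"`; selects the mandatory-column check.
#' @return A data frame (all columns character, names lower-cased) with
#'   attributes `malformed` (number of skipped lines) and `table`.
#' @export
parse_quarter <- function(path, table_name) {
  table_name <- toupper(table_name)
  if (!table_name %in% FAERS_TABLES) {
    stop("unknown table name: ", table_name, call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("cannot read file: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) {
    stop("empty file (no header line): ", path, call. = FALSE)
  }
  header <- tolower(strsplit(lines[1], "$", fixed = TRUE)[[1]])
  required <- faers_required_columns[[table_name]]
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0) {
    stop(sprintf("file %s is missing mandatory column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  ncol <- length(header)
  # field count from separator count (strsplit drops trailing empties)
  nf <- nchar(body) - nchar(gsub("$", "", body, fixed = TRUE)) + 1L
  bad <- nf != ncol
  fields <- strsplit(body, "$", fixed = TRUE)
  short <- !bad & lengths(fields) < ncol
  fields[short] <- lapply(fields[short],
                          function(f) c(f, rep("", ncol - length(f))))
  n_malformed <- sum(bad)
  if (n_malformed > 0) {
    fs_msg("%s: skipped %d malformed line(s)", basename(path), n_malformed)
  }
  fields <- fields[!bad]
  if (length(fields) == 0) {
    out <- as.data.frame(matrix(character(0), 0, ncol), stringsAsFactors = FALSE)
    names(out) <- header
  } else {
    m <- matrix(unlist(fields, use.names = FALSE), ncol = ncol, byrow = TRUE)
    m[m == ""] <- NA
    out <- as.data.frame(m, stringsAsFactors = FALSE)
    names(out) <- header
  }
  attr(out, "malformed") <- n_malformed
  attr(out, "table") <- table_name
  out
}

# read the deletion list (one CASEID per line) for one quarter; absent file
# means an empty list
parse_deletion_list <- function(path) {
  if (!file.exists(path)) return(character(0))
  x <- readLines(path, warn = FALSE)
  x[nzchar(trimws(x))]
}

#' Read a full quarterly package
#'
#' Reads every table of every requested quarter from `dir` (file names
#' `DEMO24Q3.txt` etc.) plus the deletion lists of quarters from 2019Q1 on.
#'
#' @param dir Package directory.
#' @param quarters Character vector of quarter labels, e.g. `"2024Q3"`.
#' @return A list of class `faers_package` with the five stacked tables
#'   (each carrying a `quarter` column), `deletions` (named list of CASEID
#'   vectors per quarter), and a `parse_log` data frame of per-file row and
#'   malformed-line counts.
#' @export
read_faers_package <- function(dir, quarters) {
  validate_quarter(quarters)
  tabs <- stats::setNames(vector("list", length(FAERS_TABLES)), FAERS_TABLES)
  log <- list()
  for (tb in FAERS_TABLES) {
    parts <- vector("list", length(quarters))
    for (i in seq_along(quarters)) {
      q <- quarters[i]
      path <- file.path(dir, paste0(tb, quarter_suffix(q), ".txt"))
      if (!file.exists(path)) {
        stop(sprintf("missing file for table %s, quarter %s: %s",
                     tb, q, path), call. = FALSE)
      }
      part <- parse_quarter(path, tb)
      if (nrow(part) > 0) part$quarter <- q else part$quarter <- character(0)
      parts[[i]] <- part
      log[[length(log) + 1L]] <- data.frame(
        table = tb, quarter = q, rows = nrow(part),
        malformed = attr(part, "malformed"), stringsAsFactors = FALSE)
    }
    # tolerate column drift across quarters: union of columns
    cols <- unique(unlist(lapply(parts, names)))
    parts <- lapply(parts, function(p) {
      for (cc in setdiff(cols, names(p))) p[[cc]] <- rep(NA_character_, nrow(p))
      p[cols]
    })
    tabs[[tb]] <- do.call(rbind, parts)
  }
  del_q <- quarters[has_deletion_list(quarters)]
  deletions <- lapply(stats::setNames(del_q, del_q), function(q) {
    parse_deletion_list(file.path(dir, paste0("DELETED", quarter_suffix(q), ".txt")))
  })
  structure(list(demo = tabs$DEMO, drug = tabs$DRUG, reac = tabs$REAC,
                 ther = tabs$THER, outc = tabs$OUTC,
                 deletions = deletions,
                 parse_log = do.call(rbind, log)),
            class = "faers_package")
}

#' FDA-recommended case deduplication
#'
#' Within each CASEID group the report with the latest FDA_DT is retained;
#' on FDA_DT ties the largest PRIMARYID wins. PRIMARYID comparison is
#' numeric when all ids parse as numbers, otherwise lexicographic (with a
#' warning). Partial FDA_DT values (YYYYMM / YYYY) are padded to their
#' earliest completion for ordering only.
#'
#' @param demo DEMO data frame with `primaryid`, `caseid`, `fda_dt`.
#' @return Character vector of retained PRIMARYIDs, one per CASEID.
#' @export
deduplicate <- function(demo) {
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(demo)))
  if (nrow(demo) == 0) return(character(0))
  if (any(is.na(demo$caseid)) || any(is.na(demo$primaryid)) ||
      any(is.na(demo$fda_dt))) {
    stop("deduplicate() requires caseid, primaryid and fda_dt on every record",
         call. = FALSE)
  }
  dt_key <- pad_partial_date(as.character(demo$fda_dt))
  pid <- as.character(demo$primaryid)
  pid_num <- suppressWarnings(as.numeric(pid))
  if (anyNA(pid_num)) {
    warning("non-numeric PRIMARYID(s); falling back to lexicographic comparison",
            call. = FALSE)
    ord <- order(demo$caseid, dt_key, pid)
  } else {
    ord <- order(demo$caseid, dt_key, pid_num)
  }
  # last row of each caseid group under (fda_dt, primaryid) ordering
  cid <- demo$caseid[ord]
  last_of_group <- c(cid[-1] != cid[-length(cid)], TRUE)
  sort(pid[ord][last_of_group])
}

#' Apply quarterly deletion lists to a retained case set
#'
#' Removes every retained report whose CASEID appears on any deletion list.
#' Unknown CASEIDs on the lists are ignored (counted in the message log).
#'
#' @param demo DEMO data frame (typically already filtered to the
#'   deduplicated reports).
#' @param deletions Named list of CASEID character vectors (one per
#'   quarter) or a single character vector.
#' @return The surviving subset of `demo`, with attribute `n_removed`.
#' @export
apply_deletions <- function(demo, deletions) {
  del <- unique(unlist(deletions, use.names = FALSE))
  if (length(del) == 0) {
    attr(demo, "n_removed") <- 0L
    return(demo)
  }
  hit <- demo$caseid %in% del
  unknown <- setdiff(del, demo$caseid)
  if (length(unknown) > 0) {
    fs_msg("deletion lists name %d CASEID(s) not present in the retained set",
           length(unknown))
  }
  out <- demo[!hit, , drop = FALSE]
  attr(out, "n_removed") <- sum(hit)
  fs_msg("deletion lists removed %d case(s)", sum(hit))
  out
}

#' Ingest a quarterly package into a deduplicated case store
#'
#' Runs [read_faers_package()], [deduplicate()] and [apply_deletions()],
#' then filters every table to the retained reports.
#'
#' @param dir Package directory.
#' @param quarters Quarter labels to read.
#' @return A list of class `faers_case_store`: the five filtered tables
#'   plus a `counts` funnel (raw reports, unique cases, removed by
#'   deletion, retained).
#' @export
ingest_faers <- function(dir, quarters) {
  pkg <- read_faers_package(dir, quarters)
  retained <- deduplicate(pkg$demo)
  demo_ret <- pkg$demo[pkg$demo$primaryid %in% retained, , drop = FALSE]
  demo_ret <- apply_deletions(demo_ret, pkg$deletions)
  n_deleted <- attr(demo_ret, "n_removed")
  ids <- demo_ret$primaryid
  store <- list(
    demo = demo_ret,
    drug = pkg$drug[pkg$drug$primaryid %in% ids, , drop = FALSE],
    reac = pkg$reac[pkg$reac$primaryid %in% ids, , drop = FALSE],
    ther = pkg$ther[pkg$ther$primaryid %in% ids, , drop = FALSE],
    outc = pkg$outc[pkg$outc$primaryid %in% ids, , drop = FALSE],
    parse_log = pkg$parse_log,
    counts = c(raw_reports = nrow(pkg$demo),
               unique_cases = length(retained),
               removed_by_deletion = n_deleted,
               retained_reports = nrow(demo_ret)))
  class(store) <- "faers_case_store"
  store
}

#' @export
print.faers_case_store <- function(x, ...) {
  cat("FAERS case store:", x$counts["retained_reports"], "retained reports\n")
  cat(sprintf("  raw %d | unique cases %d | deleted %d\n",
              x$counts["raw_reports"], x$counts["unique_cases"],
              x$counts["removed_by_deletion"]))
  invisible(x)
}
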