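#' @keywords internal
"_PACKAGE"

# Rounding used for all reported percentages: round-half-up, not the IEEE
# round-half-even of base::round(), so printed percentages match the usual
# table convention (e.g. 0.125 -> 0.13 at 2 digits).
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a category count within a total
#'
#' Computes `100 * count / total` rounded half-up to two decimals, the
#' convention used throughout descriptive report tables.
#'
#' @param count Numeric vector of category counts.
#' @param total Positive total the counts are taken from.
#' @param digits Number of decimals (default 2).
#' @return Numeric vector of percentages.
#' @examples
#' report_percentage(1573, 4408)
#' @export
report_percentage <- function(count, total, digits = 2) {
  stopifnot(is.numeric(count), is.numeric(total), total > 0)
  round_half_up(100 * count / total, digits)
}

# ---- dates -----------------------------------------------------------------
# FAERS dates are 8-digit YYYYMMDD strings, but partial dates (YYYYMM, YYYY)
# occur; helpers below never invent precision beyond padding for ordering.

is_full_date <- function(x) {
  !is.na(x) & grepl("^[0-9]{8}$", x)
}

is_partial_date <- function(x) {
  !is.na(x) & grepl("^[0-9]{4}$|^[0-9]{6}$", x)
}

# Pad partial dates to their earliest completion (month/day -> 01); used for
# deterministic ordering only, never for interval arithmetic.
pad_partial_date <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & grepl("^[0-9]{4}$", x)] <-
    paste0(x[!is.na(x) & grepl("^[0-9]{4}$", x)], "0101")
  x[!is.na(x) & grepl("^[0-9]{6}$", x)] <-
    paste0(x[!is.na(x) & grepl("^[0-9]{6}$", x)], "01")
  x
}

ymd_to_date <- function(x) {
  out <- rep(as.Date(NA), length(x))
  ok <- is_full_date(x)
  out[ok] <- as.Date(x[ok], format = "%Y%m%d")
  out
}

date_to_ymd <- function(d) {
  format(d, "%Y%m%d")
}

# ---- quarters --------------------------------------------------------------

quarter_pattern <- "^([0-9]{4})Q([1-4])$"

validate_quarter <- function(q) {
  bad <- !grepl(quarter_pattern, q)
  if (any(bad)) {
    stop("invalid quarter label(s): ", paste(q[bad], collapse = ", "),
         " (expected e.g. \"2019Q1\")", call. = FALSE)
  }
  invisible(q)
}

quarter_year <- function(q) as.integer(sub(quarter_pattern, "\\1", q))
quarter_num  <- function(q) as.integer(sub(quarter_pattern, "\\2", q))

# sortable numeric key: 2019Q1 -> 8077
quarter_key <- function(q) quarter_year(q) * 4L + quarter_num(q) - 1L

# "2024Q3" -> "24Q3", the suffix used in FAERS quarterly file names
quarter_suffix <- function(q) {
  paste0(substr(q, 3, 4), "Q", quarter_num(q))
}

quarter_start <- function(q) {
  as.Date(sprintf("%d-%02d-01", quarter_year(q), (quarter_num(q) - 1L) * 3L + 1L))
}

quarter_end <- function(q) {
  m <- quarter_num(q) * 3L
  y <- quarter_year(q)
  if (length(q) > 1L) return(as.Date(mapply(function(yy, mm) {
    as.character(seq(as.Date(sprintf("%d-%02d-01", yy, mm)), by = "month",
                     length.out = 2)[2] - 1)
  }, y, m)))
  seq(as.Date(sprintf("%d-%02d-01", y, m)), by = "month", length.out = 2)[2] - 1
}

# deletion lists exist from this quarter on
DELETION_LIST_FROM <- "2019Q1"

has_deletion_list <- function(q) {
  quarter_key(q) >= quarter_key(DELETION_LIST_FROM)
}

# ---- logging ---------------------------------------------------------------

fs_msg <- function(...) {
  if (isTRUE(getOption("faersignal.verbose", FALSE))) {
    message(sprintf(...))
  }
  invisible(NULL)
}
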