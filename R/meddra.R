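# PT -> SOC coding via a user-supplied dictionary table.
#
# MedDRA itself is licensed and cannot be shipped; the package defines a
# plain TSV schema (columns pt, soc, optional old_pt) so tests run on a toy
# dictionary and licensed users export their own copy. Each PT maps to
# exactly one primary SOC; obsolete PT names are renamed to their current
# PT before coding.

#' Build a PT-to-SOC coding map
#'
#' @param entries Data frame with columns `pt` and `soc` (one primary SOC
#'   per PT) and optionally `old_pt` (obsolete name renamed to `pt`).
#' @param version Dictionary version label, e.g. `"27.1"`.
#' @return Object of class `meddra_map`.
#' @export
meddra_map <- function(entries, version = "unversioned") {
  stopifnot(is.data.frame(entries), all(c("pt", "soc") %in% names(entries)))
  entries$pt <- as.character(entries$pt)
  entries$soc <- as.character(entries$soc)
  if (anyDuplicated(entries$pt)) {
    dup <- unique(entries$pt[duplicated(entries$pt)])
    stop("PT(s) mapped to more than one primary SOC: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  synonyms <- character(0)
  if ("old_pt" %in% names(entries)) {
    has_old <- !is.na(entries$old_pt) & nzchar(entries$old_pt)
    synonyms <- stats::setNames(entries$pt[has_old],
                                as.character(entries$old_pt[has_old]))
    if (anyDuplicated(names(synonyms))) {
      stop("an obsolete PT renames to more than one current PT", call. = FALSE)
    }
  }
  map <- structure(
    list(soc = stats::setNames(entries$soc, entries$pt),
         synonyms = synonyms,
         version = version),
    class = "meddra_map")
  # synonym closure must terminate (no rename cycles)
  resolve_synonyms(names(synonyms), map)
  map
}

#' Read a dictionary TSV (columns pt, soc, optional old_pt)
#'
#' @param path Path to a tab-separated UTF-8 file.
#' @param version Version label attached to the map.
#' @return A `meddra_map`.
#' @export
read_meddra <- function(path, version = "unversioned") {
  if (!file.exists(path)) stop("dictionary file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  names(tab) <- tolower(names(tab))
  meddra_map(tab, version = version)
}

# follow rename chains to their terminal PT; error on a cycle
resolve_synonyms <- function(pts, map) {
  out <- as.character(pts)
  for (i in seq_along(out)) {
    seen <- character(0)
    cur <- out[i]
    while (cur %in% names(map$synonyms)) {
      if (cur %in% seen) {
        stop("synonym cycle involving PT: ", cur, call. = FALSE)
      }
      seen <- c(seen, cur)
      cur <- unname(map$synonyms[[cur]])
    }
    out[i] <- cur
  }
  out
}

#' Recode PTs to their current names
#'
#' Applies the dictionary's obsolete-name renames (following chains to the
#' terminal name). PTs absent from the dictionary are returned unchanged
#' and collected into the `"uncoded"` attribute rather than dropped.
#'
#' @param pt Character vector of preferred terms.
#' @param map A [meddra_map()].
#' @return Character vector of current PTs, with attribute `uncoded`
#'   listing the distinct terms the dictionary does not know.
#' @export
recode_pt <- function(pt, map) {
  stopifnot(inherits(map, "meddra_map"))
  out <- resolve_synonyms(pt, map)
  known <- is.na(out) | out %in% names(map$soc)
  attr(out, "uncoded") <- sort(unique(out[!known]))
  out
}

#' Primary system organ class of a PT
#'
#' @param pt Character vector of preferred terms (recoded first via the
#'   dictionary's synonyms).
#' @param map A [meddra_map()].
#' @return Character vector of SOC names; `"uncoded"` for PTs the
#'   dictionary does not know.
#' @export
soc_of <- function(pt, map) {
  stopifnot(inherits(map, "meddra_map"))
  cur <- resolve_synonyms(pt, map)
  out <- unname(map$soc[cur])
  out[is.na(out)] <- "uncoded"
  out[is.na(cur)] <- "uncoded"
  out
}
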