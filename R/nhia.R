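# Surname-based Hispanic ethnicity assignment (NHIA).
#
# The algorithm classifies surnames into five tiers of Hispanic association
# against a Spanish-surname reference list; only the "heavily" tier codes a
# patient Hispanic, and a race-code exclusion list removes candidates who
# identify as Asian, American Indian, Aleutian, Eskimo, Filipino, Pacific
# Islander, or Hawaiian.  The reference table is pluggable: a small
# synthetic fixture ships with the package for tests and examples, and a
# full user-supplied list can be loaded from a two-column delimited file.

surname_categories <- function() {
  c("HEAVILY", "GENERALLY", "MODERATELY", "OCCASIONALLY", "RARELY")
}

nhia_excluded_race_codes <- function() {
  c("Asian", "AmericanIndian", "Aleutian", "Eskimo", "Filipino",
    "PacificIslander", "Hawaiian")
}

#' Normalize a surname for table lookup
#'
#' Uppercases, strips accents/diacritics, trims surrounding whitespace and
#' collapses internal runs of whitespace to single spaces; hyphens and
#' internal spaces are preserved (compound surnames match as whole strings).
#'
#' @param raw character vector of surnames; empty strings are an error.
#' @return normalized character vector.
#' @examples
#' normalize_surname(" garcía ")  # "GARCIA"
#' @export
normalize_surname <- function(raw) {
  if (any(is.na(raw) | !nzchar(trimws(raw)))) {
    stop("surname must be a nonempty string")
  }
  x <- trimws(raw)
  x <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
  x <- gsub("[`'^\"~]", "", x)   # iconv TRANSLIT leftovers
  x <- gsub("[[:space:]]+", " ", x)
  toupper(x)
}

#' Load a Spanish-surname reference table
#'
#' Reads a two-column delimited file (SURNAME, CATEGORY; tab or comma
#' separated, optional header) into a lookup table.  Categories must be one
#' of HEAVILY, GENERALLY, MODERATELY, OCCASIONALLY, RARELY.  With no
#' \code{path}, the synthetic fixture shipped with the package is loaded:
#' a ~50-name toy list spanning all five tiers, sufficient for tests but
#' NOT a substitute for the full census surname list.
#'
#' @param path optional path to a user-supplied surname list.
#' @return a named character vector (class \code{surname_table}) mapping
#'   normalized surname to category.
#' @export
load_surname_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "spanish_surnames_synthetic.tsv",
                        package = "psadens", mustWork = TRUE)
  }
  first <- readLines(path, n = 50L)
  first <- first[!grepl("^\\s*(#|$)", first)][1]
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("surname", "category"),
                           comment.char = "#", quote = "\"")
  if (toupper(raw$surname[1]) == "SURNAME") raw <- raw[-1, , drop = FALSE]
  cat_up <- toupper(trimws(raw$category))
  bad <- !cat_up %in% surname_categories()
  if (any(bad)) {
    stop("unknown surname category: ",
         paste(unique(raw$category[bad]), collapse = ", "),
         " (valid: ", paste(surname_categories(), collapse = ", "), ")")
  }
  keys <- normalize_surname(raw$surname)
  if (anyDuplicated(keys)) {
    stop("duplicate surnames after normalization: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  tab <- stats::setNames(cat_up, keys)
  class(tab) <- "surname_table"
  tab
}

#' Classify a surname against the reference table
#'
#' Exact whole-string lookup after normalization; surnames not in the table
#' return "ABSENT".
#'
#' @param surname character vector of surnames.
#' @param table a \code{surname_table} from \code{\link{load_surname_table}}.
#' @return character vector of categories ("HEAVILY", ..., "RARELY",
#'   "ABSENT").
#' @export
classify_surname <- function(surname, table) {
  stopifnot(inherits(table, "surname_table"))
  key <- normalize_surname(surname)
  out <- unclass(table)[key]
  out[is.na(out)] <- "ABSENT"
  unname(out)
}

#' Assign Hispanic/Non-Hispanic ethnicity from surname and race code
#'
#' Implements the surname rule set: a surname in the "heavily" Hispanic tier
#' codes the patient HISPANIC; every other tier (and surnames absent from
#' the table) codes NON_HISPANIC; and patients whose race code is in the
#' exclusion set (Asian, American Indian, Aleutian, Eskimo, Filipino,
#' Pacific Islander, Hawaiian) are coded NON_HISPANIC regardless of
#' surname.  Records with a missing surname are coded NON_HISPANIC with a
#' warning.
#'
#' @param cohort a \code{psa_cohort} (or data.frame with \code{surname} and
#'   \code{race_code} columns).
#' @param table a \code{surname_table}; default loads the shipped synthetic
#'   fixture.
#' @return the cohort with an \code{ethnicity_nhia} column ("HISPANIC" /
#'   "NON_HISPANIC") appended.
#' @examples
#' tab <- load_surname_table()
#' df <- data.frame(surname = "Garcia", race_code = "White")
#' assign_ethnicity(df, tab)$ethnicity_nhia
#' @export
assign_ethnicity <- function(cohort, table = load_surname_table()) {
  x <- as.data.frame(cohort)
  stopifnot(all(c("surname", "race_code") %in% names(x)))
  n <- nrow(x)
  eth <- rep("NON_HISPANIC", n)
  missing_sn <- is.na(x$surname) | !nzchar(trimws(as.character(x$surname)))
  if (any(missing_sn)) {
    warning(sum(missing_sn),
            " record(s) lack a surname; coded NON_HISPANIC")
  }
  if (any(!missing_sn)) {
    cat_i <- classify_surname(x$surname[!missing_sn], table)
    excluded <- x$race_code[!missing_sn] %in% nhia_excluded_race_codes()
    eth[!missing_sn][cat_i == "HEAVILY" & !excluded] <- "HISPANIC"
  }
  x$ethnicity_nhia <- eth
  if (inherits(cohort, "psa_cohort")) {
    attr(x, "provenance") <- attr(cohort, "provenance")
    class(x) <- class(cohort)
  }
  x
}
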