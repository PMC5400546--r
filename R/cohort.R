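# Cohort data model and CSV interchange.
#
# A cohort is a data.frame with one validated row per patient and class
# "psa_cohort".  Units are SI throughout: height in meters, weight in kg,
# PSA in ng/mL, prostate weight (without seminal vesicles) in grams, tumor
# volume in cm^3, tumor grid counts in mm^2.

#' @rdname read_cohort
#' @export
race_ethnicity_levels <- function() {
  c("NHW", "NHB", "HISPANIC_LATINO", "OTHER", "UNKNOWN")
}

#' @rdname read_cohort
#' @export
race_code_levels <- function() {
  c("White", "Black", "Asian", "AmericanIndian", "Aleutian", "Eskimo",
    "Filipino", "PacificIslander", "Hawaiian", "Other", "Unknown")
}

#' @rdname read_cohort
#' @export
institution_levels <- function() c("UM", "JHU", "OTHER")

# Canonical column order of the interchange CSV.
cohort_columns <- function() {
  c("id", "age", "race_ethnicity", "race_code", "surname", "institution",
    "height", "weight", "psa", "prostate_weight", "tumor_grid_mm2",
    "tumor_volume")
}

#' Construct a validated patient cohort
#'
#' Builds a \code{psa_cohort} from per-patient vectors, applying the data
#' model invariants: positive prostate weight, nonnegative PSA, age in
#' [18, 100], positive height/weight where present, unique ids, and (for
#' analysis records) at least one of \code{tumor_grid_mm2} /
#' \code{tumor_volume}.
#'
#' @param data data.frame with (a subset of) the cohort columns; missing
#'   optional columns (\code{surname}, \code{tumor_grid_mm2},
#'   \code{tumor_volume}, \code{height}, \code{weight}) are filled with NA.
#' @param provenance free-text label describing where the records came from.
#' @param strict if TRUE (default), any invalid row is an error; if FALSE,
#'   invalid rows are dropped with a warning and kept (with reasons) in
#'   \code{attr(x, "invalid")}.
#' @param require_tumor if TRUE (default), records must carry a tumor
#'   measurement (grid count or volume) to be valid.
#' @return a data.frame of class \code{psa_cohort}.
#' @export
as_cohort <- function(data, provenance = "unspecified", strict = TRUE,
                      require_tumor = TRUE) {
  stopifnot(is.data.frame(data))
  need <- c("id", "age", "race_ethnicity", "race_code", "institution",
            "psa", "prostate_weight")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("cohort is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (opt in setdiff(cohort_columns(), names(data))) data[[opt]] <- NA
  data <- data[, cohort_columns()]

  blank_to_na <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
    x
  }
  data$id <- as.character(data$id)
  data$surname <- blank_to_na(data$surname)
  data$race_ethnicity <- blank_to_na(data$race_ethnicity)
  data$race_code <- blank_to_na(data$race_code)
  data$institution <- blank_to_na(data$institution)
  for (num in c("age", "height", "weight", "psa", "prostate_weight",
                "tumor_grid_mm2", "tumor_volume")) {
    data[[num]] <- as.numeric(data[[num]])
  }
  data$race_ethnicity <- as.character(data$race_ethnicity)
  data$race_ethnicity[is.na(data$race_ethnicity)] <- "UNKNOWN"
  data$race_code <- as.character(data$race_code)
  data$race_code[is.na(data$race_code)] <- "Unknown"
  data$institution <- as.character(data$institution)

  reasons <- validate_cohort_rows(data, require_tumor = require_tumor)
  bad <- nchar(reasons) > 0
  if (any(bad)) {
    msg <- paste0("row ", which(bad), " (id=", data$id[which(bad)], "): ",
                  reasons[bad])
    if (strict) {
      stop("invalid patient record(s):\n  ", paste(msg, collapse = "\n  "))
    }
    warning(sum(bad), " invalid record(s) dropped:\n  ",
            paste(utils::head(msg, 10), collapse = "\n  "))
    invalid <- data[bad, , drop = FALSE]
    invalid$reason <- reasons[bad]
    data <- data[!bad, , drop = FALSE]
    attr(data, "invalid") <- invalid
  }
  if (anyDuplicated(data$id)) stop("patient ids are not unique")
  rownames(data) <- NULL
  attr(data, "provenance") <- provenance
  class(data) <- c("psa_cohort", "data.frame")
  data
}

# One reason string per row; "" means valid.
validate_cohort_rows <- function(data, require_tumor = TRUE) {
  n <- nrow(data)
  reasons <- character(n)
  add <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reasons[cond] <<- ifelse(nchar(reasons[cond]) > 0,
                             paste(reasons[cond], why, sep = "; "), why)
  }
  add(is.na(data$id) | !nzchar(data$id), "missing id")
  add(is.na(data$age), "missing age")
  add(data$age < 18 | data$age > 100, "age outside [18, 100]")
  add(is.na(data$psa), "missing psa")
  add(data$psa < 0, "psa < 0")
  add(is.na(data$prostate_weight), "missing prostate_weight")
  add(data$prostate_weight <= 0, "prostate_weight <= 0")
  add(!is.na(data$height) & data$height <= 0, "height <= 0")
  add(!is.na(data$weight) & data$weight <= 0, "weight <= 0")
  add(!data$race_ethnicity %in% race_ethnicity_levels(),
      "unknown race_ethnicity code")
  add(!data$race_code %in% race_code_levels(), "unknown race_code")
  add(!data$institution %in% institution_levels(), "unknown institution")
  add(!is.na(data$tumor_grid_mm2) & data$tumor_grid_mm2 < 0,
      "tumor_grid_mm2 < 0")
  add(!is.na(data$tumor_volume) & data$tumor_volume < 0, "tumor_volume < 0")
  if (require_tumor) {
    add(is.na(data$tumor_grid_mm2) & is.na(data$tumor_volume),
        "no tumor measurement (grid count or volume)")
  }
  reasons
}

#' Read and write patient cohorts as CSV
#'
#' The interchange format is a plain CSV with one documented header:
#' \code{id, age, race_ethnicity, race_code, surname, institution, height,
#' weight, psa, prostate_weight, tumor_grid_mm2, tumor_volume}.  Height is in
#' meters, weight in kg, PSA in ng/mL, prostate weight in grams, tumor volume
#' in cm^3.  \code{read_cohort(write_cohort(x))} is the identity on valid
#' cohorts.
#'
#' @param path file path of the cohort CSV.
#' @param strict,require_tumor validation flags, see \code{\link{as_cohort}}.
#' @param cohort a \code{psa_cohort}.
#' @return \code{read_cohort}: a \code{psa_cohort}; \code{write_cohort}:
#'   (invisibly) the path written.
#' @examples
#' cohort <- generate_cohort(cohort_preset("table1_default", seed = 1))
#' tmp <- tempfile(fileext = ".csv")
#' write_cohort(cohort, tmp)
#' identical(dim(read_cohort(tmp)), dim(cohort))
#' @export
read_cohort <- function(path, strict = TRUE, require_tumor = TRUE) {
  if (!file.exists(path)) stop("cohort file does not exist: ", path)
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  classes <- stats::setNames(rep(NA_character_, length(header)), header)
  classes[intersect(c("id", "surname", "race_ethnicity", "race_code",
                      "institution"), header)] <- "character"
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = classes)
  as_cohort(raw, provenance = path, strict = strict,
            require_tumor = require_tumor)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "psa_cohort") || is.data.frame(cohort))
  out <- as.data.frame(cohort)[, cohort_columns()]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.psa_cohort <- function(x, ...) {
  cat(sprintf("<psa_cohort> %d patients (%s)\n", nrow(x),
              attr(x, "provenance")))
  tab <- table(factor(x$race_ethnicity, levels = race_ethnicity_levels()))
  tab <- tab[tab > 0]
  cat("  race/ethnicity:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  PSA median %.2f ng/mL, prostate weight median %.1f g\n",
              stats::median(x$psa), stats::median(x$prostate_weight)))
  invisible(x)
}

#' Load an analysis or cohort configuration file
#'
#' Reads a YAML (or JSON-as-YAML) configuration, validates the keys against
#' the documented set and fills defaults.  Two kinds are supported:
#' \code{kind: cohort} maps onto \code{\link{cohort_config}} (the synthetic
#' generator) and \code{kind: analysis} onto \code{\link{analysis_config}}.
#'
#' @param path path to a YAML config file.  An empty file yields all
#'   defaults for the requested kind.
#' @param kind "cohort" or "analysis"; overridden by a \code{kind} key in
#'   the file.
#' @return a \code{cohort_config} or \code{analysis_config} object.
#' @export
load_config <- function(path, kind = c("cohort", "analysis")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("config file does not exist: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.null(vals$kind)) {
    kind <- match.arg(vals$kind, c("cohort", "analysis"))
    vals$kind <- NULL
  }
  # YAML maps arrive as lists; flatten scalar maps into named vectors for
  # the keys that expect them (list-valued keys keep their structure)
  keep_list <- c("pw_range", "bmi_probs", "bmi_ranges")
  vals <- lapply(stats::setNames(names(vals), names(vals)), function(k) {
    v <- vals[[k]]
    if (is.list(v) && !k %in% keep_list &&
        all(vapply(v, function(e) is.numeric(e) && length(e) == 1, TRUE))) {
      unlist(v)
    } else v
  })
  target <- if (kind == "cohort") cohort_config else analysis_config
  valid <- names(formals(target))
  unknown <- setdiff(names(vals), valid)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "\n  valid keys: ", paste(valid, collapse = ", "))
  }
  do.call(target, vals)
}
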