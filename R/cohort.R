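#' Patient cohorts: reading, writing and validation
#'
#' A cohort is a data frame with one row per ED visit and columns
#' `id`, `age`, `sex`, `cause`, `avpu`, `sbp`, `dbp`, `hr`, `rr`, `bt`,
#' `spo2`, `arrival_arrest`, `transferred_out`, `ed_result`,
#' `hospital_result`. Vital signs are real-valued and may be missing (`NA`);
#' categorical fields are closed enumerations and are validated strictly:
#' `sex` in {male, female}, `cause` in {disease, non_disease}, `avpu` in
#' {A, V, P, U}, `ed_result` in {discharged, admitted, died, transferred,
#' hopeless_discharge}, `hospital_result` in {discharged, died,
#' hopeless_discharge, not_admitted}.
#'
#' @name cohort
NULL

cohort_columns <- function() {
  c("id", "age", "sex", "cause", "avpu", "sbp", "dbp", "hr", "rr", "bt",
    "spo2", "arrival_arrest", "transferred_out", "ed_result",
    "hospital_result")
}

cohort_enums <- function() {
  list(sex = c("male", "female"),
       cause = c("disease", "non_disease"),
       avpu = c("A", "V", "P", "U"),
       ed_result = c("discharged", "admitted", "died", "transferred",
                     "hopeless_discharge"),
       hospital_result = c("discharged", "died", "hopeless_discharge",
                           "not_admitted"))
}

#' Read a patient cohort from CSV
#'
#' Reads a UTF-8, comma-separated file with a header row. `schema` maps the
#' canonical column names to the file's column names, so files with
#' different headers can be ingested without rewriting them. Vital-sign
#' cells that do not parse as numbers become `NA` with a warning; empty
#' categorical cells become `NA`; any other unknown categorical value is an
#' error naming the row and field.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping canonical names (see
#'   [cohort]) to the file's column names; defaults to the identity mapping.
#' @return a validated cohort data frame.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) == 0) stop("empty input: ", path, " has no data rows")
  cols <- cohort_columns()
  if (is.null(schema)) schema <- stats::setNames(cols, cols)
  missing_map <- setdiff(cols, names(schema))
  if (length(missing_map)) {
    schema[missing_map] <- missing_map
  }
  absent <- setdiff(unname(schema[cols]), names(raw))
  if (length(absent)) {
    stop("missing mandatory column(s) in ", path, ": ",
         paste(absent, collapse = ", "))
  }
  df <- stats::setNames(raw[unname(schema[cols])], cols)

  num_cols <- c("age", "sbp", "dbp", "hr", "rr", "bt", "spo2")
  for (nm in num_cols) {
    txt <- trimws(df[[nm]])
    txt[txt == ""] <- NA_character_
    val <- suppressWarnings(as.numeric(txt))
    bad <- !is.na(txt) & is.na(val)
    if (any(bad)) {
      warning("column '", nm, "': ", sum(bad),
              " unparseable value(s) treated as missing (rows ",
              paste(utils::head(which(bad), 5), collapse = ", "), ")")
    }
    neg <- !is.na(val) & (val < 0 | !is.finite(val))
    if (any(neg)) {
      stop("column '", nm, "': negative or non-finite value at row ",
           which(neg)[1])
    }
    df[[nm]] <- val
  }
  for (nm in c("arrival_arrest", "transferred_out")) {
    txt <- tolower(trimws(df[[nm]]))
    val <- rep(NA, length(txt))
    val[txt %in% c("true", "1", "yes")] <- TRUE
    val[txt %in% c("false", "0", "no", "")] <- FALSE
    if (anyNA(val)) {
      stop("column '", nm, "': unrecognized boolean at row ",
           which(is.na(val))[1])
    }
    df[[nm]] <- val
  }
  enums <- cohort_enums()
  for (nm in names(enums)) {
    txt <- trimws(df[[nm]])
    txt[txt == ""] <- NA_character_
    bad <- !is.na(txt) & !txt %in% enums[[nm]]
    if (any(bad)) {
      stop("invalid value '", txt[which(bad)[1]], "' for field '", nm,
           "' at row ", which(bad)[1])
    }
    df[[nm]] <- txt
  }
  validate_cohort(df)
}

#' @rdname read_cohort
#' @param cohort a cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  extra <- setdiff(names(cohort), cohort_columns())
  out <- cohort[c(cohort_columns(), extra)]
  utils::write.csv(out, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

validate_cohort <- function(df) {
  # structural invariant: not_admitted iff not admitted to hospital
  adm <- !is.na(df$ed_result) & df$ed_result == "admitted"
  hosp <- df$hospital_result
  bad <- !is.na(hosp) & ((hosp == "not_admitted") == adm)
  if (any(bad)) {
    stop("hospital_result inconsistent with ed_result at row ",
         which(bad)[1],
         " (hospital_result must be 'not_admitted' iff ed_result is not",
         " 'admitted')")
  }
  df
}

#' Derive the binary mortality outcome
#'
#' A visit counts as a death if the patient died in the ED or in hospital
#' after admission, or was discharged with essentially no chance of recovery
#' (hopeless discharge, from either setting); every other visit is a
#' survival.
#'
#' @param cohort a cohort data frame (or any data frame with `ed_result` and
#'   `hospital_result` columns).
#' @return character vector, `"died"` or `"survived"`, one per row.
#' @export
derive_outcome <- function(cohort) {
  er <- cohort$ed_result
  hr <- cohort$hospital_result
  if (anyNA(er) || anyNA(hr)) {
    stop("ed_result/hospital_result must be populated to derive the outcome")
  }
  died <- er %in% c("died", "hopeless_discharge") |
    hr %in% c("died", "hopeless_discharge")
  ifelse(died, "died", "survived")
}

as_died <- function(outcomes) {
  if (is.logical(outcomes)) return(outcomes)
  if (is.character(outcomes) || is.factor(outcomes)) {
    x <- as.character(outcomes)
    bad <- !x %in% c("died", "survived")
    if (any(bad)) stop("outcome must be 'died' or 'survived'")
    return(x == "died")
  }
  stop("outcomes must be logical (died) or 'died'/'survived'")
}

#' Apply the exclusion cascade
#'
#' Removes records that cannot be scored or benchmarked: children under 15,
#' patients transferred out of the ED, arrivals in cardiac arrest, records
#' missing a required variable (sbp, hr, rr, spo2, avpu, cause, sex — body
#' temperature and diastolic pressure are carried but never required, since
#' the final model excludes them), and implausible measurements (blood
#' pressure above 300 mmHg, pulse oximetry above 100%). Each excluded record
#' is tallied under the FIRST failing reason in the fixed precedence order
#' `under_15` -> `transfer_out` -> `arrival_arrest` -> `missing_variable` ->
#' `implausible_value`, so the report partitions the input exactly.
#'
#' @param cohort a cohort data frame.
#' @return a list with `retained` (the surviving rows) and `report`, an
#'   `edies_exclusion_report` with `n_input`, `n_retained` and
#'   `counts_by_reason`.
#' @export
apply_exclusions <- function(cohort) {
  n <- nrow(cohort)
  reasons <- c("under_15", "transfer_out", "arrival_arrest",
               "missing_variable", "implausible_value")
  required <- c("sbp", "hr", "rr", "spo2", "avpu", "cause", "sex")
  missing_any <- Reduce(`|`, lapply(required, function(nm) is.na(cohort[[nm]])))
  # an unrecorded age cannot clear the age gate; treat it as a missing variable
  missing_any <- missing_any | is.na(cohort$age)
  implaus <- (!is.na(cohort$sbp) & cohort$sbp > 300) |
    (!is.na(cohort$dbp) & cohort$dbp > 300) |
    (!is.na(cohort$spo2) & cohort$spo2 > 100)

  reason <- rep(NA_character_, n)
  pick <- function(cond, code) {
    sel <- is.na(reason) & cond
    reason[sel] <<- code
  }
  pick(!is.na(cohort$age) & cohort$age < 15, "under_15")
  pick(cohort$transferred_out, "transfer_out")
  pick(cohort$arrival_arrest, "arrival_arrest")
  pick(missing_any, "missing_variable")
  pick(implaus, "implausible_value")

  keep <- is.na(reason)
  counts <- vapply(reasons, function(r) sum(reason == r, na.rm = TRUE), 1L)
  report <- structure(
    list(n_input = n, n_retained = sum(keep),
         counts_by_reason = as.list(counts)),
    class = "edies_exclusion_report")
  list(retained = cohort[keep, , drop = FALSE], report = report)
}

#' @export
print.edies_exclusion_report <- function(x, ...) {
  cat("Exclusion report:", x$n_input, "records in,", x$n_retained,
      "retained\n")
  for (nm in names(x$counts_by_reason)) {
    cat(sprintf("  %-18s %d\n", nm, x$counts_by_reason[[nm]]))
  }
  invisible(x)
}

#' @rdname apply_exclusions
#' @param report an `edies_exclusion_report`.
#' @param path output file path.
#' @export
write_exclusion_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
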