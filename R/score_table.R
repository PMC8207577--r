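#' Score tables: bin-based integer point scores
#'
#' A score table maps each scored item either from a closed set of categories
#' (categorical items) or from a real-valued measurement via ordered bins with
#' inclusive upper bounds (binned items) to a non-negative integer point
#' score. The total score of a record is the sum of its item scores.
#'
#' @param items named list of score items, each created by
#'   [score_item_categorical()] or [score_item_binned()].
#' @return an object of class `edies_score_table`.
#' @seealso [builtin_edies()] for the published table.
#' @export
score_table <- function(items) {
  stopifnot(is.list(items), length(items) > 0, !is.null(names(items)))
  for (nm in names(items)) {
    it <- items[[nm]]
    if (!inherits(it, "edies_score_item")) {
      stop("item '", nm, "' is not a score item")
    }
  }
  structure(list(items = items), class = "edies_score_table")
}

#' @rdname score_table
#' @param scores for categorical items, a named numeric vector mapping each
#'   category to its score; for binned items, the score of each bin.
#' @export
score_item_categorical <- function(scores) {
  stopifnot(is.numeric(scores), !is.null(names(scores)), all(scores >= 0))
  structure(list(kind = "categorical", scores = scores),
            class = "edies_score_item")
}

#' @rdname score_table
#' @param upper strictly increasing inclusive upper bounds of the bins.
#' @param above score assigned to values greater than the last upper bound;
#'   `NA` means such values are an error (used by the strict respiratory-rate
#'   mode, see [builtin_edies()]).
#' @param gap optional numeric length-2 interval `(lo, hi]` of values that are
#'   rejected rather than scored (strict mode only).
#' @export
score_item_binned <- function(upper, scores, above, gap = NULL) {
  stopifnot(is.numeric(upper), length(upper) == length(scores),
            all(diff(upper) > 0), all(scores >= 0), length(above) == 1L)
  structure(list(kind = "binned", upper = upper, scores = scores,
                 above = above, gap = gap),
            class = "edies_score_item")
}

#' The published ED initial-evaluation score table
#'
#' Returns the eight-item integer score table exactly as published: sex
#' (male 1, female 0), cause of visit (disease 2, other 0), AVPU (A 0, V 2,
#' P 3, U 7), and inclusive-upper-bound bins for age, systolic blood
#' pressure, heart rate, respiratory rate and pulse oximetry. Totals range
#' from 0 to 39.
#'
#' The printed respiratory-rate bins leave values in (33, 35] unmapped
#' (`<= 33` scores 1, the next printed bin starts above 35). By default the
#' final bin is read as `> 33 -> 2` so the bins are contiguous; with
#' `strict_rr = TRUE` the printed gap is kept and scoring a respiratory rate
#' in (33, 35] is an error.
#'
#' @param strict_rr keep the printed respiratory-rate gap (33, 35] as an
#'   error region instead of closing it.
#' @return an `edies_score_table` with items `sex`, `cause`, `avpu`, `age`,
#'   `sbp`, `hr`, `rr`, `spo2`.
#' @examples
#' tab <- builtin_edies()
#' max_attainable_score(tab)  # 39
#' @export
builtin_edies <- function(strict_rr = FALSE) {
  rr <- if (strict_rr) {
    score_item_binned(upper = c(5, 7, 13, 20, 33),
                      scores = c(6, 3, 1, 0, 1), above = 2, gap = c(33, 35))
  } else {
    score_item_binned(upper = c(5, 7, 13, 20, 33),
                      scores = c(6, 3, 1, 0, 1), above = 2)
  }
  score_table(list(
    sex  = score_item_categorical(c(male = 1, female = 0)),
    cause = score_item_categorical(c(disease = 2, non_disease = 0)),
    avpu = score_item_categorical(c(A = 0, V = 2, P = 3, U = 7)),
    age  = score_item_binned(upper = c(39, 70, 78, 85, 93),
                             scores = c(0, 1, 2, 3, 4), above = 5),
    sbp  = score_item_binned(
      upper = c(21, 26, 33, 39, 46, 52, 60, 67, 78, 90, 106, 202),
      scores = c(11, 10, 9, 8, 7, 6, 5, 4, 3, 2, 1, 0), above = 1),
    hr   = score_item_binned(upper = c(42, 54, 87, 120, 140),
                             scores = c(2, 1, 0, 1, 2), above = 3),
    rr   = rr,
    spo2 = score_item_binned(upper = c(82, 86, 91, 96),
                             scores = c(4, 3, 2, 1), above = 0)
  ))
}

# score one item for a vector of values; NA propagates as error upstream
score_item_lookup <- function(item, values) {
  if (item$kind == "categorical") {
    out <- item$scores[as.character(values)]
    if (anyNA(out)) {
      bad <- unique(as.character(values)[is.na(out)])
      stop("unknown category value(s): ", paste(bad, collapse = ", "))
    }
    unname(out)
  } else {
    if (!is.null(item$gap)) {
      in_gap <- !is.na(values) & values > item$gap[1] & values <= item$gap[2]
      if (any(in_gap)) {
        stop(sprintf("value(s) in unmapped bin gap (%g, %g]: %s",
                     item$gap[1], item$gap[2],
                     paste(utils::head(values[in_gap], 5), collapse = ", ")))
      }
    }
    idx <- findInterval(values, item$upper, left.open = TRUE) + 1L
    all_scores <- c(item$scores, item$above)
    out <- all_scores[idx]
    if (anyNA(out[!is.na(values)])) stop("value above last bin is unmapped")
    out
  }
}

#' Score patient records
#'
#' `score_record()` returns the total integer score of a single record;
#' `score_cohort()` scores every row of a cohort data frame at once. Bin
#' lookup is `value <= upper_bound` with inclusive upper bounds. Records must
#' have passed [apply_exclusions()] so that every required item is present;
#' a missing required field is an error naming the item.
#'
#' @param table an `edies_score_table`.
#' @param record a single patient record (one-row data frame or named list).
#' @param cohort a cohort data frame (see [read_cohort()]).
#' @return `score_record()`: a single integer. `score_cohort()`: an integer
#'   vector, one score per row.
#' @examples
#' rec <- list(sex = "male", cause = "disease", avpu = "A", age = 30,
#'             sbp = 120, hr = 80, rr = 16, spo2 = 99)
#' score_record(builtin_edies(), rec)  # 3
#' @export
score_record <- function(table, record) {
  stopifnot(inherits(table, "edies_score_table"))
  total <- 0
  for (nm in names(table$items)) {
    val <- record[[nm]]
    if (is.null(val) || length(val) != 1L || is.na(val)) {
      stop("cannot score record: item '", nm, "' is absent")
    }
    total <- total + score_item_lookup(table$items[[nm]], val)
  }
  as.integer(total)
}

#' @rdname score_record
#' @export
score_cohort <- function(table, cohort) {
  stopifnot(inherits(table, "edies_score_table"), is.data.frame(cohort))
  total <- numeric(nrow(cohort))
  for (nm in names(table$items)) {
    if (!nm %in% names(cohort)) stop("cohort lacks column '", nm, "'")
    vals <- cohort[[nm]]
    if (anyNA(vals)) {
      stop("cannot score cohort: item '", nm, "' missing in ",
           sum(is.na(vals)), " record(s)")
    }
    total <- total + score_item_lookup(table$items[[nm]], vals)
  }
  as.integer(total)
}

# enumerate the attainable per-item score values (used by the synthetic
# generator's composition sampler and by max/min attainability checks)
item_score_values <- function(item) {
  v <- if (item$kind == "categorical") item$scores else c(item$scores, item$above)
  sort(unique(as.integer(v[!is.na(v)])))
}

#' Attainable score range of a table
#'
#' Exhaustively combines each item's attainable scores.
#'
#' @param table an `edies_score_table`.
#' @return a single integer.
#' @export
max_attainable_score <- function(table) {
  sum(vapply(table$items, function(it) max(item_score_values(it)), 1L))
}

#' @rdname max_attainable_score
#' @export
min_attainable_score <- function(table) {
  sum(vapply(table$items, function(it) min(item_score_values(it)), 1L))
}

#' Serialize score tables
#'
#' Score tables round-trip through JSON so user-supplied tables can be kept
#' under version control and reports can reference them by checksum.
#'
#' @param table an `edies_score_table`.
#' @param path file path.
#' @return `read_score_table()` returns an `edies_score_table`;
#'   `write_score_table()` returns `path` invisibly.
#' @export
write_score_table <- function(table, path) {
  items <- lapply(table$items, function(it) {
    if (it$kind == "categorical") {
      list(kind = "categorical", scores = as.list(it$scores))
    } else {
      out <- list(kind = "binned", upper = it$upper, scores = it$scores,
                  above = it$above)
      if (!is.null(it$gap)) out$gap <- it$gap
      out
    }
  })
  jsonlite::write_json(items, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  items <- lapply(raw, function(it) {
    if (identical(it$kind, "categorical")) {
      score_item_categorical(unlist(it$scores))
    } else {
      score_item_binned(it$upper, it$scores, it$above, gap = it$gap)
    }
  })
  score_table(items)
}
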