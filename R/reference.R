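#' Reference tables: predicted survival and severity strata
#'
#' A reference table carries (i) the predicted probability of survival Ps for
#' each score value, with a grouped top bucket for the highest scores, and
#' (ii) the severity strata used to standardize the W statistic, each with a
#' reference count and fraction. The two groupings are independent: Ps
#' buckets default to single scores 0..21 plus ">= 22", strata default to
#' single scores 0..16 plus {17-18} and {>= 19}.
#'
#' @param ps data frame with columns `score_min`, `score_max` (Inf for the
#'   open top bucket) and `ps` in [0, 1]; buckets must be disjoint, ordered
#'   and contiguous. `ps` may be NA for a bucket observed empty during
#'   derivation; using such a bucket downstream is an error.
#' @param strata data frame with columns `label`, `score_min`, `score_max`
#'   (Inf for the open top stratum), `count` and `fraction`; fractions must
#'   sum to 1 within `1e-3` (printed fixtures) and are renormalized exactly
#'   when built from counts.
#' @param nonmonotone_warning flag set when the Ps sequence is not
#'   monotonically decreasing in score (true for the built-in fixture, whose
#'   printed Ps at score 14 breaks monotonicity; it is stored as printed, not
#'   smoothed).
#' @return an object of class `edies_reference`.
#' @seealso [builtin_reference()], [derive_reference()]
#' @export
reference_table <- function(ps, strata, nonmonotone_warning = NA) {
  stopifnot(is.data.frame(ps),
            all(c("score_min", "score_max", "ps") %in% names(ps)),
            is.data.frame(strata),
            all(c("label", "score_min", "score_max", "count", "fraction")
                %in% names(strata)))
  stopifnot(all(ps$score_min <= ps$score_max),
            all(diff(ps$score_min) > 0),
            all(is.na(ps$ps) | (ps$ps >= 0 & ps$ps <= 1)))
  if (abs(sum(strata$fraction) - 1) > 1e-3) {
    stop("stratum fractions must sum to 1 (got ", sum(strata$fraction), ")")
  }
  if (is.na(nonmonotone_warning)) {
    d <- diff(ps$ps[!is.na(ps$ps)])
    nonmonotone_warning <- any(d > 0)
  }
  structure(list(ps = ps, strata = strata,
                 nonmonotone_warning = nonmonotone_warning),
            class = "edies_reference")
}

#' The published reference fixture
#'
#' Predicted survival probability per score and severity-stratum counts and
#' fractions from the published construction dataset (N = 1,836,577). Values
#' are stored exactly as printed. The printed Ps at score 14 (0.95177) breaks
#' the otherwise monotone decline between scores 13 and 15; it is kept
#' as printed and flagged via `nonmonotone_warning`.
#'
#' @return an `edies_reference`.
#' @examples
#' ref <- builtin_reference()
#' sum(ref$strata$count)  # 1836577
#' @export
builtin_reference <- function() {
  ps_vals <- c(1.00000, 0.99973, 0.99935, 0.99842, 0.99511, 0.98673,
               0.97252, 0.95153, 0.92339, 0.88886, 0.84543, 0.79589,
               0.75019, 0.69430, 0.95177, 0.59030, 0.52206, 0.49335,
               0.46640, 0.44246, 0.40063, 0.37624, 0.24753)
  ps <- data.frame(score_min = 0:22,
                   score_max = c(0:21, Inf),
                   ps = ps_vals)
  counts <- c(27248, 106039, 198739, 356919, 393640, 284345, 177881,
              110766, 68128, 41147, 25930, 16462, 10616, 6670, 4319,
              2763, 1768, 1871, 1326)
  strata <- data.frame(
    label = c(as.character(0:16), "17-18", ">=19"),
    score_min = c(0:16, 17, 19),
    score_max = c(0:16, 18, Inf),
    count = counts,
    fraction = counts / sum(counts)
  )
  reference_table(ps, strata, nonmonotone_warning = TRUE)
}

# map scores to Ps-bucket index / Ps value / stratum index; -1 => no bucket
ps_bucket_index <- function(reference, scores) {
  findInterval(scores, reference$ps$score_min)
}

#' Look up predicted survival for score values
#'
#' @param reference an `edies_reference`.
#' @param scores integer score vector.
#' @return numeric vector of survival probabilities.
#' @export
ps_lookup <- function(reference, scores) {
  idx <- ps_bucket_index(reference, scores)
  bad <- idx < 1 | scores > reference$ps$score_max[pmax(idx, 1L)]
  if (any(bad)) {
    stop("score(s) outside reference Ps domain: ",
         paste(utils::head(unique(scores[bad]), 5), collapse = ", "))
  }
  p <- reference$ps$ps[idx]
  if (anyNA(p)) {
    stop("Ps bucket(s) with no derived probability needed for score(s): ",
         paste(utils::head(unique(scores[is.na(p)]), 5), collapse = ", "))
  }
  p
}

#' @rdname ps_lookup
#' @return `stratum_lookup()`: integer index into `reference$strata` rows.
#' @export
stratum_lookup <- function(reference, scores) {
  idx <- findInterval(scores, reference$strata$score_min)
  bad <- idx < 1 | scores > reference$strata$score_max[pmax(idx, 1L)]
  if (any(bad)) {
    stop("score(s) outside reference stratum domain: ",
         paste(utils::head(unique(scores[bad]), 5), collapse = ", "))
  }
  idx
}

#' Derive a reference table from a scored cohort
#'
#' Ps per score bucket is the observed survivor proportion in that bucket;
#' stratum fractions are the cohort's stratum proportions. A Ps bucket with
#' no records is recorded as `NA` with a warning (never interpolated);
#' downstream expected-survivor computation fails if such a bucket is needed.
#'
#' @param scores integer score per record.
#' @param outcomes outcome per record: `"survived"`/`"died"` character vector
#'   or logical `TRUE` for died.
#' @param ps_buckets list of integer vectors of member scores per Ps bucket;
#'   an attribute-free open top bucket is expressed by its lowest member with
#'   `open_top = TRUE`. Defaults to single scores `0..top-1` plus an open
#'   `>= top` bucket matching the built-in layout.
#' @param strata_spec list of integer vectors of member scores per stratum;
#'   the last may be open-ended. Defaults to the built-in layout
#'   ({0}, ..., {16}, {17,18}, {>= 19}).
#' @return an `edies_reference` whose stratum counts come from the cohort.
#' @export
derive_reference <- function(scores, outcomes,
                             ps_buckets = NULL, strata_spec = NULL) {
  stopifnot(length(scores) > 0, length(scores) == length(outcomes))
  died <- as_died(outcomes)
  if (is.null(ps_buckets)) ps_buckets <- c(as.list(0:21), list(22:39))
  if (is.null(strata_spec)) {
    strata_spec <- c(as.list(0:16), list(17:18), list(19:39))
  }
  mins <- vapply(ps_buckets, min, 1)
  maxs <- vapply(ps_buckets, max, 1)
  maxs[length(maxs)] <- Inf
  idx <- findInterval(scores, mins)
  if (any(idx < 1)) stop("score below first Ps bucket")
  n_b <- tabulate(idx, nbins = length(ps_buckets))
  surv_b <- tabulate(idx[!died], nbins = length(ps_buckets))
  ps_vec <- ifelse(n_b > 0, surv_b / pmax(n_b, 1L), NA_real_)
  if (any(n_b == 0)) {
    warning(sum(n_b == 0), " empty Ps bucket(s); Ps recorded as NA")
  }
  ps <- data.frame(score_min = mins, score_max = maxs, ps = ps_vec)

  smins <- vapply(strata_spec, min, 1)
  smaxs <- vapply(strata_spec, max, 1)
  smaxs[length(smaxs)] <- Inf
  sidx <- findInterval(scores, smins)
  cnt <- tabulate(sidx, nbins = length(strata_spec))
  lab <- vapply(strata_spec, function(g) {
    if (length(g) == 1) as.character(g)
    else paste0(min(g), "-", max(g))
  }, "")
  lab[length(lab)] <- paste0(">=", smins[length(smins)])
  strata <- data.frame(label = lab, score_min = smins, score_max = smaxs,
                       count = cnt, fraction = cnt / sum(cnt))
  reference_table(ps, strata)
}

#' Serialize reference tables
#'
#' @param reference an `edies_reference`.
#' @param path file path.
#' @export
write_reference <- function(reference, path) {
  jsonlite::write_json(
    list(ps = reference$ps, strata = reference$strata,
         nonmonotone_warning = reference$nonmonotone_warning),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ps <- as.data.frame(raw$ps)
  strata <- as.data.frame(raw$strata)
  ps$score_max[is.na(ps$score_max)] <- Inf
  strata$score_max[is.na(strata$score_max)] <- Inf
  reference_table(ps, strata, nonmonotone_warning = raw$nonmonotone_warning)
}
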