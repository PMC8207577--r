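#' Generator specification for synthetic ED populations
#'
#' The generator emulates the published construction population: the score
#' distribution defaults to the printed per-score reference counts, with the
#' grouped rows (17-18, >= 19) split uniformly across member scores (19..22,
#' one per remaining survival bucket), and score-conditional survival
#' defaults to the printed predicted-survival curve. It makes no claim of
#' clinical realism beyond these marginals.
#'
#' @param n number of records.
#' @param score_distribution named numeric vector of fractions per score
#'   (names are score values); defaults to the expanded reference
#'   distribution.
#' @param survival_curve named numeric vector of survival probability per
#'   score; defaults to the built-in reference Ps.
#' @param emit_vitals generate full patient records whose vitals score back
#'   to the assigned value (slower); otherwise emit (score, outcome) pairs.
#' @param exclusion_noise fraction of extra records appended per exclusion
#'   rule (see [inject_exclusions()]).
#' @param seed RNG seed.
#' @return an object of class `edies_generator_spec`.
#' @export
generator_spec <- function(n, score_distribution = NULL,
                           survival_curve = NULL, emit_vitals = FALSE,
                           exclusion_noise = 0, seed = 1L) {
  if (is.null(score_distribution)) {
    score_distribution <- default_score_distribution()
  }
  if (is.null(survival_curve)) survival_curve <- default_survival_curve()
  stopifnot(abs(sum(score_distribution) - 1) < 1e-9,
            all(survival_curve >= 0 & survival_curve <= 1),
            exclusion_noise >= 0)
  if (!all(names(score_distribution) %in% names(survival_curve))) {
    stop("every score in the distribution needs a survival probability")
  }
  structure(list(n = as.integer(n),
                 score_distribution = score_distribution,
                 survival_curve = survival_curve,
                 emit_vitals = isTRUE(emit_vitals),
                 exclusion_noise = exclusion_noise,
                 seed = as.integer(seed)),
            class = "edies_generator_spec")
}

#' @rdname generator_spec
#' @export
default_score_distribution <- function() {
  ref <- builtin_reference()
  cnt <- ref$strata$count
  # singles 0..16 as printed; 17-18 split in half; >=19 split over 19..22
  n_s <- c(cnt[1:17], rep(cnt[18] / 2, 2), rep(cnt[19] / 4, 4))
  stats::setNames(n_s / sum(n_s), 0:22)
}

#' @rdname generator_spec
#' @export
default_survival_curve <- function() {
  ref <- builtin_reference()
  stats::setNames(ref$ps$ps, ref$ps$score_min)
}

#' Generate a synthetic population
#'
#' Per-score record counts are the largest-remainder apportionment of
#' `n * score_distribution` (so the empirical score distribution matches the
#' request exactly, not merely in expectation); each record's death is an
#' independent Bernoulli draw at `1 - Ps(score)`. With `emit_vitals`, every
#' record receives demographics and vital signs constructed so that
#' [score_record()] with the built-in table returns exactly the assigned
#' score; body temperature and diastolic pressure are uninformative fillers
#' (the scoring model ignores them).
#'
#' @param spec an [generator_spec()].
#' @param table score table used when `emit_vitals = TRUE`.
#' @return with `emit_vitals = FALSE`, a data frame with columns `score` and
#'   `outcome`; otherwise a full cohort data frame (see [cohort]) with the
#'   assigned `score` and `outcome` appended.
#' @export
generate_population <- function(spec, table = builtin_edies()) {
  stopifnot(inherits(spec, "edies_generator_spec"))
  set.seed(spec$seed)
  scores_lev <- as.integer(names(spec$score_distribution))
  counts <- largest_remainder(spec$n, spec$score_distribution)
  score <- rep(scores_lev, counts)
  ps <- spec$survival_curve[as.character(score)]
  died <- stats::runif(length(score)) >= ps
  out <- data.frame(score = score,
                    outcome = ifelse(died, "died", "survived"))
  if (!spec$emit_vitals) {
    if (spec$exclusion_noise > 0) {
      stop("exclusion noise requires emit_vitals = TRUE")
    }
    return(out)
  }
  vit <- vitals_for_scores(score, table)
  cohort <- data.frame(
    id = sprintf("syn%07d", seq_along(score)),
    vit,
    dbp = round(stats::rnorm(length(score), 80, 10), 1),
    bt = round(stats::rnorm(length(score), 36.6, 0.4), 1),
    arrival_arrest = FALSE,
    transferred_out = FALSE,
    ed_result = ifelse(died, "died", "discharged"),
    hospital_result = "not_admitted",
    score = score,
    outcome = out$outcome
  )
  cohort <- cohort[c(cohort_columns(), "score", "outcome")]
  if (spec$exclusion_noise > 0) {
    cohort <- inject_exclusions(cohort, spec)
  }
  cohort
}

# attainable score values per item, in table order
table_score_sets <- function(table) {
  lapply(table$items, item_score_values)
}

# DP table: counts[[i]][t+1] = number of item-score compositions of items
# i..m summing to t
composition_counts <- function(sets) {
  m <- length(sets)
  maxs <- vapply(sets, max, 1L)
  tot <- sum(maxs)
  counts <- vector("list", m + 1)
  counts[[m + 1]] <- c(1, numeric(tot))  # empty suffix: only sum 0
  for (i in m:1) {
    nxt <- counts[[i + 1]]
    cur <- numeric(tot + 1)
    for (v in sets[[i]]) {
      cur[(v + 1):(tot + 1)] <- cur[(v + 1):(tot + 1)] +
        nxt[1:(tot + 1 - v)]
    }
    counts[[i]] <- cur
  }
  counts
}

#' Construct vitals that score to a given total
#'
#' Chooses an item-score composition summing to `target` uniformly at random
#' among all feasible compositions (counted by dynamic programming over the
#' items), then, for each item, picks uniformly among the bins carrying that
#' item score and draws a value uniformly inside the bin. Open-ended bins
#' use finite physiologic caps (age 110, SBP 300, HR 250, RR 60, SpO2 100).
#'
#' @param target integer total score, within the table's attainable range.
#' @param table an `edies_score_table`.
#' @param seed optional RNG seed.
#' @return named list of field values (`sex`, `cause`, `avpu`, `age`, `sbp`,
#'   `hr`, `rr`, `spo2`).
#' @export
vitals_for_score <- function(target, table = builtin_edies(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as.list(vitals_for_scores(target, table)[1, ])
}

# vectorized core: one row per requested score
vitals_for_scores <- function(targets, table) {
  sets <- table_score_sets(table)
  counts <- composition_counts(sets)
  tot <- length(counts[[1]]) - 1L
  if (any(targets < 0 | targets > tot)) stop("target score out of range")
  if (any(counts[[1]][targets + 1] == 0)) {
    stop("no feasible item-score composition for requested score")
  }
  m <- length(sets)
  nrec <- length(targets)
  comp <- matrix(0L, nrow = nrec, ncol = m,
                 dimnames = list(NULL, names(sets)))
  rem <- targets
  for (i in seq_len(m)) {
    vs <- sets[[i]]
    nxt <- counts[[i + 1]]
    # P(item i takes value v | remaining sum) ~ count of suffix completions
    w <- vapply(vs, function(v) {
      ok <- rem - v >= 0
      out <- numeric(nrec)
      out[ok] <- nxt[rem[ok] - v + 1]
      out
    }, numeric(nrec))
    if (nrec == 1) w <- matrix(w, nrow = 1)
    u <- stats::runif(nrec) * rowSums(w)
    cum <- w
    for (cidx in seq_len(ncol(w))[-1]) {
      cum[, cidx] <- cum[, cidx - 1] + w[, cidx]
    }
    pick <- max.col(cum >= u, ties.method = "first")
    comp[, i] <- vs[pick]
    rem <- rem - comp[, i]
  }
  stopifnot(all(rem == 0))
  fields <- lapply(seq_len(m), function(i) {
    draw_item_values(table$items[[i]], names(sets)[i], comp[, i])
  })
  names(fields) <- names(sets)
  as.data.frame(fields, stringsAsFactors = FALSE)
}

# finite caps for the open-ended top bins, and lower bounds for first bins
vital_caps <- function() {
  list(age = c(lo = 15, hi = 110), sbp = c(lo = 0, hi = 300),
       hr = c(lo = 0, hi = 250), rr = c(lo = 0, hi = 60),
       spo2 = c(lo = 0, hi = 100))
}

# given per-record item scores, draw concrete field values that map back
draw_item_values <- function(item, name, scores_wanted) {
  n <- length(scores_wanted)
  if (item$kind == "categorical") {
    out <- character(n)
    for (v in unique(scores_wanted)) {
      cats <- names(item$scores)[item$scores == v]
      sel <- scores_wanted == v
      out[sel] <- cats[sample.int(length(cats), sum(sel), replace = TRUE)]
    }
    return(out)
  }
  caps <- vital_caps()[[name]]
  lows <- c(caps[["lo"]], item$upper)
  highs <- c(item$upper, caps[["hi"]])
  all_scores <- c(item$scores, item$above)
  out <- numeric(n)
  for (v in unique(scores_wanted)) {
    bins <- which(!is.na(all_scores) & all_scores == v)
    sel <- scores_wanted == v
    b <- bins[sample.int(length(bins), sum(sel), replace = TRUE)]
    # uniform in (low, high]; round to 1 decimal staying inside the bin
    val <- lows[b] + (highs[b] - lows[b]) * stats::runif(sum(sel))
    val <- pmin(highs[b], pmax(lows[b] + 0.05, round(val, 1)))
    out[sel] <- val
  }
  out
}

#' Append records violating each exclusion rule
#'
#' For each exclusion rule (age under 15, transfer out, arrival arrest,
#' missing variable, SBP above 300, SpO2 above 100) appends
#' `round(exclusion_noise * n)` otherwise-valid records corrupted to violate
#' exactly that rule, then shuffles the cohort with the spec's seed. The
#' injected record ids carry an `excl_` prefix so bookkeeping against
#' [apply_exclusions()] is exact.
#'
#' @param cohort a cohort data frame (as from [generate_population()] with
#'   vitals).
#' @param spec an [generator_spec()] with `exclusion_noise > 0`.
#' @return the augmented, shuffled cohort; the injection log (id, rule) is
#'   attached as attribute `injection_log`.
#' @export
inject_exclusions <- function(cohort, spec) {
  noise <- spec$exclusion_noise
  if (noise == 0) return(cohort)
  n_each <- round(noise * nrow(cohort))
  if (n_each == 0) return(cohort)
  rules <- c("under_15", "transfer_out", "arrival_arrest",
             "missing_variable", "sbp_implausible", "spo2_implausible")
  set.seed(spec$seed + 1L)
  base_scores <- sample(as.integer(names(spec$score_distribution)),
                        n_each * length(rules), replace = TRUE,
                        prob = spec$score_distribution)
  vit <- vitals_for_scores(base_scores, builtin_edies())
  extra <- data.frame(
    id = sprintf("excl_%s_%05d", rep(rules, each = n_each),
                 seq_along(base_scores)),
    vit,
    dbp = 80, bt = 36.6,
    arrival_arrest = FALSE, transferred_out = FALSE,
    ed_result = "discharged", hospital_result = "not_admitted",
    score = NA_integer_, outcome = NA_character_
  )
  rule_of <- rep(rules, each = n_each)
  extra$age[rule_of == "under_15"] <- 10
  extra$transferred_out[rule_of == "transfer_out"] <- TRUE
  extra$arrival_arrest[rule_of == "arrival_arrest"] <- TRUE
  extra$sbp[rule_of == "missing_variable"] <- NA_real_
  extra$sbp[rule_of == "sbp_implausible"] <- 310
  extra$spo2[rule_of == "spo2_implausible"] <- 101
  extra <- extra[c(cohort_columns(), "score", "outcome")]
  out <- rbind(cohort, extra)
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "injection_log") <- data.frame(id = extra$id, rule = rule_of)
  out
}
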