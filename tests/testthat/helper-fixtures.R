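# Shared fixtures built in code.

# a single fully populated, scoreable record
valid_record <- function(...) {
  rec <- list(id = "r1", age = 30, sex = "male", cause = "disease",
              avpu = "A", sbp = 120, dbp = 80, hr = 80, rr = 16, bt = 36.6,
              spo2 = 99, arrival_arrest = FALSE, transferred_out = FALSE,
              ed_result = "discharged", hospital_result = "not_admitted")
  mods <- list(...)
  rec[names(mods)] <- mods
  rec
}

# a cohort data frame from a list of records
cohort_of <- function(...) {
  recs <- list(...)
  do.call(rbind, lapply(recs, function(r) {
    as.data.frame(r[!vapply(r, is.null, TRUE)], stringsAsFactors = FALSE)
  }))
}

# write a cohort CSV and return its path
write_temp_cohort <- function(cohort) {
  path <- tempfile(fileext = ".csv")
  edies::write_cohort(cohort, path)
  path
}

# independent brute-force standardized W for tiny cohorts: per-record
# summation, no grouping tricks
brute_ws <- function(scores, outcomes, reference) {
  died <- outcomes == "died"
  k <- nrow(reference$strata)
  # reference fractions renormalized over the populated strata (part of the
  # statistic's definition when strata are empty)
  populated <- vapply(seq_len(k), function(j) {
    any(scores >= reference$strata$score_min[j] &
          scores <= reference$strata$score_max[j])
  }, TRUE)
  f_all <- reference$strata$fraction
  f_all[!populated] <- 0
  f_all <- f_all / sum(f_all)
  ws <- 0
  var_acc <- 0
  for (j in seq_len(k)) {
    lo <- reference$strata$score_min[j]
    hi <- reference$strata$score_max[j]
    members <- which(scores >= lo & scores <= hi)
    if (length(members) == 0) next
    n_j <- length(members)
    O_j <- sum(!died[members])
    E_j <- 0
    v_j <- 0
    for (i in members) {
      p <- reference$ps$ps[reference$ps$score_min <= scores[i] &
                             reference$ps$score_max >= scores[i]]
      E_j <- E_j + p
      v_j <- v_j + p * (1 - p)
    }
    f_j <- f_all[j]
    ws <- ws + f_j * 100 * (O_j - E_j) / n_j
    var_acc <- var_acc + f_j^2 * (100 / n_j)^2 * v_j
  }
  list(ws = ws, se = sqrt(var_acc))
}

# brute-force AUROC over all (death, survivor) pairs
brute_auroc <- function(scores, outcomes) {
  d <- scores[outcomes == "died"]
  s <- scores[outcomes == "survived"]
  tot <- 0
  for (x in d) for (y in s) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(d) * length(s))
}

# brute-force enumeration of item-score compositions of the built-in table
brute_composition_count <- function(target, table = edies::builtin_edies()) {
  sets <- lapply(table$items, function(it) {
    v <- if (it$kind == "categorical") it$scores else c(it$scores, it$above)
    sort(unique(as.integer(v[!is.na(v)])))
  })
  grids <- expand.grid(sets)
  sum(rowSums(grids) == target)
}
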