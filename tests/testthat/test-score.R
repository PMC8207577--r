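test_that("built-in table scores reference records correctly", {
  tab <- builtin_edies()
  cases <- list(
    # record fields, expected total
    list(valid_record(), 3),  # male 1 + disease 2, all vitals in 0 bins
    list(valid_record(sex = "female", cause = "non_disease", age = 20), 0),
    list(valid_record(avpu = "U", age = 95, sbp = 20, hr = 150, rr = 4,
                      spo2 = 80), 39),  # the unique maximal record
    list(valid_record(sbp = 130), 3),   # SBP 130 sits in the wide 0 bin
    list(valid_record(sbp = 250), 4),   # very high SBP scores 1 again
    list(valid_record(age = 70), 4),    # inclusive upper bound: 70 -> 1
    list(valid_record(age = 70.5), 5),  # just above the bound -> 2
    list(valid_record(hr = 42), 5),     # hr <= 42 -> 2
    list(valid_record(spo2 = 96), 4)    # spo2 <= 96 -> 1
  )
  for (cs in cases) {
    expect_equal(score_record(tab, cs[[1]]), cs[[2]])
  }
  # vectorized scoring agrees with per-record scoring
  cohort <- do.call(cohort_of, lapply(cases, `[[`, 1))
  expect_equal(score_cohort(tab, cohort),
               vapply(cases, function(cs) as.integer(cs[[2]]), 1L))
})

test_that("attainable range of the built-in table is 0..39", {
  tab <- builtin_edies()
  expect_identical(max_attainable_score(tab), 39L)
  expect_identical(min_attainable_score(tab), 0L)
})

test_that("scoring a record with a missing required item names the item", {
  expect_error(score_record(builtin_edies(), valid_record(rr = NA)), "rr")
})

test_that("strict respiratory-rate mode errors inside the printed gap", {
  strict <- builtin_edies(strict_rr = TRUE)
  default <- builtin_edies()
  expect_error(score_record(strict, valid_record(rr = 34)), "gap")
  expect_equal(score_record(default, valid_record(rr = 34)), 5)  # 3 + rr 2
  # outside the gap the two modes agree
  for (rr in c(5, 13, 33, 36, 50)) {
    expect_equal(score_record(strict, valid_record(rr = rr)),
                 score_record(default, valid_record(rr = rr)))
  }
})

test_that("score tables round-trip through JSON", {
  tab <- builtin_edies(strict_rr = TRUE)
  path <- tempfile(fileext = ".json")
  write_score_table(tab, path)
  back <- read_score_table(path)
  set.seed(5)
  for (i in 1:20) {
    rec <- vitals_for_score(sample(0:39, 1), builtin_edies())
    expect_equal(score_record(back, c(rec, list())),
                 score_record(builtin_edies(), rec))
  }
})

test_that("built-in reference matches its printed totals and flags", {
  ref <- builtin_reference()
  expect_equal(sum(ref$strata$count), 1836577)
  expect_lt(abs(sum(ref$strata$fraction) - 1), 1e-9)
  expect_equal(ps_lookup(ref, 0), 1.0)
  expect_equal(ps_lookup(ref, 14), 0.95177)  # stored as printed
  expect_equal(ps_lookup(ref, 25), 0.24753)  # grouped >=22 bucket
  expect_true(ref$nonmonotone_warning)
  expect_error(ps_lookup(ref, -1), "domain")
  # stratum grouping is independent of the Ps buckets
  expect_equal(stratum_lookup(ref, c(17, 18, 19, 30)), c(18, 18, 19, 19))
})

test_that("derive_reference recovers proportions and fractions", {
  # trivial proportion (other buckets are empty: warning expected)
  ref <- suppressWarnings(
    derive_reference(rep(3, 100), rep(c("survived", "died"), c(90, 10))))
  expect_equal(ref$ps$ps[ref$ps$score_min == 3], 0.90)
  expect_warning(
    derive_reference(rep(3, 10), rep("survived", 10)), "empty")
  # single stratum normalizes to 1
  ref1 <- suppressWarnings(
    derive_reference(rep(c(1, 2), 50), rep("survived", 100),
                     strata_spec = list(0:39)))
  expect_equal(ref1$strata$fraction, 1.0)
  expect_lt(abs(sum(ref1$strata$fraction) - 1), 1e-9)
})

test_that("derive_reference recovers generator parameters within 3 SE", {
  spec <- generator_spec(n = 200000, seed = 11)
  pop <- generate_population(spec)
  ref <- suppressWarnings(derive_reference(pop$score, pop$outcome))
  truth <- default_survival_curve()
  dist <- default_score_distribution()
  for (s in 0:22) {
    n_s <- sum(pop$score == s)
    p_hat <- ref$ps$ps[ref$ps$score_min == s]
    se <- sqrt(truth[[as.character(s)]] *
                 (1 - truth[[as.character(s)]]) / n_s)
    expect_lt(abs(p_hat - truth[[as.character(s)]]), 3 * se + 1e-12)
  }
  # stratum fractions equal the apportioned counts exactly
  expect_equal(ref$strata$count[1], sum(pop$score == 0))
})

test_that("reference tables round-trip through JSON", {
  ref <- builtin_reference()
  path <- tempfile(fileext = ".json")
  write_reference(ref, path)
  back <- read_reference(path)
  expect_equal(back$ps$ps, ref$ps$ps)
  expect_equal(back$strata$count, ref$strata$count)
  expect_equal(back$strata$score_max, ref$strata$score_max)
  expect_true(back$nonmonotone_warning)
})
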