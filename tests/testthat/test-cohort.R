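test_that("cohort CSV round trip preserves records and missing values", {
  cohort <- cohort_of(
    valid_record(id = "a"),
    valid_record(id = "b", sex = "female", cause = "non_disease",
                 avpu = "V", age = 80),
    valid_record(id = "c", ed_result = "admitted",
                 hospital_result = "died")
  )
  path <- write_temp_cohort(cohort)
  back <- read_cohort(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$id, cohort$id)
  expect_equal(back$sbp, cohort$sbp)
  expect_equal(back$ed_result, cohort$ed_result)

  # an empty vitals cell becomes NA
  cohort$sbp[2] <- NA
  back <- read_cohort(write_temp_cohort(cohort))
  expect_true(is.na(back$sbp[2]))
  expect_false(is.na(back$sbp[1]))

  # unparseable vitals become NA with a warning naming the column
  lines <- readLines(path)
  lines[2] <- sub("120", "n/a", lines[2])
  bad <- tempfile(fileext = ".csv")
  writeLines(lines, bad)
  expect_warning(out <- read_cohort(bad), "sbp")
  expect_true(is.na(out$sbp[1]))
})

test_that("categorical fields are strictly validated", {
  cohort <- cohort_of(valid_record(), valid_record(id = "r2"))
  path <- write_temp_cohort(cohort)
  lines <- readLines(path)
  lines[3] <- sub(",A,", ",X,", lines[3])
  bad <- tempfile(fileext = ".csv")
  writeLines(lines, bad)
  expect_error(read_cohort(bad), "avpu.*row 2|row 2.*avpu")
})

test_that("schema errors name the missing column; empty files are rejected", {
  cohort <- cohort_of(valid_record())
  path <- write_temp_cohort(cohort)
  lines <- readLines(path)
  lines[1] <- sub("spo2", "saturation", lines[1])
  renamed <- tempfile(fileext = ".csv")
  writeLines(lines, renamed)
  expect_error(read_cohort(renamed), "spo2")
  # a schema mapping recovers the renamed column
  ok <- read_cohort(renamed, schema = c(spo2 = "saturation"))
  expect_equal(ok$spo2, 99)

  empty <- tempfile(fileext = ".csv")
  writeLines(lines[1], empty)
  expect_error(read_cohort(empty), "empty")
})

test_that("outcome derivation: any ED or hospital death path counts", {
  cohort <- cohort_of(
    valid_record(ed_result = "died"),
    valid_record(ed_result = "hopeless_discharge"),
    valid_record(ed_result = "admitted", hospital_result = "died"),
    valid_record(ed_result = "admitted",
                 hospital_result = "hopeless_discharge"),
    valid_record(ed_result = "admitted", hospital_result = "discharged"),
    valid_record(ed_result = "discharged"),
    valid_record(ed_result = "transferred")
  )
  expect_equal(derive_outcome(cohort),
               c("died", "died", "died", "died",
                 "survived", "survived", "survived"))
})

test_that("exclusion cascade applies the documented rules and precedence", {
  cohort <- cohort_of(
    valid_record(id = "keep"),
    valid_record(id = "child", age = 10),
    valid_record(id = "xfer", transferred_out = TRUE),
    valid_record(id = "arrest", arrival_arrest = TRUE),
    valid_record(id = "nosbp", sbp = NA),
    valid_record(id = "hisbp", sbp = 310),
    valid_record(id = "hispo2", spo2 = 101),
    # precedence: a child in arrest with bad vitals counts only as under_15
    valid_record(id = "multi", age = 5, arrival_arrest = TRUE, spo2 = 101),
    # bt / dbp absence never triggers missing_variable
    valid_record(id = "nobt", bt = NA, dbp = NA)
  )
  res <- apply_exclusions(cohort)
  expect_setequal(res$retained$id, c("keep", "nobt"))
  expect_equal(res$report$counts_by_reason,
               list(under_15 = 2L, transfer_out = 1L, arrival_arrest = 1L,
                    missing_variable = 1L, implausible_value = 2L))
  # partition invariant
  expect_equal(res$report$n_input,
               res$report$n_retained +
                 sum(unlist(res$report$counts_by_reason)))
  # idempotence
  again <- apply_exclusions(res$retained)
  expect_equal(again$report$n_retained, nrow(res$retained))
  expect_equal(sum(unlist(again$report$counts_by_reason)), 0L)
})

test_that("exclusion report partition holds on randomized cohorts", {
  set.seed(71)
  for (rep in 1:5) {
    spec <- generator_spec(n = 300, emit_vitals = TRUE,
                           exclusion_noise = 0.05, seed = rep)
    pop <- generate_population(spec)
    res <- apply_exclusions(pop)
    expect_equal(res$report$n_input,
                 res$report$n_retained +
                   sum(unlist(res$report$counts_by_reason)))
  }
})

test_that("inconsistent hospital_result is rejected at read time", {
  cohort <- cohort_of(valid_record(ed_result = "admitted",
                                   hospital_result = "discharged"))
  cohort$hospital_result <- "not_admitted"  # admitted yet not_admitted
  expect_error(read_cohort(write_temp_cohort(cohort)), "not_admitted")
})
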