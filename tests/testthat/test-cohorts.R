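make_events <- function(patient_id, days) {
  data.frame(patient_id = patient_id, day = as.integer(days), code = "C01.1",
             domain = "condition", abnormal = "none",
             stringsAsFactors = FALSE)
}

pop_from <- function(events, admissions, demographics) {
  structure(list(events = data.table::as.data.table(events),
                 admissions = data.table::as.data.table(admissions),
                 demographics = data.table::as.data.table(demographics),
                 ontology = make_synthetic_ontology(2, 3)),
            class = "ehr_population")
}

test_that("pretraining inclusion needs enough in-window event days", {
  ev <- rbind(make_events("A", c(10, 20)),          # 2 days: excluded
              make_events("B", c(10, 20, 30)),      # 3 days: included
              make_events("C", c(10, 20, 30, 40)))  # included but listed
  pop <- pop_from(ev, data.frame(), data.frame())
  spec <- cohort_spec(c(2009, 2009), excluded_patients = "C")
  out <- build_pretraining_cohort(pop, spec)
  expect_identical(out$patient_ids, "B")
})

test_that("timelines are truncated to the pretraining window", {
  # 5 event days, 3 inside 2009 (days 0..364)
  ev <- make_events("A", c(100, 200, 300, 400, 800))
  pop <- pop_from(ev, data.frame(), data.frame())
  out <- build_pretraining_cohort(pop, cohort_spec(c(2009, 2009)))
  expect_identical(out$patient_ids, "A")
  expect_setequal(out$events$day, c(100, 200, 300))
})

test_that("task cohort applies adult and same-day exclusions", {
  demo <- data.frame(patient_id = c("A", "B", "C"),
                     birth_day = c(-17L * 365L, -40L * 365L, -40L * 365L),
                     sex = "F", race = "white", ethnicity = "non-hispanic")
  adm <- data.frame(patient_id = c("A", "B", "C"),
                    admit_day = c(100L, 100L, 100L),
                    discharge_day = c(105L, 100L, 107L),
                    died = FALSE, icu_day = NA_integer_)
  pop <- pop_from(make_events("A", 1), adm, demo)
  tt <- build_task_cohort(pop, seed = 1)
  # A is 17 at admission, B discharged the same day
  expect_setequal(tt$patient_id, "C")
})

test_that("index admission choice is seeded and unique per patient", {
  demo <- data.frame(patient_id = "A", birth_day = -40L * 365L, sex = "M",
                     race = "white", ethnicity = "non-hispanic")
  adm <- data.frame(patient_id = "A",
                    admit_day = c(100L, 500L, 900L),
                    discharge_day = c(103L, 503L, 903L),
                    died = FALSE, icu_day = NA_integer_)
  pop <- pop_from(make_events("A", 1), adm, demo)
  t1 <- build_task_cohort(pop, seed = 3)
  t2 <- build_task_cohort(pop, seed = 3)
  expect_equal(nrow(t1), 1L)
  expect_identical(t1$admit_day, t2$admit_day)
  picks <- vapply(1:12, function(s) build_task_cohort(pop, seed = s)$admit_day,
                  integer(1))
  expect_gt(length(unique(picks)), 1L) # different seeds can differ
})

test_that("admission without demographics is an error", {
  adm <- data.frame(patient_id = "GHOST", admit_day = 10L,
                    discharge_day = 15L, died = FALSE, icu_day = NA_integer_)
  pop <- pop_from(make_events("A", 1), adm,
                  data.frame(patient_id = "A", birth_day = -40L * 365L,
                             sex = "F", race = "white",
                             ethnicity = "non-hispanic"))
  expect_error(build_task_cohort(pop, seed = 1), "GHOST")
})

test_that("labels implement the stated day-count conventions", {
  adm_base <- data.frame(patient_id = "A", admit_day = 100L,
                         discharge_day = 106L, died = FALSE,
                         icu_day = NA_integer_)
  # 7-day stay (discharge - admit = 6) is long; 6-day stay is not
  l7 <- derive_labels(list(patient_id = "A", admit_day = 100L,
                           discharge_day = 106L, died = FALSE,
                           icu_day = NA_integer_), adm_base)
  expect_equal(unname(l7$labels["long_los"]), 1L)
  l6 <- derive_labels(list(patient_id = "A", admit_day = 100L,
                           discharge_day = 105L, died = FALSE,
                           icu_day = NA_integer_), adm_base)
  expect_equal(unname(l6$labels["long_los"]), 0L)

  # readmission window and the discharge-day ineligibility rule
  two <- function(gap) {
    rbind(adm_base,
          data.frame(patient_id = "A", admit_day = 106L + gap,
                     discharge_day = 110L + gap, died = FALSE,
                     icu_day = NA_integer_))
  }
  row <- list(patient_id = "A", admit_day = 100L, discharge_day = 106L,
              died = FALSE, icu_day = NA_integer_)
  expect_false(derive_labels(row, two(0))$eligible[["readmission"]])
  l30 <- derive_labels(row, two(30))
  expect_true(l30$eligible[["readmission"]])
  expect_equal(unname(l30$labels["readmission"]), 1L)
  l31 <- derive_labels(row, two(31))
  expect_equal(unname(l31$labels["readmission"]), 0L)

  # ICU first-day transfer is ineligible; later transfer is positive
  icu1 <- derive_labels(list(patient_id = "A", admit_day = 100L,
                             discharge_day = 106L, died = FALSE,
                             icu_day = 100L), adm_base)
  expect_false(icu1$eligible[["icu"]])
  icu2 <- derive_labels(list(patient_id = "A", admit_day = 100L,
                             discharge_day = 106L, died = FALSE,
                             icu_day = 102L), adm_base)
  expect_true(icu2$eligible[["icu"]])
  expect_equal(unname(icu2$labels["icu"]), 1L)

  # mortality
  ld <- derive_labels(list(patient_id = "A", admit_day = 100L,
                           discharge_day = 106L, died = TRUE,
                           icu_day = NA_integer_), adm_base)
  expect_equal(unname(ld$labels["mortality"]), 1L)
})

test_that("eligibility exclusions never remove rows from other tasks", {
  pop <- small_population()
  tt <- build_task_cohort(pop, seed = 2)
  expect_equal(anyDuplicated(tt$patient_id), 0L)
  # ineligible-for-ICU rows still carry labels for the other tasks
  inel <- which(!tt$eligible_icu)
  if (length(inel) > 0) {
    expect_true(all(tt$label_mortality[inel] %in% c(0L, 1L)))
    expect_true(all(tt$eligible_mortality[inel]))
  }
})

test_that("patient splits partition deterministically with exact sizes", {
  ids <- sprintf("P%03d", 1:100)
  s1 <- split_patients(ids, c(train = 0.8, val = 0.1, test = 0.1), seed = 4)
  s2 <- split_patients(ids, c(train = 0.8, val = 0.1, test = 0.1), seed = 4)
  expect_identical(s1, s2)
  expect_equal(unname(table(s1)[c("train", "val", "test")]),
               c(80L, 10L, 10L), ignore_attr = TRUE)
  expect_setequal(names(s1), ids)
  # stratified variant keeps per-stratum proportions
  strata <- rep(c("a", "b"), each = 50)
  s3 <- split_patients(ids, c(train = 0.8, val = 0.1, test = 0.1),
                       seed = 4, stratify_by = strata)
  expect_equal(sum(s3[1:50] == "train"), 40L)
})

test_that("leakage assertion passes when clean and fails on a violation", {
  pop <- small_population()
  tt <- build_task_cohort(pop, seed = 1)
  tt$split <- unname(split_patients(tt$patient_id, seed = 1)[tt$patient_id])
  held <- tt$patient_id[tt$split %in% c("val", "test")]
  pre <- build_pretraining_cohort(
    pop, cohort_spec(c(2009, 2012), excluded_patients = held))
  expect_true(assert_no_leakage(pre$patient_ids, tt))
  expect_length(intersect(pre$patient_ids, held), 0L)
  # violated fixture must fail
  bad_ids <- c(pre$patient_ids, held[1])
  expect_error(assert_no_leakage(bad_ids, tt), "leakage")
})
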