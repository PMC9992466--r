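# Pretraining and task-specific cohort construction, with the anti-leakage
# rule: task validation/test patients never enter a pretraining cohort.

ADULT_AGE_YEARS <- 18

#' Pretraining cohort specification
#'
#' @param year_range inclusive calendar years whose event days count toward
#'   inclusion; timelines are truncated to this range.
#' @param min_event_days minimum number of distinct days with at least one
#'   event inside `year_range` (default 3).
#' @param excluded_patients patient ids barred from the cohort (used to
#'   prevent leakage of task validation/test patients).
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(year_range, min_event_days = 3L,
                        excluded_patients = character(0)) {
  stopifnot(length(year_range) == 2L, year_range[2] >= year_range[1],
            min_event_days >= 1L)
  structure(list(year_range = as.integer(year_range),
                 min_event_days = as.integer(min_event_days),
                 excluded_patients = as.character(excluded_patients)),
            class = "cohort_spec")
}

#' Build a pretraining cohort
#'
#' Includes a patient iff they have at least `min_event_days` distinct days
#' with clinical events inside the spec's year range and are not on the
#' exclusion list. Returned timelines are truncated to the year range.
#'
#' @param population an `ehr_population`.
#' @param spec a [cohort_spec()].
#' @param epoch_year calendar year of day 0.
#' @return list with `patient_ids` and `events` (truncated event rows).
#' @export
build_pretraining_cohort <- function(population, spec, epoch_year = 2009L) {
  stopifnot(inherits(spec, "cohort_spec"))
  ev <- data.table::as.data.table(population$events)
  lo <- year_start_day(spec$year_range[1], epoch_year)
  hi <- year_start_day(spec$year_range[2] + 1L, epoch_year) - 1L
  day <- patient_id <- NULL
  ev <- ev[day >= lo & day <= hi]
  n_days <- ev[, list(nd = data.table::uniqueN(day)), by = patient_id]
  ids <- n_days$patient_id[n_days$nd >= spec$min_event_days]
  ids <- setdiff(ids, spec$excluded_patients)
  list(patient_ids = sort(ids), events = ev[patient_id %in% ids])
}

#' Derive task labels and eligibility flags for one index admission
#'
#' Label conventions: length of stay counts both endpoints
#' (`discharge_day - admit_day + 1` days), so a long stay (seven or more
#' days) means `discharge_day - admit_day >= 6`. A readmission on the day
#' of discharge (gap 0) makes the patient ineligible for the readmission
#' task; gaps of 1-30 days are positive. An ICU transfer on the first
#' admission day makes the patient ineligible for the ICU task because the
#' transfer precedes the prediction time.
#'
#' @param row a single admission record (list or one-row data.frame with
#'   `patient_id`, `admit_day`, `discharge_day`, `died`, `icu_day`).
#' @param admissions all admissions (to locate the next inpatient stay).
#' @return list with `labels` and `eligible`, each named by task.
#' @export
derive_labels <- function(row, admissions) {
  adm <- data.table::as.data.table(admissions)
  nxt <- adm[adm$patient_id == row$patient_id &
               adm$admit_day > row$admit_day, ]
  next_admit <- if (nrow(nxt) > 0) min(nxt$admit_day) else NA_integer_
  gap <- next_admit - row$discharge_day

  labels <- c(
    mortality = as.integer(isTRUE(as.logical(row$died))),
    long_los = as.integer(row$discharge_day - row$admit_day >= 6L),
    readmission = as.integer(!is.na(gap) && gap >= 1L && gap <= 30L),
    icu = as.integer(!is.na(row$icu_day))
  )
  eligible <- c(
    mortality = TRUE,
    long_los = TRUE,
    readmission = is.na(gap) || gap >= 1L,
    icu = is.na(row$icu_day) || row$icu_day > row$admit_day
  )
  list(labels = labels, eligible = eligible)
}

#' Build the task-specific cohort table
#'
#' Applies the inclusion rules for the inpatient prediction tasks: adult
#' patients (age >= 18 years at admission), same-day discharges excluded,
#' and one index admission selected uniformly at random (seeded) per
#' patient. Labels and per-task eligibility come from [derive_labels()];
#' prediction day is the admission day for mortality, long LOS and ICU and
#' the discharge day for 30-day readmission.
#'
#' @param population an `ehr_population`.
#' @param year_range optional inclusive years to which index admissions are
#'   restricted (default: all).
#' @param seed integer seed for index-admission selection.
#' @param epoch_year calendar year of day 0.
#' @return data.table with one row per patient: admit/discharge days, year,
#'   `label_*`, `eligible_*` and `predday_*` columns per task, and a `split`
#'   column initialized to NA.
#' @export
build_task_cohort <- function(population, year_range = NULL, seed = 1L,
                              epoch_year = 2009L) {
  adm <- data.table::as.data.table(population$admissions)
  demo <- data.table::as.data.table(population$demographics)
  if (nrow(adm) == 0) stop("population has no admissions")
  orphan <- setdiff(adm$patient_id, demo$patient_id)
  if (length(orphan) > 0) {
    stop("admission without matching timeline for patient '", orphan[1], "'")
  }
  adm <- merge(adm, demo[, c("patient_id", "birth_day")], by = "patient_id")
  age <- (adm$admit_day - adm$birth_day) / 365
  keep <- age >= ADULT_AGE_YEARS & adm$discharge_day > adm$admit_day
  if (!is.null(year_range)) {
    yr <- day_to_year(adm$admit_day, epoch_year)
    keep <- keep & yr >= year_range[1] & yr <= year_range[2]
  }
  cand <- adm[keep]
  if (nrow(cand) == 0) stop("no eligible admissions for the task cohort")

  # one index admission per patient, uniformly at random
  set.seed(derive_seed(seed, "index-admission"))
  patient_id <- NULL
  data.table::setorder(cand, patient_id, admit_day)
  pick <- cand[, list(row_i = .I[sample.int(.N, 1)]), by = patient_id]
  idx <- cand[pick$row_i]

  lab <- lapply(seq_len(nrow(idx)), function(i) {
    derive_labels(as.list(idx[i]), population$admissions)
  })
  out <- data.table::data.table(
    patient_id = idx$patient_id,
    admit_day = idx$admit_day,
    discharge_day = idx$discharge_day,
    year = day_to_year(idx$admit_day, epoch_year)
  )
  for (task in TASKS) {
    out[[paste0("label_", task)]] <-
      vapply(lab, function(l) l$labels[[task]], integer(1))
    out[[paste0("eligible_", task)]] <-
      vapply(lab, function(l) l$eligible[[task]], logical(1))
    out[[paste0("predday_", task)]] <-
      if (task == "readmission") idx$discharge_day else idx$admit_day
  }
  out$split <- NA_character_
  out[]
}

#' Partition patient ids into train/validation/test splits
#'
#' @param ids character vector of patient ids.
#' @param fractions positive fractions summing to 1, named
#'   (e.g. `c(train = .8, val = .1, test = .1)`).
#' @param seed integer seed.
#' @param stratify_by optional vector aligned with `ids`; when given, the
#'   partition is drawn within each stratum (e.g. outcome label).
#' @return named character vector mapping id to split name.
#' @export
split_patients <- function(ids, fractions = c(train = 0.8, val = 0.1,
                                              test = 0.1),
                           seed = 1L, stratify_by = NULL) {
  stopifnot(all(fractions > 0), abs(sum(fractions) - 1) < 1e-8,
            !is.null(names(fractions)))
  set.seed(derive_seed(seed, "split"))
  assign_group <- function(n) {
    sizes <- floor(fractions * n)
    rem <- n - sum(sizes)
    if (rem > 0) {
      extra <- order(fractions * n - sizes, decreasing = TRUE)[seq_len(rem)]
      sizes[extra] <- sizes[extra] + 1L
    }
    sample(rep(names(fractions), times = sizes))
  }
  out <- character(length(ids))
  if (is.null(stratify_by)) {
    out <- assign_group(length(ids))
  } else {
    for (g in unique(stratify_by)) {
      sel <- which(stratify_by == g)
      out[sel] <- assign_group(length(sel))
    }
  }
  names(out) <- ids
  out
}

#' Assert that a pretraining cohort cannot leak task evaluation patients
#'
#' @param pretrain_ids patient ids of a pretraining cohort.
#' @param task_table a task cohort table with an assigned `split` column.
#' @return TRUE invisibly; errors if any validation/test patient appears in
#'   the pretraining cohort.
#' @export
assert_no_leakage <- function(pretrain_ids, task_table) {
  if (any(is.na(task_table$split))) {
    stop("task table has unassigned splits; assign splits before checking leakage")
  }
  held_out <- task_table$patient_id[task_table$split %in% c("val", "test")]
  bad <- intersect(pretrain_ids, held_out)
  if (length(bad) > 0) {
    stop("leakage: ", length(bad), " task val/test patient(s) present in ",
         "the pretraining cohort (e.g. '", bad[1], "')")
  }
  invisible(TRUE)
}
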