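# Delimited-text persistence for populations: events.csv, admissions.csv,
# demographics.csv (+ ontology.csv) in one directory. Integer days are
# 0-based offsets from the calendar epoch.

EVENT_COLS <- c(patient_id = "character", day = "integer", code = "character",
                domain = "character", abnormal = "character")
ADM_COLS <- c(patient_id = "character", admit_day = "integer",
              discharge_day = "integer", died = "logical",
              icu_day = "integer")
DEMO_COLS <- c(patient_id = "character", birth_day = "integer",
               sex = "character", race = "character",
               ethnicity = "character")

#' Write a population's event stream to a directory
#'
#' Emits `events.csv`, `admissions.csv`, `demographics.csv` and
#' `ontology.csv` under `path`.
#'
#' @param population an `ehr_population` (or a list with `events`,
#'   `admissions`, `demographics` data.frames and an `ontology`).
#' @param path output directory; created if missing.
#' @return `path`, invisibly.
#' @export
write_event_stream <- function(population, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(population$events, file.path(path, "events.csv"))
  data.table::fwrite(population$admissions, file.path(path, "admissions.csv"))
  data.table::fwrite(population$demographics,
                     file.path(path, "demographics.csv"))
  write_ontology(population$ontology, file.path(path, "ontology.csv"))
  invisible(path)
}

read_table_checked <- function(path, spec) {
  if (!file.exists(path)) stop("missing file: ", path)
  dt <- data.table::fread(path, colClasses = unname(spec), sep = ",",
                          header = TRUE, na.strings = "")
  miss <- setdiff(names(spec), names(dt))
  if (length(miss) > 0) {
    stop("parse error in ", basename(path), " line 1, column ", miss[1],
         ": missing column '", miss[1], "'")
  }
  dt[, names(spec), with = FALSE]
}

#' Read a population's event stream from a directory
#'
#' Validates the schema on load: every event code must exist in the
#' ontology, abnormal flags may only appear on measurement-domain rows, and
#' admission day intervals must be well-formed. Violations raise a parse
#' error naming the file, line and offending value.
#'
#' @param path directory written by [write_event_stream()].
#' @param ontology optional `ehr_ontology`; defaults to the `ontology.csv`
#'   stored alongside the stream.
#' @return an `ehr_population` (without a latent risk model).
#' @export
read_event_stream <- function(path, ontology = NULL) {
  events <- read_table_checked(file.path(path, "events.csv"), EVENT_COLS)
  admissions <- read_table_checked(file.path(path, "admissions.csv"), ADM_COLS)
  demographics <- read_table_checked(file.path(path, "demographics.csv"),
                                     DEMO_COLS)
  if (is.null(ontology)) {
    ontology <- read_ontology(file.path(path, "ontology.csv"))
  }

  if (nrow(events) > 0) {
    bad <- which(!(events$code %in% ontology$nodes))
    if (length(bad) > 0) {
      stop("parse error in events.csv line ", bad[1] + 1L,
           ", column code: code '", events$code[bad[1]],
           "' absent from ontology")
    }
    bad <- which(!(events$abnormal %in% c("none", "above", "below")))
    if (length(bad) > 0) {
      stop("parse error in events.csv line ", bad[1] + 1L,
           ", column abnormal: invalid value '", events$abnormal[bad[1]], "'")
    }
    bad <- which(events$abnormal != "none" & events$domain != "measurement")
    if (length(bad) > 0) {
      stop("parse error in events.csv line ", bad[1] + 1L,
           ", column abnormal: abnormal flag on non-measurement code '",
           events$code[bad[1]], "'")
    }
  }
  if (nrow(admissions) > 0) {
    bad <- which(admissions$discharge_day < admissions$admit_day)
    if (length(bad) > 0) {
      stop("parse error in admissions.csv line ", bad[1] + 1L,
           ", column discharge_day: discharge before admission")
    }
    bad <- which(!is.na(admissions$icu_day) &
                   (admissions$icu_day < admissions$admit_day |
                      admissions$icu_day > admissions$discharge_day))
    if (length(bad) > 0) {
      stop("parse error in admissions.csv line ", bad[1] + 1L,
           ", column icu_day: ICU day outside the admission interval")
    }
  }

  structure(
    list(events = events, demographics = demographics,
         admissions = admissions, ontology = ontology, config = NULL,
         risk_model = NULL),
    class = "ehr_population"
  )
}
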