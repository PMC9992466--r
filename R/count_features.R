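# Count-based patient featurization: binary indicators of code occurrence
# in clinical time bins relative to the prediction day, plus demographics
# and abnormal-direction indicators for measurements.

TIME_BINS <- c("bin_24h", "bin_1_7", "bin_8_30", "bin_31_plus")

# delta = prediction_day - event_day (>= 0)
delta_to_bin <- function(delta) {
  bin <- character(length(delta))
  bin[delta == 0] <- "bin_24h"
  bin[delta >= 1 & delta <= 7] <- "bin_1_7"
  bin[delta >= 8 & delta <= 30] <- "bin_8_30"
  bin[delta >= 31] <- "bin_31_plus"
  bin
}

age_bin_label <- function(age_years) {
  k <- pmax(0, floor(age_years / 5))
  sprintf("[%d,%d)", k * 5, k * 5 + 5)
}

demographic_features <- function(demo_row, prediction_day) {
  age <- (prediction_day - demo_row$birth_day) / 365
  c(paste0("demo|sex|", demo_row$sex),
    paste0("demo|race|", demo_row$race),
    paste0("demo|ethnicity|", demo_row$ethnicity),
    paste0("demo|age_bin|", age_bin_label(age)))
}

#' Count-based features for one patient at a prediction day
#'
#' Events strictly after the prediction day contribute nothing. Each unique
#' code occurring in a time bin (24 h prior = the prediction day itself,
#' 1-7 days prior, 8-30 days prior, 31 days or more prior) yields one
#' binary feature `domain|code|bin`; measurement results flagged above or
#' below the reference range additionally yield
#' `measurement|code|direction|bin`. Demographics contribute sex, race,
#' ethnicity and the 5-year age bin at prediction.
#'
#' @param events event rows for one patient (day, code, domain, abnormal).
#' @param prediction_day integer day; events with `day <= prediction_day`
#'   are visible.
#' @param demo_row the patient's demographics row.
#' @return character vector of active feature names.
#' @export
featurize_one <- function(events, prediction_day, demo_row) {
  feats <- demographic_features(demo_row, prediction_day)
  if (!is.null(events) && nrow(events) > 0) {
    delta <- prediction_day - events$day
    vis <- delta >= 0
    if (any(vis)) {
      ev <- events[vis, , drop = FALSE]
      bin <- delta_to_bin(delta[vis])
      code_f <- paste(ev$domain, ev$code, bin, sep = "|")
      abn <- ev$abnormal != "none"
      abn_f <- if (any(abn)) {
        paste("measurement", ev$code[abn], ev$abnormal[abn], bin[abn],
              sep = "|")
      } else character(0)
      feats <- c(feats, code_f, abn_f)
    }
  }
  sort(unique(feats))
}

#' Featurize every row of a task cohort table
#'
#' @param population an `ehr_population`.
#' @param task_table a task cohort table from [build_task_cohort()].
#' @param task one of `mortality`, `long_los`, `readmission`, `icu`;
#'   selects the prediction day column.
#' @return list of feature-name vectors, aligned with `task_table` rows.
#' @export
featurize_cohort <- function(population, task_table, task = "mortality") {
  stopifnot(task %in% TASKS)
  ev <- data.table::as.data.table(population$events)
  demo <- data.table::as.data.table(population$demographics)
  pred_col <- paste0("predday_", task)

  rows <- data.table::data.table(
    row_id = seq_len(nrow(task_table)),
    patient_id = task_table$patient_id,
    pred_day = task_table[[pred_col]]
  )
  m <- merge(rows, ev, by = "patient_id", allow.cartesian = TRUE)
  m <- m[m$pred_day - m$day >= 0]
  clin <- vector("list", nrow(task_table))
  if (nrow(m) > 0) {
    bin <- delta_to_bin(m$pred_day - m$day)
    f <- paste(m$domain, m$code, bin, sep = "|")
    abn <- m$abnormal != "none"
    rid <- c(m$row_id, m$row_id[abn])
    fall <- c(f, paste("measurement", m$code[abn], m$abnormal[abn], bin[abn],
                       sep = "|"))
    by_row <- split(fall, rid)
    clin[as.integer(names(by_row))] <- by_row
  }

  demo <- demo[match(rows$patient_id, demo$patient_id)]
  lapply(seq_len(nrow(task_table)), function(i) {
    sort(unique(c(demographic_features(as.list(demo[i]), rows$pred_day[i]),
                  clin[[i]] %||% character(0))))
  })
}

#' Fit a feature vocabulary with minimum-count pruning
#'
#' A feature's count is the number of training rows in which it is active;
#' features with count below `min_count` are pruned (and must be pruned
#' from validation/test encodings by sharing this vocabulary).
#'
#' @param feature_sets list of training feature-name vectors.
#' @param min_count minimum observation count (default 25).
#' @return a `feature_vocabulary`: data.frame with lexicographically
#'   ordered `name` and `train_count`.
#' @export
fit_vocabulary <- function(feature_sets, min_count = 25L) {
  if (length(feature_sets) == 0) stop("cannot fit a vocabulary on no rows")
  counts <- table(unlist(lapply(feature_sets, unique), use.names = FALSE))
  keep <- counts[counts >= min_count]
  vocab <- data.frame(name = names(keep), train_count = as.integer(keep),
                      stringsAsFactors = FALSE)
  vocab <- vocab[order(vocab$name), , drop = FALSE]
  rownames(vocab) <- NULL
  structure(vocab, class = c("feature_vocabulary", "data.frame"))
}

#' Encode feature sets against a fitted vocabulary
#'
#' Features absent from the vocabulary are silently ignored; row order is
#' preserved.
#'
#' @param feature_sets list of feature-name vectors.
#' @param vocab a [fit_vocabulary()] result.
#' @return sparse binary matrix (`Matrix::sparseMatrix`), one row per set,
#'   one column per vocabulary feature. Persist with [Matrix::writeMM()]
#'   (MatrixMarket sparse triplet text) alongside the vocabulary CSV.
#' @export
encode_matrix <- function(feature_sets, vocab) {
  nr <- length(feature_sets)
  nc <- nrow(vocab)
  ij <- lapply(seq_len(nr), function(i) {
    j <- match(feature_sets[[i]], vocab$name)
    j <- j[!is.na(j)]
    if (length(j) > 0) cbind(i, j) else NULL
  })
  ij <- do.call(rbind, ij)
  if (is.null(ij)) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(nr, nc),
                                dimnames = list(NULL, vocab$name)))
  }
  Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = 1,
                       dims = c(nr, nc), dimnames = list(NULL, vocab$name))
}

#' Persist / load a feature vocabulary as CSV
#' @param vocab a `feature_vocabulary`.
#' @param path CSV path.
#' @export
write_vocabulary <- function(vocab, path) {
  utils::write.csv(as.data.frame(vocab), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  vocab <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(vocab, class = c("feature_vocabulary", "data.frame"))
}
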