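# Synthetic EHR generator.
#
# Emits coded patient timelines (day-granular event streams), demographics
# and inpatient admission records with four binary outcomes, under
# controllable temporal distribution shift. The shift mechanism operates
# strictly at the LEAF level of the code ontology: per-year log-frequency
# drift redistributes probability mass among sibling leaves, and sibling
# replacement permutes leaf identities within a parent. Parent-level
# (ancestor) marginals are therefore time-invariant by construction, and the
# latent outcome risk -- a fixed linear function of parent-code indicators
# plus demographics -- carries a stable signal across years. Models that see
# only leaf identities are exposed to the shift; models that exploit the
# ontology are not.

TASKS <- c("mortality", "long_los", "readmission", "icu")

#' Configuration for the synthetic EHR generator
#'
#' @param n_patients number of patients to simulate.
#' @param year_range inclusive calendar year range, e.g. `c(2009, 2021)`.
#' @param ontology an `ehr_ontology` (leaves are the emitted codes).
#' @param events_per_day mean number of extra codes per outpatient event day
#'   (each day gets `1 + Poisson(events_per_day - 1)` codes); inpatient days
#'   draw twice this rate.
#' @param admission_rate expected inpatient admissions per patient-year.
#' @param outcome_prevalence named vector of target prevalences (in the
#'   reference = earliest-four-year group) for
#'   `mortality`, `long_los`, `readmission`, `icu`; all in (0, 1).
#' @param drift_magnitude per-year decorrelation rate of
#'   within-sibling-group leaf log-frequencies (AR(1) mixing: year-on-year
#'   correlation `exp(-drift_magnitude)`, stationary N(0,1) marginal);
#'   0 disables drift.
#' @param code_replacement_rate per-year probability that a leaf code is
#'   replaced by (swapped with) a random sibling leaf; 0 disables.
#' @param within_group_logit_sd sd of within-sibling-group leaf
#'   log-frequencies; large values concentrate each parent's emission on
#'   one or two dominant leaf codes (one canonical coding per concept at
#'   any given time), which is what makes leaf-identity drift
#'   consequential for leaf-level models.
#' @param chronic_parents_per_patient number of persistent "chronic
#'   condition" parent codes drawn per patient (weighted by parent
#'   frequency); these recur across the patient's event days and carry the
#'   patient-level structure that sequence models can learn.
#' @param chronic_share probability that a code draw comes from the
#'   patient's chronic parents rather than the background distribution.
#' @param visit_rate expected outpatient event days per patient-year.
#' @param risk_noise_sd sd of the admission-level latent noise added to each
#'   task's linear risk score.
#' @param seed integer seed; the generator is deterministic given
#'   (config, seed).
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_patients = 2000L,
                             year_range = c(2009L, 2021L),
                             ontology = make_synthetic_ontology(),
                             events_per_day = 3,
                             admission_rate = 0.3,
                             outcome_prevalence = c(mortality = 0.03,
                                                    long_los = 0.25,
                                                    readmission = 0.15,
                                                    icu = 0.08),
                             drift_magnitude = 0.3,
                             code_replacement_rate = 0.1,
                             within_group_logit_sd = 2.5,
                             chronic_parents_per_patient = 3L,
                             chronic_share = 0.6,
                             visit_rate = 6,
                             risk_noise_sd = 0.5,
                             seed = 1L) {
  year_range <- as.integer(year_range)
  if (length(year_range) != 2L || year_range[2] < year_range[1]) {
    stop("year_range must be a non-empty inclusive range c(first, last)")
  }
  if (!all(TASKS %in% names(outcome_prevalence))) {
    stop("outcome_prevalence must name all of: ", paste(TASKS, collapse = ", "))
  }
  outcome_prevalence <- outcome_prevalence[TASKS]
  if (any(outcome_prevalence <= 0 | outcome_prevalence >= 1)) {
    stop("outcome prevalences must lie in (0, 1)")
  }
  if (drift_magnitude < 0) stop("drift_magnitude must be >= 0")
  stopifnot(within_group_logit_sd > 0)
  if (code_replacement_rate < 0 || code_replacement_rate > 1) {
    stop("code_replacement_rate must be in [0, 1]")
  }
  stopifnot(inherits(ontology, "ehr_ontology"), n_patients >= 1,
            events_per_day > 0, admission_rate > 0, visit_rate > 0,
            chronic_share >= 0, chronic_share < 1,
            chronic_parents_per_patient >= 0)
  structure(
    list(
      n_patients = as.integer(n_patients),
      year_range = year_range,
      ontology = ontology,
      events_per_day = events_per_day,
      admission_rate = admission_rate,
      outcome_prevalence = outcome_prevalence,
      drift_magnitude = drift_magnitude,
      code_replacement_rate = code_replacement_rate,
      within_group_logit_sd = within_group_logit_sd,
      chronic_parents_per_patient = as.integer(chronic_parents_per_patient),
      chronic_share = chronic_share,
      visit_rate = visit_rate,
      risk_noise_sd = risk_noise_sd,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# Per-year leaf sampling distributions. Parent mass is fixed across years;
# drift and replacement act within sibling groups only, so for every year
# sum_{leaf in parent} p(leaf) == parent weight.
leaf_frequency_table <- function(config) {
  ont <- config$ontology
  leaves <- ontology_leaves(ont)
  parent_of <- unname(ont$parent[leaves])
  parents <- unique(parent_of)
  years <- seq(config$year_range[1], config$year_range[2])
  n_years <- length(years)

  set.seed(derive_seed(config$seed, "frequencies"))
  # moderately skewed concept frequencies: skewed enough to be realistic,
  # balanced enough that no single concept dominates a replicate
  parent_w <- stats::rgamma(length(parents), shape = 6)
  parent_w <- parent_w / sum(parent_w)
  names(parent_w) <- parents

  # stationary AR(1) drift on within-group logits: the marginal
  # distribution of leaf frequencies is N(0,1) in every year (no
  # concentration artifact over time) while leaf identities decorrelate
  # at rate drift_magnitude per year boundary
  sw <- config$within_group_logit_sd %||% 2.5
  logits <- matrix(0, nrow = n_years, ncol = length(leaves))
  logits[1, ] <- stats::rnorm(length(leaves), 0, sw)
  if (n_years > 1 && config$drift_magnitude > 0) {
    rho <- exp(-config$drift_magnitude)
    for (t in 2:n_years) {
      logits[t, ] <- rho * logits[t - 1, ] +
        sqrt(1 - rho^2) * stats::rnorm(length(leaves), 0, sw)
    }
  } else if (n_years > 1) {
    for (t in 2:n_years) logits[t, ] <- logits[1, ]
  }
  # sibling-replacement permutations, composed across year boundaries
  perms <- matrix(rep(seq_along(leaves), n_years), nrow = n_years, byrow = TRUE)
  if (n_years > 1 && config$code_replacement_rate > 0) {
    cur <- seq_along(leaves)
    for (t in 2:n_years) {
      for (p in parents) {
        idx <- which(parent_of == p)
        if (length(idx) < 2) next
        hit <- idx[stats::runif(length(idx)) < config$code_replacement_rate]
        for (i in hit) {
          j <- sample(setdiff(idx, i), 1)
          tmp <- cur[i]; cur[i] <- cur[j]; cur[j] <- tmp
        }
      }
      perms[t, ] <- cur
    }
  }

  prob <- matrix(0, nrow = n_years, ncol = length(leaves),
                 dimnames = list(years, leaves))
  for (t in seq_len(n_years)) {
    logit_t <- logits[t, ]
    q <- numeric(length(leaves))
    for (p in parents) {
      idx <- which(parent_of == p)
      w <- exp(logit_t[idx] - max(logit_t[idx]))
      q[idx] <- parent_w[[p]] * w / sum(w)
    }
    # leaf i in year t is emitted with the frequency slot of perms[t, i]
    prob[t, perms[t, ]] <- q
  }
  list(years = years, leaves = leaves, parent_of = parent_of,
       parents = parents, parent_weight = parent_w, prob = prob,
       leaf_idx_by_parent = lapply(stats::setNames(parents, parents),
                                   function(p) which(parent_of == p)))
}

# Latent outcome model: fixed linear function of parent indicators plus
# demographics; coefficients drawn once per seed.
draw_risk_model <- function(config, freq) {
  set.seed(derive_seed(config$seed, "risk-model"))
  n_par <- length(freq$parents)
  beta <- matrix(stats::rnorm(n_par * length(TASKS)),
                 nrow = n_par, dimnames = list(freq$parents, TASKS))
  # standardize each task's effect-size vector so every replicate has the
  # same total signal strength (0.9 per-parent root-mean-square)
  beta <- sweep(beta, 2, sqrt(colMeans(beta^2)), "/") * 0.9
  demo <- rbind(
    age = stats::rnorm(length(TASKS), 0.4, 0.2),
    sexF = stats::rnorm(length(TASKS), 0, 0.3)
  )
  colnames(demo) <- TASKS
  # mortality risk is purely code-based: tying death to persistent
  # demographics would selectively remove high-risk patients over calendar
  # time and break the designed time-invariance of the outcome signal
  demo[, "mortality"] <- 0
  list(beta = beta, demo = demo)
}

# linear risk scores (one per task) from a parent-indicator vector
risk_scores <- function(active_parents, age_years, sex, model, freq) {
  z <- as.numeric(freq$parents %in% active_parents)
  demo_x <- c(age = (age_years - 60) / 20, sexF = as.numeric(sex == "F"))
  drop(z %*% model$beta) + drop(demo_x %*% model$demo)
}

RISK_WINDOW_DAYS <- 30L

# Calibrate per-task intercepts so that mean sigmoid(a + s) over a
# Monte-Carlo sample of reference-period risk scores hits the target
# prevalence. The pseudo-sample mirrors the generator's own window model:
# admission-day codes plus ~180 days of outpatient history (and possibly a
# recent prior admission).
calibrate_intercepts <- function(config, freq, model, n_mc = 20000L) {
  set.seed(derive_seed(config$seed, "calibration"))
  ref_years <- seq(config$year_range[1],
                   min(config$year_range[1] + 3L, config$year_range[2]))
  ref_rows <- match(ref_years, freq$years)
  n_leaves <- length(freq$leaves)

  # admission offset within the reference period; the lookback window is
  # truncated at the start of the record, exactly as in generation
  ref_span <- length(ref_years) * 365L
  offsets <- sample.int(ref_span, n_mc, replace = TRUE) - 1L
  win <- pmin(RISK_WINDOW_DAYS, offsets + 1L)
  amb_days <- stats::rpois(n_mc, config$visit_rate * win / 365)
  prior_adm <- stats::runif(n_mc) <
    (1 - exp(-config$admission_rate * win / 365))
  prior_days <- ifelse(prior_adm, 1 + stats::rpois(n_mc, 2), 0)

  ages <- sample_age_years(n_mc) + offsets / 365
  sexes <- sample(c("F", "M"), n_mc, replace = TRUE)

  scores <- matrix(0, nrow = n_mc, ncol = length(TASKS),
                   dimnames = list(NULL, TASKS))
  k_chr <- min(config$chronic_parents_per_patient, length(freq$parents))
  for (i in seq_len(n_mc)) {
    yr_row <- ref_rows[offsets[i] %/% 365L + 1L]
    chronic <- if (k_chr > 0) {
      sample(freq$parents, k_chr, prob = freq$parent_weight)
    } else character(0)
    codes <- c(
      sample_day_codes(amb_days[i] + 1L, config$events_per_day - 1, freq,
                       yr_row, chronic, config$chronic_share)$codes,
      if (prior_days[i] > 0) {
        sample_day_codes(prior_days[i], 2 * config$events_per_day - 1, freq,
                         yr_row, chronic, config$chronic_share)$codes
      })
    act <- unique(freq$parent_of[match(unique(codes), freq$leaves)])
    scores[i, ] <- risk_scores(act, ages[i], sexes[i], model, freq)
  }
  noise <- matrix(stats::rnorm(n_mc * length(TASKS), 0, config$risk_noise_sd),
                  nrow = n_mc)
  scores <- scores + noise

  vapply(TASKS, function(task) {
    target <- config$outcome_prevalence[[task]]
    s <- scores[, task]
    stats::uniroot(function(a) mean(sigmoid(a + s)) - target,
                   lower = -30, upper = 30, tol = 1e-10)$root
  }, numeric(1))
}

# mixture of adult-dominated ages with a pediatric tail, so the task
# cohort's adult filter has something to exclude
sample_age_years <- function(n) {
  ped <- stats::runif(n) < 0.10
  age <- 18 + 72 * stats::rbeta(n, 2, 2.2)
  age[ped] <- stats::runif(sum(ped), 0, 18)
  age
}

# Codes for a block of event days: each draw comes from the patient's
# chronic parents with probability `share` (leaf chosen by the year's
# within-parent distribution), otherwise from the year's background leaf
# distribution.
sample_day_codes <- function(n_days, mean_extra, freq, yr_row,
                             chronic = character(0), share = 0) {
  n_codes <- 1L + stats::rpois(n_days, mean_extra)
  m <- sum(n_codes)
  idx <- integer(m)
  is_chr <- if (length(chronic) > 0 && share > 0) {
    stats::runif(m) < share
  } else rep(FALSE, m)
  nb <- sum(!is_chr)
  if (nb > 0) {
    idx[!is_chr] <- sample.int(length(freq$leaves), nb, replace = TRUE,
                               prob = freq$prob[yr_row, ])
  }
  if (any(is_chr)) {
    pars <- chronic[sample.int(length(chronic), sum(is_chr), replace = TRUE)]
    wchr <- which(is_chr)
    for (p in unique(pars)) {
      sel <- wchr[pars == p]
      li <- freq$leaf_idx_by_parent[[p]]
      idx[sel] <- li[sample.int(length(li), length(sel), replace = TRUE,
                                prob = freq$prob[yr_row, li])]
    }
  }
  list(codes = freq$leaves[idx], day_of = rep(seq_len(n_days), n_codes))
}

# One simulation pass over n_patients patients. Returns per-patient event /
# admission / demographic tables and (optionally) the realized latent risk
# scores of reference-period admissions, used for intercept self-calibration.
simulate_patients <- function(config, freq, model, intercepts, n_patients,
                              stream, collect_scores = FALSE) {
  ont <- config$ontology
  leaf_domain <- unname(ont$domain[freq$leaves])
  start_day <- year_start_day(config$year_range[1], config$year_range[1])
  end_day <- year_start_day(config$year_range[2] + 1L, config$year_range[1]) - 1L
  span <- end_day - start_day + 1L
  p_adm_day <- config$admission_rate / 365
  ref_last_year <- min(config$year_range[1] + 3L, config$year_range[2])
  ref_end_day <- year_start_day(ref_last_year + 1L, config$year_range[1]) - 1L

  year_row_of_day <- function(day) {
    match(day_to_year(day, config$year_range[1]), freq$years)
  }

  set.seed(derive_seed(config$seed, stream))
  ev_list <- vector("list", n_patients)
  adm_list <- vector("list", n_patients)
  demo_list <- vector("list", n_patients)
  score_list <- list()

  for (pid_i in seq_len(n_patients)) {
    pid <- sprintf("P%06d", pid_i)
    age0 <- sample_age_years(1)
    birth_day <- as.integer(round(start_day - age0 * 365))
    sex <- sample(c("F", "M"), 1)
    race <- sample(c("white", "black", "asian", "pacific", "other"), 1,
                   prob = c(0.5, 0.15, 0.2, 0.05, 0.1))
    ethnicity <- sample(c("hispanic", "non-hispanic"), 1, prob = c(0.2, 0.8))
    demo_list[[pid_i]] <- data.frame(
      patient_id = pid, birth_day = birth_day, sex = sex, race = race,
      ethnicity = ethnicity, stringsAsFactors = FALSE
    )
    k_chr <- min(config$chronic_parents_per_patient, length(freq$parents))
    chronic <- if (k_chr > 0) {
      sample(freq$parents, k_chr, prob = freq$parent_weight)
    } else character(0)

    # outpatient event days over the whole span, codes drawn per year block
    n_amb <- stats::rpois(1, config$visit_rate * span / 365)
    amb_days <- if (n_amb > 0) {
      sort(sample.int(span, min(n_amb, span))) + start_day - 1L
    } else integer(0)

    ev_days <- integer(0)   # one entry per event row
    ev_codes <- character(0)
    for (yr_row in unique(year_row_of_day(amb_days))) {
      d_yr <- amb_days[year_row_of_day(amb_days) == yr_row]
      drawn <- sample_day_codes(length(d_yr), config$events_per_day - 1,
                                freq, yr_row, chronic, config$chronic_share)
      ev_days <- c(ev_days, d_yr[drawn$day_of])
      ev_codes <- c(ev_codes, drawn$codes)
    }

    # sequential admission process
    adms <- list()
    death_day <- NA_integer_
    t <- start_day + stats::rgeom(1, p_adm_day)
    while (!is.na(t) && t <= end_day - 1L) {
      admit_day <- as.integer(t)
      yr_row <- year_row_of_day(admit_day)
      # codes observed on the admission day itself (visible at prediction)
      adm_codes <- sample_day_codes(1L, 2 * config$events_per_day - 1,
                                    freq, yr_row, chronic,
                                    config$chronic_share)$codes
      in_win <- ev_days > admit_day - RISK_WINDOW_DAYS & ev_days <= admit_day
      act_leaves <- unique(c(adm_codes, ev_codes[in_win]))
      act_parents <- unique(freq$parent_of[match(act_leaves, freq$leaves)])
      age_adm <- (admit_day - birth_day) / 365
      s <- risk_scores(act_parents, age_adm, sex, model, freq) +
        stats::rnorm(length(TASKS), 0, config$risk_noise_sd)
      if (collect_scores && admit_day <= ref_end_day) {
        score_list[[length(score_list) + 1L]] <- s
      }
      p_out <- sigmoid(intercepts + s)

      died <- stats::runif(1) < p_out[["mortality"]]
      long <- stats::runif(1) < p_out[["long_los"]]
      los <- if (long) 7L + stats::rgeom(1, 0.25) else
        sample(1:6, 1, prob = c(0.25, 0.25, 0.2, 0.15, 0.1, 0.05))
      discharge_day <- as.integer(min(admit_day + los - 1L, end_day))

      icu <- stats::runif(1) < p_out[["icu"]]
      icu_day <- NA_integer_
      if (icu) {
        # transfers cluster early in the stay but mostly after the first
        # day (first-day transfers are excluded from the ICU task)
        n_off <- discharge_day - admit_day + 1L
        w <- c(0.15, 0.6 ^ (seq_len(max(0L, n_off - 1L)) - 1))[seq_len(n_off)]
        off <- sample.int(n_off, 1, prob = w) - 1L
        icu_day <- admit_day + off
      }

      adms[[length(adms) + 1L]] <- data.frame(
        patient_id = pid, admit_day = admit_day,
        discharge_day = discharge_day, died = died, icu_day = icu_day,
        stringsAsFactors = FALSE
      )

      # inpatient event rows: admission-day codes plus later stay days
      ev_days <- c(ev_days, rep(admit_day, length(adm_codes)))
      ev_codes <- c(ev_codes, adm_codes)
      if (discharge_day > admit_day) {
        stay <- (admit_day + 1L):discharge_day
        drawn <- sample_day_codes(length(stay), 2 * config$events_per_day - 1,
                                  freq, yr_row, chronic,
                                  config$chronic_share)
        ev_days <- c(ev_days, stay[drawn$day_of])
        ev_codes <- c(ev_codes, drawn$codes)
      }

      if (died) {
        death_day <- discharge_day
        break
      }
      readm <- stats::runif(1) < p_out[["readmission"]]
      # non-readmission gaps keep the configured marginal admission rate
      mean_gap <- max(60, 365 / config$admission_rate - 31)
      gap <- if (readm) sample.int(30L, 1) else 31L + stats::rgeom(1, 1 / mean_gap)
      t <- discharge_day + gap
    }

    if (!is.na(death_day)) {
      keep <- ev_days <= death_day
      ev_days <- ev_days[keep]
      ev_codes <- ev_codes[keep]
    }

    if (length(ev_days) > 0) {
      dom <- leaf_domain[match(ev_codes, freq$leaves)]
      abnormal <- rep("none", length(ev_codes))
      meas <- dom == "measurement"
      flag <- meas & stats::runif(length(ev_codes)) < 0.3
      abnormal[flag] <- sample(c("above", "below"), sum(flag), replace = TRUE)
      ev_list[[pid_i]] <- data.frame(
        patient_id = pid, day = as.integer(ev_days), code = ev_codes,
        domain = dom, abnormal = abnormal, stringsAsFactors = FALSE
      )
    }
    adm_list[[pid_i]] <- if (length(adms) > 0) do.call(rbind, adms) else NULL
  }

  scores <- if (length(score_list) > 0) do.call(rbind, score_list) else NULL
  list(ev_list = ev_list, adm_list = adm_list, demo_list = demo_list,
       scores = scores)
}

#' Generate a synthetic patient population
#'
#' Simulates coded day-granular timelines, demographics and inpatient
#' admissions with four binary outcomes (hospital mortality, long length of
#' stay, 30-day readmission, ICU transfer). Outcome risk is a fixed linear
#' function of parent-level (ancestor) code indicators over a 180-day
#' lookback window plus demographics; temporal drift acts only on leaf
#' frequencies/identities, never on that signal.
#'
#' Outcome intercepts are self-calibrated: a Monte-Carlo initializer is
#' refined against the realized risk-score distribution of a pilot
#' generation pass, so that reference-period prevalences converge to the
#' configured targets.
#'
#' @param config a [generator_config()].
#' @return an `ehr_population`: list with data.tables `events`
#'   (patient_id, day, code, domain, abnormal), `demographics`
#'   (patient_id, birth_day, sex, race, ethnicity), `admissions`
#'   (patient_id, admit_day, discharge_day, died, icu_day), plus the
#'   ontology, config, and the latent risk model (for diagnostics).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  ont <- config$ontology
  freq <- leaf_frequency_table(config)
  model <- draw_risk_model(config, freq)
  intercepts0 <- calibrate_intercepts(config, freq, model)

  # refine intercepts on realized pilot scores
  n_pilot <- min(config$n_patients, 1500L)
  pilot <- simulate_patients(config, freq, model, intercepts0, n_pilot,
                             stream = "pilot", collect_scores = TRUE)
  intercepts <- intercepts0
  if (!is.null(pilot$scores) && nrow(pilot$scores) >= 50) {
    intercepts <- vapply(seq_along(TASKS), function(k) {
      target <- config$outcome_prevalence[[TASKS[k]]]
      s <- pilot$scores[, k]
      stats::uniroot(function(a) mean(sigmoid(a + s)) - target,
                     lower = -30, upper = 30, tol = 1e-10)$root
    }, numeric(1))
    names(intercepts) <- TASKS
    # a patient who dies in hospital cannot be readmitted, which deflates
    # the observed 30-day readmission prevalence; absorb that competing
    # risk into the readmission intercept
    p_die <- sigmoid(intercepts[["mortality"]] + pilot$scores[, "mortality"])
    s_r <- pilot$scores[, "readmission"]
    target_r <- config$outcome_prevalence[["readmission"]]
    if (target_r < mean(1 - p_die)) {
      intercepts[["readmission"]] <- stats::uniroot(
        function(a) mean((1 - p_die) * sigmoid(a + s_r)) - target_r,
        lower = -30, upper = 30, tol = 1e-10)$root
    }
  }

  sim <- simulate_patients(config, freq, model, intercepts,
                           config$n_patients, stream = "population")

  events <- data.table::rbindlist(Filter(Negate(is.null), sim$ev_list))
  if (nrow(events) == 0) {
    events <- data.table::data.table(
      patient_id = character(0), day = integer(0), code = character(0),
      domain = character(0), abnormal = character(0))
  }
  data.table::setorder(events, patient_id, day, code)
  admissions <- data.table::rbindlist(Filter(Negate(is.null), sim$adm_list))
  if (nrow(admissions) == 0) {
    admissions <- data.table::data.table(
      patient_id = character(0), admit_day = integer(0),
      discharge_day = integer(0), died = logical(0), icu_day = integer(0))
  }
  demographics <- data.table::rbindlist(sim$demo_list)

  structure(
    list(events = events, demographics = demographics,
         admissions = admissions, ontology = ont, config = config,
         risk_model = list(model = model, intercepts = intercepts,
                           freq = freq)),
    class = "ehr_population"
  )
}

#' @export
print.ehr_population <- function(x, ...) {
  cat("<ehr_population> ", nrow(x$demographics), " patients, ",
      nrow(x$events), " events, ", nrow(x$admissions), " admissions; years ",
      x$config$year_range[1], "-", x$config$year_range[2], "\n", sep = "")
  invisible(x)
}
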