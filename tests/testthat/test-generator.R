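test_that("generation is byte-identical under a fixed config and seed", {
  cfg <- generator_config(n_patients = 40, year_range = c(2009, 2011),
                          ontology = make_synthetic_ontology(2, 3),
                          seed = 9)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1$events, p2$events)
  expect_identical(p1$admissions, p2$admissions)
  expect_identical(p1$demographics, p2$demographics)
  p3 <- generate_population(generator_config(
    n_patients = 40, year_range = c(2009, 2011),
    ontology = make_synthetic_ontology(2, 3), seed = 10))
  expect_false(identical(p1$events, p3$events))
})

test_that("generated records satisfy the structural invariants", {
  pop <- small_population()
  leaves <- ontology_leaves(pop$ontology)
  expect_true(all(pop$events$code %in% leaves))
  expect_true(all(pop$events$abnormal[pop$events$domain != "measurement"] ==
                    "none"))
  expect_true(all(pop$events$abnormal %in% c("none", "above", "below")))
  adm <- pop$admissions
  expect_true(all(adm$discharge_day >= adm$admit_day))
  icu <- adm[!is.na(adm$icu_day), ]
  expect_true(all(icu$icu_day >= icu$admit_day &
                    icu$icu_day <= icu$discharge_day))
  # strictly increasing event days per patient after dedup
  ev <- pop$events[order(pop$events$patient_id, pop$events$day), ]
  expect_true(all(ev$day >= 0))
})

test_that("config validation rejects degenerate settings", {
  expect_error(generator_config(year_range = c(2012, 2009)), "year_range")
  expect_error(generator_config(outcome_prevalence = c(
    mortality = 0, long_los = 0.2, readmission = 0.1, icu = 0.05)),
    "\\(0, 1\\)")
  expect_error(generator_config(drift_magnitude = -1), "drift_magnitude")
  expect_error(generator_config(code_replacement_rate = 1.5),
               "replacement")
})

test_that("leaf frequencies are stationary when drift is off", {
  cfg <- generator_config(n_patients = 600, year_range = c(2009, 2012),
                          ontology = make_synthetic_ontology(2, 4),
                          drift_magnitude = 0, code_replacement_rate = 0,
                          seed = 17)
  pop <- generate_population(cfg)
  ev <- pop$events
  yr <- day_to_year(ev$day)
  first <- table(factor(ev$code[yr == 2009], levels = ontology_leaves(pop$ontology)))
  last <- table(factor(ev$code[yr == 2012], levels = ontology_leaves(pop$ontology)))
  n1 <- sum(first); n2 <- sum(last)
  pooled <- (as.numeric(first) + as.numeric(last)) / (n1 + n2)
  # exact binomial CI oracle per leaf at 99.9% (Bonferroni-ish guard)
  viol <- 0L
  for (i in seq_along(pooled)) {
    ci1 <- stats::binom.test(as.numeric(first[i]), n1, pooled[i],
                             conf.level = 0.999)$p.value
    ci2 <- stats::binom.test(as.numeric(last[i]), n2, pooled[i],
                             conf.level = 0.999)$p.value
    if (ci1 < 0.001 || ci2 < 0.001) viol <- viol + 1L
  }
  expect_lte(viol, 2L)
})

test_that("drift keeps parent-level marginals stable while moving leaves", {
  cfg <- generator_config(n_patients = 600, year_range = c(2009, 2014),
                          ontology = make_synthetic_ontology(2, 4),
                          drift_magnitude = 0.5, code_replacement_rate = 0.15,
                          seed = 23)
  pop <- generate_population(cfg)
  freq <- pop$risk_model$freq
  ev <- pop$events
  yr <- day_to_year(ev$day)
  parent <- freq$parent_of[match(ev$code, freq$leaves)]
  p_first <- prop.table(table(factor(parent[yr == 2009],
                                     levels = freq$parents)))
  p_last <- prop.table(table(factor(parent[yr == 2014],
                                    levels = freq$parents)))
  expect_lt(max(abs(as.numeric(p_first) - as.numeric(p_last))), 0.05)
  l_first <- prop.table(table(factor(ev$code[yr == 2009], levels = freq$leaves)))
  l_last <- prop.table(table(factor(ev$code[yr == 2014], levels = freq$leaves)))
  expect_gt(max(abs(as.numeric(l_first) - as.numeric(l_last))), 0.05)
})

test_that("configured prevalences are recovered in the reference years", {
  cfg <- generator_config(n_patients = 5000, year_range = c(2009, 2012),
                          ontology = make_synthetic_ontology(2, 4),
                          seed = 31)
  pop <- generate_population(cfg)
  adm <- pop$admissions
  n <- nrow(adm)
  for (task in c("long_los", "icu", "mortality")) {
    observed <- switch(task,
      long_los = mean(adm$discharge_day - adm$admit_day >= 6),
      icu = mean(!is.na(adm$icu_day)),
      mortality = mean(adm$died))
    target <- cfg$outcome_prevalence[[task]]
    ci <- stats::binom.test(round(observed * n), n,
                            target, conf.level = 0.99)$conf.int
    expect_true(target >= ci[1] && target <= ci[2],
                label = sprintf("%s observed %.4f target %.3f n %d",
                                task, observed, target, n))
  }
})

test_that("ancestor-level risk distribution is invariant under leaf drift", {
  cfg <- generator_config(n_patients = 800, year_range = c(2009, 2014),
                          ontology = make_synthetic_ontology(2, 4),
                          drift_magnitude = 0.5, code_replacement_rate = 0.15,
                          seed = 37)
  pop <- generate_population(cfg)
  freq <- pop$risk_model$freq
  model <- pop$risk_model$model
  ev <- data.table::as.data.table(pop$events)
  adm <- data.table::as.data.table(pop$admissions)
  scores <- function(rows) {
    vapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i]
      e <- ev[ev$patient_id == r$patient_id &
                ev$day > r$admit_day - 30 & ev$day <= r$admit_day, ]
      act <- unique(freq$parent_of[match(unique(e$code), freq$leaves)])
      sum(model$beta[freq$parents %in% act, "long_los"])
    }, numeric(1))
  }
  early <- adm[day_to_year(adm$admit_day) <= 2010]
  late <- adm[day_to_year(adm$admit_day) >= 2013]
  s_early <- scores(early)
  s_late <- scores(late)
  # direct recomputation oracle: same latent-score distribution early/late
  expect_gt(stats::ks.test(s_early, s_late)$p.value, 0.001)
  expect_lt(abs(mean(s_early) - mean(s_late)),
            3 * sqrt(var(s_early) / length(s_early) +
                       var(s_late) / length(s_late)) + 0.05)
})

test_that("with drift off, code-frequency shift tests reject at type-I rate", {
  # codes cluster within patients (chronic conditions), so the valid null
  # test permutes year labels within each patient's event days
  chisq_stat <- function(code, year, levels) {
    tab <- table(factor(code, levels = levels), year)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    suppressWarnings(stats::chisq.test(tab)$statistic)
  }
  rejections <- 0L
  n_seeds <- 8L
  for (s in seq_len(n_seeds)) {
    cfg <- generator_config(n_patients = 120, year_range = c(2009, 2011),
                            ontology = make_synthetic_ontology(2, 3),
                            drift_magnitude = 0, code_replacement_rate = 0,
                            seed = 100 + s)
    pop <- generate_population(cfg)
    lv <- ontology_leaves(pop$ontology)
    ev <- pop$events[day_to_year(pop$events$day) %in% c(2009, 2011), ]
    ev$year <- day_to_year(ev$day)
    obs <- chisq_stat(ev$code, ev$year, lv)
    # permute year labels at the patient-day level
    key <- paste(ev$patient_id, ev$day)
    day_year <- tapply(ev$year, key, `[`, 1)
    day_pat <- tapply(ev$patient_id, key, `[`, 1)
    set.seed(1000 + s)
    perm_stats <- replicate(120, {
      new_year <- unlist(lapply(split(seq_along(day_year), day_pat),
                                function(ix) sample(day_year[ix])),
                         use.names = FALSE)
      names(new_year) <- unlist(split(names(day_year), day_pat),
                                use.names = FALSE)
      chisq_stat(ev$code, new_year[key], lv)
    })
    p <- mean(perm_stats >= obs)
    if (p < 0.05) rejections <- rejections + 1L
  }
  # 8 trials at alpha = .05: P(>3 rejections) < 1e-3 under the null
  expect_lte(rejections, 3L)
})
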