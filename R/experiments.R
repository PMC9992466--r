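# Experiment orchestration: baseline count-LR trajectory with per-year
# oracles, Experiment 1 (ID/OOD robustness of CLMBR-LR vs count-LR vs
# ETE, plus the pretraining/downstream correlation), Experiment 2
# (pretraining-size scaling), and reporting. All randomness flows from a
# single root seed through named substreams.

#' Configuration for an experiment run
#'
#' @param generator a [generator_config()]; defines the synthetic study
#'   population.
#' @param id_years inclusive in-distribution year range (default
#'   2009-2012).
#' @param ood_year_groups list of inclusive OOD year ranges (default
#'   2013-2016 and 2017-2021).
#' @param pretrain_years year range for pretraining timelines.
#' @param encoder a [pretrain_config()] template (architecture is
#'   overridden per run).
#' @param architectures encoders to run (`gru`, `transformer`).
#' @param tasks tasks to evaluate.
#' @param size_ladder increasing pretraining set sizes (Experiment 2).
#' @param exp2_head_years years whose admissions train the task heads in
#'   Experiment 2.
#' @param exp2_ood_years OOD evaluation years for Experiment 2.
#' @param split_fractions train/val/test fractions for the task cohort.
#' @param pretrain_cap optional ceiling on the number of pretraining
#'   patients (seeded subsample); NULL uses the whole pretraining cohort.
#' @param ood_eval_splits splits evaluated in the OOD year groups
#'   (default `"test"`; `c("val", "test")` is leakage-safe too, since both
#'   are excluded from pretraining and OOD rows play no role in head
#'   selection, and roughly doubles the evaluation sample).
#' @param n_boot bootstrap samples for confidence intervals.
#' @param min_count count-feature pruning threshold.
#' @param l2_grid penalty grid for logistic heads.
#' @param hyper_grid list of named lists of [pretrain_config()] overrides
#'   for the correlation analysis (Experiment 1).
#' @param seed root seed.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(generator = generator_config(),
                              id_years = c(2009L, 2012L),
                              ood_year_groups = list(c(2013L, 2016L),
                                                     c(2017L, 2021L)),
                              pretrain_years = NULL,
                              encoder = pretrain_config(),
                              architectures = "gru",
                              tasks = TASKS,
                              size_ladder = NULL,
                              exp2_head_years = NULL,
                              exp2_ood_years = NULL,
                              split_fractions = c(train = 0.8, val = 0.1,
                                                  test = 0.1),
                              pretrain_cap = NULL,
                              ood_eval_splits = "test",
                              n_boot = 1000L,
                              min_count = 25L,
                              l2_grid = DEFAULT_L2_GRID,
                              hyper_grid = list(
                                list(learning_rate = 5e-3),
                                list(learning_rate = 1e-3),
                                list(learning_rate = 2e-2)),
                              seed = 1L) {
  for (g in ood_year_groups) {
    if (g[1] <= id_years[2] && g[2] >= id_years[1]) {
      stop("ID and OOD year groups must be disjoint")
    }
  }
  if (!is.null(size_ladder) && any(diff(size_ladder) <= 0)) {
    stop("size ladder must be strictly increasing")
  }
  structure(
    list(generator = generator, id_years = as.integer(id_years),
         ood_year_groups = lapply(ood_year_groups, as.integer),
         pretrain_years = as.integer(pretrain_years %||% id_years),
         encoder = encoder, architectures = architectures,
         tasks = tasks, size_ladder = size_ladder,
         exp2_head_years = as.integer(exp2_head_years %||%
                                        c(id_years[1],
                                          generator$year_range[2] - 2L)),
         exp2_ood_years = as.integer(exp2_ood_years %||%
                                       c(generator$year_range[2] - 1L,
                                         generator$year_range[2])),
         split_fractions = split_fractions,
         pretrain_cap = pretrain_cap,
         ood_eval_splits = ood_eval_splits,
         n_boot = as.integer(n_boot), min_count = as.integer(min_count),
         l2_grid = l2_grid, hyper_grid = hyper_grid,
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

year_group_label <- function(years) paste0(years[1], "-", years[2])

epoch_of <- function(config) config$generator$year_range[1]

# Shared scaffolding: population, task cohort with splits, and the
# leakage-safe pretraining cohort.
prepare_study <- function(config, population = NULL) {
  if (is.null(population)) {
    gen <- config$generator
    gen$seed <- derive_seed(config$seed, "generator")
    population <- generate_population(gen)
  }
  tt <- build_task_cohort(population, seed = derive_seed(config$seed, "cohort"),
                          epoch_year = epoch_of(config))
  split <- split_patients(tt$patient_id, fractions = config$split_fractions,
                          seed = derive_seed(config$seed, "task-split"))
  tt$split <- unname(split[tt$patient_id])

  held_out <- tt$patient_id[tt$split %in% c("val", "test")]
  spec <- cohort_spec(config$pretrain_years, excluded_patients = held_out)
  pre <- build_pretraining_cohort(population, spec,
                                  epoch_year = epoch_of(config))
  if (!is.null(config$pretrain_cap) &&
      length(pre$patient_ids) > config$pretrain_cap) {
    set.seed(derive_seed(config$seed, "pretrain-cap"))
    pre$patient_ids <- sort(sample(pre$patient_ids, config$pretrain_cap))
    pre$events <- pre$events[pre$events$patient_id %in% pre$patient_ids, ]
  }
  assert_no_leakage(pre$patient_ids, tt)
  list(population = population, task_table = tt, pretrain = pre)
}

task_eval_sets <- function(config, task_table, task) {
  eli <- task_table[[paste0("eligible_", task)]]
  id_sel <- task_table$year >= config$id_years[1] &
    task_table$year <= config$id_years[2]
  list(
    train = which(eli & id_sel & task_table$split == "train"),
    val = which(eli & id_sel & task_table$split == "val"),
    id_test = which(eli & id_sel & task_table$split == "test"),
    ood_test = lapply(config$ood_year_groups, function(g) {
      which(eli & task_table$year >= g[1] & task_table$year <= g[2] &
              task_table$split == "test")
    })
  )
}

metric_rows <- function(labels, probs, pi_ref, n_boot, seed, meta) {
  ests <- list(
    auroc = bootstrap_summary(auroc, labels, probs, n_boot = n_boot,
                              seed = seed, name = "auroc"),
    auprc_c = bootstrap_summary(auprc_c, labels, probs, n_boot = n_boot,
                                seed = seed, reference_prevalence = pi_ref,
                                name = "auprc_c"),
    ace = bootstrap_summary(ace, labels, probs, n_boot = n_boot,
                            seed = seed, name = "ace")
  )
  data.table::rbindlist(lapply(names(ests), function(m) {
    e <- ests[[m]]
    data.table::data.table(meta, metric = m, point = e$point,
                           boot_median = e$boot_median, ci_low = e$ci_low,
                           ci_high = e$ci_high, n = length(labels),
                           n_boot = n_boot)
  }))
}

#' Baseline experiment: count-LR over calendar years with per-year oracles
#'
#' Trains a count-feature logistic head on the ID years and evaluates on
#' the test rows of every calendar year; fits an oracle within each OOD
#' year for comparison.
#'
#' @param config an [experiment_config()].
#' @param population optional pre-generated `ehr_population`.
#' @return list with the metric table (`metrics`), the task table, and a
#'   manifest of seeds.
#' @export
run_baseline <- function(config, population = NULL) {
  study <- prepare_study(config, population)
  tt <- study$task_table
  pop <- study$population
  all_years <- sort(unique(tt$year))
  ood_years <- setdiff(all_years,
                       seq(config$id_years[1], config$id_years[2]))
  out <- list()
  for (task in config$tasks) {
    feats <- featurize_cohort(pop, tt, task)
    sets <- task_eval_sets(config, tt, task)
    lab <- tt[[paste0("label_", task)]]
    eli <- tt[[paste0("eligible_", task)]]
    vocab <- fit_vocabulary(feats[sets$train], min_count = config$min_count)
    head <- train_linear_head(encode_matrix(feats[sets$train], vocab),
                              lab[sets$train],
                              encode_matrix(feats[sets$val], vocab),
                              lab[sets$val], l2_grid = config$l2_grid,
                              seed = config$seed)
    pi_ref <- mean(lab[c(sets$train, sets$val, sets$id_test)])
    oracles <- train_oracles(tt, feats, task, ood_years,
                             min_count = config$min_count,
                             l2_grid = config$l2_grid, seed = config$seed)
    for (yr in all_years) {
      te <- which(eli & tt$year == yr & tt$split == "test")
      if (length(te) < 10 || length(unique(lab[te])) < 2) next
      p <- predict_proba(head, encode_matrix(feats[te], vocab))
      out[[length(out) + 1L]] <- metric_rows(
        lab[te], p, pi_ref, config$n_boot,
        derive_seed(config$seed, paste0("eval-", task, "-", yr)),
        data.table::data.table(model = "count-LR", task = task, year = yr))
      orc <- oracles[[as.character(yr)]]
      if (!is.null(orc)) {
        p_o <- predict_proba(orc$model, encode_matrix(feats[te], orc$vocab))
        out[[length(out) + 1L]] <- metric_rows(
          lab[te], p_o, pi_ref, config$n_boot,
          derive_seed(config$seed, paste0("oracle-", task, "-", yr)),
          data.table::data.table(model = "oracle", task = task, year = yr))
      }
    }
  }
  list(metrics = data.table::rbindlist(out), task_table = tt,
       manifest = run_manifest(config))
}

# fit heads for one representation type and evaluate ID + OOD groups
eval_model_idood <- function(config, tt, task, probs_by_set, model_name,
                             pi_ref, lab) {
  out <- list()
  groups <- c(list(id = config$id_years), config$ood_year_groups)
  names(groups) <- c(year_group_label(config$id_years),
                     vapply(config$ood_year_groups, year_group_label, ""))
  for (gname in names(groups)) {
    sel <- probs_by_set[[gname]]
    if (is.null(sel) || length(sel$rows) < 10 ||
        length(unique(lab[sel$rows])) < 2) next
    out[[length(out) + 1L]] <- metric_rows(
      lab[sel$rows], sel$probs, pi_ref, config$n_boot,
      derive_seed(config$seed, paste0("eval-", model_name, "-", task, "-",
                                      gname)),
      data.table::data.table(model = model_name, task = task,
                             year_group = gname))
  }
  data.table::rbindlist(out)
}

#' Experiment 1: robustness of CLMBR-LR vs count-LR vs ETE
#'
#' Pretrains an encoder per architecture on the leakage-safe pretraining
#' cohort, adapts logistic heads on frozen representations (z-scored by
#' training statistics) and on count features, trains end-to-end
#' baselines, and evaluates all models in the ID and OOD year groups.
#' Also emits the OOD-minus-ID decay per model and the Pearson
#' correlation between pretraining validation loss and downstream head
#' validation BCE across hyperparameter settings.
#'
#' @param config an [experiment_config()].
#' @param population optional pre-generated population.
#' @param with_ete train end-to-end baselines.
#' @param with_correlation run the hyperparameter-grid correlation
#'   analysis.
#' @return list with `metrics`, `decays`, `correlations`, the task table
#'   and manifest.
#' @export
run_experiment1 <- function(config, population = NULL, with_ete = TRUE,
                            with_correlation = TRUE) {
  study <- prepare_study(config, population)
  tt <- study$task_table
  pop <- study$population
  groups <- c(list(config$id_years), config$ood_year_groups)
  gnames <- vapply(groups, year_group_label, "")

  rows_of_group <- function(task, g, ood = FALSE) {
    eli <- tt[[paste0("eligible_", task)]]
    splits <- if (ood) config$ood_eval_splits else "test"
    which(eli & tt$year >= g[1] & tt$year <= g[2] & tt$split %in% splits)
  }

  metrics <- list()
  decays <- list()
  correlations <- list()

  encoders <- list()
  for (arch in config$architectures) {
    enc_cfg <- config$encoder
    enc_cfg$architecture <- arch
    enc_cfg$seed <- derive_seed(config$seed, paste0("pretrain-", arch))
    encoders[[arch]] <- pretrain(pop, enc_cfg,
                                 patient_ids = study$pretrain$patient_ids)
  }

  for (task in config$tasks) {
    feats <- featurize_cohort(pop, tt, task)
    sets <- task_eval_sets(config, tt, task)
    lab <- tt[[paste0("label_", task)]]
    pi_ref <- mean(lab[c(sets$train, sets$val, sets$id_test)])

    # count-LR
    vocab <- fit_vocabulary(feats[sets$train], min_count = config$min_count)
    count_head <- train_linear_head(
      encode_matrix(feats[sets$train], vocab), lab[sets$train],
      encode_matrix(feats[sets$val], vocab), lab[sets$val],
      l2_grid = config$l2_grid, seed = config$seed)
    probs_fns <- list(
      "count-LR" = function(rows) {
        predict_proba(count_head, encode_matrix(feats[rows], vocab))
      })

    # CLMBR-LR per architecture
    for (arch in names(encoders)) {
      reps <- extract_representations(encoders[[arch]], tt, pop, task)
      zs <- standardize_by_train(reps[sets$train, , drop = FALSE],
                                 all = reps)
      Z_all <- zs$all
      clmbr_head <- train_linear_head(
        Z_all[sets$train, , drop = FALSE], lab[sets$train],
        Z_all[sets$val, , drop = FALSE], lab[sets$val],
        l2_grid = config$l2_grid, seed = config$seed)
      local({
        Z <- Z_all; h <- clmbr_head
        probs_fns[[paste0("CLMBR-LR-", arch)]] <<- function(rows) {
          predict_proba(h, Z[rows, , drop = FALSE])
        }
      })
    }

    # ETE per architecture (trained on ID-years task rows only)
    if (with_ete) {
      for (arch in config$architectures) {
        ete_cfg <- config$encoder
        ete_cfg$architecture <- arch
        ete_cfg$seed <- derive_seed(config$seed, paste0("ete-", arch, task))
        id_rows <- tt$year >= config$id_years[1] &
          tt$year <= config$id_years[2]
        tt_id <- tt[id_rows]
        ete <- train_ete(pop, tt_id, task, ete_cfg)
        local({
          m <- ete
          probs_fns[[paste0("ETE-", arch)]] <<- function(rows) {
            predict_proba(m, NULL, population = pop,
                          task_table = tt[rows])
          }
        })
      }
    }

    for (model_name in names(probs_fns)) {
      probs_by_set <- list()
      for (k in seq_along(groups)) {
        rows <- rows_of_group(task, groups[[k]], ood = k > 1)
        if (length(rows) < 10 || length(unique(lab[rows])) < 2) next
        probs_by_set[[gnames[k]]] <- list(rows = rows,
                                          probs = probs_fns[[model_name]](rows))
      }
      metrics[[length(metrics) + 1L]] <-
        eval_model_idood(config, tt, task, probs_by_set, model_name,
                         pi_ref, lab)
      # decay = OOD - ID per metric (point estimates)
      idg <- gnames[1]
      if (!is.null(probs_by_set[[idg]])) {
        for (k in seq_along(config$ood_year_groups)) {
          gname <- gnames[k + 1]
          if (is.null(probs_by_set[[gname]])) next
          id_sel <- probs_by_set[[idg]]
          ood_sel <- probs_by_set[[gname]]
          for (mfun in c("auroc", "auprc_c", "ace")) {
            f <- switch(mfun, auroc = auroc,
                        auprc_c = function(l, p) auprc_c(l, p, pi_ref),
                        ace = ace)
            decays[[length(decays) + 1L]] <- data.table::data.table(
              model = model_name, task = task, metric = mfun,
              ood_group = gname,
              id_value = f(lab[id_sel$rows], id_sel$probs),
              ood_value = f(lab[ood_sel$rows], ood_sel$probs))
          }
        }
      }
    }

    # pretraining-loss vs downstream-BCE correlation across hyperparameters
    if (with_correlation && length(config$hyper_grid) >= 3) {
      for (arch in config$architectures) {
        pre_losses <- numeric(0)
        head_bces <- list()
        for (hi in seq_along(config$hyper_grid)) {
          hcfg <- config$encoder
          hcfg$architecture <- arch
          for (nm in names(config$hyper_grid[[hi]])) {
            hcfg[[nm]] <- config$hyper_grid[[hi]][[nm]]
          }
          hcfg$seed <- derive_seed(config$seed, paste0("hyper-", arch, hi))
          enc_h <- pretrain(pop, hcfg,
                            patient_ids = study$pretrain$patient_ids)
          pre_losses <- c(pre_losses, enc_h$best_val_loss)
          reps_h <- extract_representations(enc_h, tt, pop, task)
          zs_h <- standardize_by_train(reps_h[sets$train, , drop = FALSE],
                                       all = reps_h)
          head_h <- train_linear_head(
            zs_h$all[sets$train, , drop = FALSE], lab[sets$train],
            zs_h$all[sets$val, , drop = FALSE], lab[sets$val],
            l2_grid = config$l2_grid, seed = config$seed)
          for (k in seq_along(groups)) {
            rows <- rows_of_group(task, groups[[k]], ood = k > 1)
            if (length(rows) < 10 || length(unique(lab[rows])) < 2) next
            p <- predict_proba(head_h, zs_h$all[rows, , drop = FALSE])
            key <- gnames[k]
            head_bces[[key]] <- c(head_bces[[key]], bce_loss(lab[rows], p))
          }
        }
        for (key in names(head_bces)) {
          if (length(head_bces[[key]]) == length(pre_losses) &&
              stats::sd(pre_losses) > 0 && stats::sd(head_bces[[key]]) > 0) {
            correlations[[length(correlations) + 1L]] <-
              data.table::data.table(
                architecture = arch, task = task, year_group = key,
                r = pearson_correlation(pre_losses, head_bces[[key]]),
                n_settings = length(pre_losses))
          }
        }
      }
    }
  }

  list(metrics = data.table::rbindlist(metrics, fill = TRUE),
       decays = data.table::rbindlist(decays),
       correlations = data.table::rbindlist(correlations),
       task_table = tt, manifest = run_manifest(config))
}

#' Experiment 2: scaling of pretraining set size
#'
#' Pretrains each architecture on nested subsets of the pretraining
#' cohort (larger sets contain the smaller ones), adapts logistic heads,
#' evaluates ID and OOD, and fits the scaling slope of each metric
#' against log10(pretraining patients). Also emits the reclassification
#' analysis of the best (largest-set transformer, if run, otherwise
#' largest-set) CLMBR-LR against count-LR.
#'
#' @param config an [experiment_config()] with a `size_ladder`.
#' @param population optional pre-generated population.
#' @return list with `scaling` (per-size metrics), `slopes`,
#'   `reclassification`, task table and manifest.
#' @export
run_experiment2 <- function(config, population = NULL) {
  stopifnot(!is.null(config$size_ladder))
  study <- prepare_study(config, population)
  tt <- study$task_table
  pop <- study$population
  pre_ids <- study$pretrain$patient_ids
  if (max(config$size_ladder) > length(pre_ids)) {
    stop("size ladder exceeds the pretraining cohort (",
         length(pre_ids), " patients)")
  }
  set.seed(derive_seed(config$seed, "ladder"))
  shuffled <- sample(pre_ids)
  subsets <- lapply(config$size_ladder, function(k) sort(shuffled[seq_len(k)]))

  head_sel <- tt$year >= config$exp2_head_years[1] &
    tt$year <= config$exp2_head_years[2]
  ood_sel <- tt$year >= config$exp2_ood_years[1] &
    tt$year <= config$exp2_ood_years[2]
  id_sel <- tt$year >= config$id_years[1] & tt$year <= config$id_years[2]

  rows <- list()
  best_probs <- list() # for reclassification: largest size per arch
  count_probs <- list()
  for (task in config$tasks) {
    feats <- featurize_cohort(pop, tt, task)
    lab <- tt[[paste0("label_", task)]]
    eli <- tt[[paste0("eligible_", task)]]
    tr <- which(eli & head_sel & tt$split == "train")
    va <- which(eli & head_sel & tt$split == "val")
    te_id <- which(eli & id_sel & tt$split == "test")
    te_ood <- which(eli & ood_sel & tt$split == "test")
    pi_ref <- mean(lab[which(eli & id_sel)])
    vocab <- fit_vocabulary(feats[tr], min_count = config$min_count)
    count_head <- train_linear_head(
      encode_matrix(feats[tr], vocab), lab[tr],
      encode_matrix(feats[va], vocab), lab[va],
      l2_grid = config$l2_grid, seed = config$seed)
    count_probs[[task]] <- list(
      id = list(rows = te_id,
                probs = predict_proba(count_head,
                                      encode_matrix(feats[te_id], vocab))),
      ood = list(rows = te_ood,
                 probs = predict_proba(count_head,
                                       encode_matrix(feats[te_ood], vocab))))

    for (arch in config$architectures) {
      for (si in seq_along(subsets)) {
        enc_cfg <- config$encoder
        enc_cfg$architecture <- arch
        enc_cfg$seed <- derive_seed(config$seed, paste0("exp2-", arch, si))
        enc <- pretrain(pop, enc_cfg, patient_ids = subsets[[si]])
        reps <- extract_representations(enc, tt, pop, task)
        zs <- standardize_by_train(reps[tr, , drop = FALSE], all = reps)
        headm <- train_linear_head(zs$all[tr, , drop = FALSE], lab[tr],
                                   zs$all[va, , drop = FALSE], lab[va],
                                   l2_grid = config$l2_grid,
                                   seed = config$seed)
        for (grp in c("id", "ood")) {
          te <- if (grp == "id") te_id else te_ood
          if (length(te) < 10 || length(unique(lab[te])) < 2) next
          p <- predict_proba(headm, zs$all[te, , drop = FALSE])
          for (mfun in c("auroc", "auprc_c", "ace")) {
            f <- switch(mfun, auroc = auroc,
                        auprc_c = function(l, q) auprc_c(l, q, pi_ref),
                        ace = ace)
            rows[[length(rows) + 1L]] <- data.table::data.table(
              architecture = arch, task = task,
              pretrain_size = config$size_ladder[si],
              year_group = if (grp == "id")
                year_group_label(config$id_years)
              else year_group_label(config$exp2_ood_years),
              metric = mfun, value = f(lab[te], p))
          }
          if (si == length(subsets)) {
            best_probs[[paste(task, arch, grp)]] <-
              list(rows = te, probs = p)
          }
        }
      }
    }
  }
  scaling <- data.table::rbindlist(rows)

  # slopes per (architecture, task, metric, year group)
  slopes <- scaling[, list(slope = scaling_slope(pretrain_size, value)),
                    by = c("architecture", "task", "metric", "year_group")]

  # reclassification: best CLMBR-LR (transformer if present) vs count-LR
  best_arch <- if ("transformer" %in% config$architectures) "transformer"
  else config$architectures[1]
  reclass <- list()
  for (task in config$tasks) {
    for (grp in c("id", "ood")) {
      key <- paste(task, best_arch, grp)
      if (is.null(best_probs[[key]])) next
      cp <- count_probs[[task]][[grp]]
      bp <- best_probs[[key]]
      stopifnot(identical(cp$rows, bp$rows))
      lab <- tt[[paste0("label_", task)]]
      rc <- reclassification(lab[cp$rows], cp$probs, bp$probs)
      rc$task <- task
      rc$year_group <- if (grp == "id") year_group_label(config$id_years)
      else year_group_label(config$exp2_ood_years)
      reclass[[length(reclass) + 1L]] <- rc
    }
  }

  list(scaling = scaling, slopes = slopes,
       reclassification = data.table::rbindlist(reclass),
       pretrain_subsets = subsets,
       task_table = tt, manifest = run_manifest(config))
}

run_manifest <- function(config) {
  list(seed = config$seed,
       generator_seed = derive_seed(config$seed, "generator"),
       cohort_seed = derive_seed(config$seed, "cohort"),
       split_seed = derive_seed(config$seed, "task-split"),
       id_years = config$id_years,
       ood_year_groups = config$ood_year_groups,
       n_boot = config$n_boot,
       timestamp = NA_character_)
}

#' Write experiment outputs as tidy CSVs
#'
#' @param result a result list from one of the `run_*` functions.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result)) {
    obj <- result[[nm]]
    if (data.table::is.data.table(obj) || is.data.frame(obj)) {
      data.table::fwrite(obj, file.path(dir, paste0(nm, ".csv")))
    } else if (nm == "manifest") {
      writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                                  null = "null"),
                 file.path(dir, "manifest.json"))
    }
  }
  invisible(dir)
}

#' Summarize a completed experiment run directory
#'
#' Reads the emitted CSVs (never recomputing metrics) and writes compact
#' summary tables: per-year trajectories, ID/OOD decay, scaling curves
#' and reclassification fractions, as available. Regeneration is
#' idempotent.
#'
#' @param run_dir directory written by [write_experiment()].
#' @return named list of summary data.frames (also written to
#'   `run_dir/summary_*.csv`).
#' @export
make_report <- function(run_dir) {
  need <- function(name) {
    path <- file.path(run_dir, name)
    if (!file.exists(path)) stop("report input missing: ", path)
    data.table::fread(path)
  }
  out <- list()
  if (file.exists(file.path(run_dir, "metrics.csv"))) {
    m <- need("metrics.csv")
    key <- intersect(c("model", "task", "year", "year_group", "metric"),
                     names(m))
    out$trajectory <- m[, c(key, "point", "ci_low", "ci_high"), with = FALSE]
  }
  if (file.exists(file.path(run_dir, "decays.csv"))) {
    d <- need("decays.csv")
    d$decay <- d$ood_value - d$id_value
    out$decay <- d
  }
  if (file.exists(file.path(run_dir, "scaling.csv"))) {
    out$scaling <- need("scaling.csv")
    out$slopes <- need("slopes.csv")
  }
  if (file.exists(file.path(run_dir, "reclassification.csv"))) {
    out$reclassification <- need("reclassification.csv")
  }
  if (length(out) == 0) stop("report input missing: ",
                             file.path(run_dir, "metrics.csv"))
  for (nm in names(out)) {
    data.table::fwrite(out[[nm]], file.path(run_dir,
                                            paste0("summary_", nm, ".csv")))
  }
  invisible(out)
}
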