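# Task adaptation: L2-penalized logistic heads on frozen representations
# or count features, per-year oracle models, and end-to-end (ETE)
# sequence-model baselines trained on task labels alone.

DEFAULT_L2_GRID <- 10 ^ seq(-6, 2)

feature_hash <- function(names) {
  if (is.null(names)) return(NA_character_)
  s <- paste(names, collapse = "|")
  chars <- utf8ToInt(s)
  sprintf("%d-%.0f", length(names),
          sum(as.numeric(chars) * (seq_along(chars) %% 89 + 1)) %% 1e12)
}

#' Train an L2-regularized logistic classification head
#'
#' Fits a ridge-penalized logistic regression for every value of the L2
#' grid and returns the model minimizing binary cross-entropy on the
#' validation rows; ties break toward stronger regularization.
#'
#' @param X_train,X_val feature matrices (dense or `Matrix` sparse).
#' @param y_train,y_val binary 0/1 labels aligned with the rows.
#' @param l2_grid penalty strengths (default `10^-6 .. 10^2` by powers of
#'   ten).
#' @param seed recorded in the returned model.
#' @return a `head_model`: kind `linear_l2`, `weights`, `intercept`,
#'   selected `l2`, `val_bce`, and the feature-registry hash.
#' @export
train_linear_head <- function(X_train, y_train, X_val, y_val,
                              l2_grid = DEFAULT_L2_GRID, seed = 1L) {
  if (length(unique(y_train)) < 2) {
    stop("training labels contain a single class")
  }
  stopifnot(nrow(X_train) == length(y_train), nrow(X_val) == length(y_val))
  lambdas <- sort(unique(l2_grid), decreasing = TRUE)
  fit <- glmnet::glmnet(X_train, y_train, family = "binomial", alpha = 0,
                        lambda = lambdas, standardize = FALSE)
  p_val <- stats::predict(fit, newx = X_val, s = lambdas, type = "response")
  bces <- apply(p_val, 2, function(p) bce_loss(y_val, p))
  # lambdas are decreasing; the LAST index among minima is the strongest
  best_i <- max(which(bces <= min(bces) + 1e-12))
  best_lambda <- lambdas[best_i]
  cf <- stats::coef(fit, s = best_lambda)
  structure(
    list(kind = "linear_l2",
         weights = as.numeric(cf)[-1],
         intercept = as.numeric(cf)[1],
         l2 = best_lambda,
         l2_grid = l2_grid,
         val_bce = unname(bces[best_i]),
         feature_hash = feature_hash(colnames(X_train)),
         seed = seed),
    class = "head_model"
  )
}

#' @export
print.head_model <- function(x, ...) {
  cat("<head_model> ", x$kind,
      if (x$kind == "linear_l2") sprintf(", l2 = %g", x$l2) else "",
      sprintf(", validation BCE %.4f\n", x$val_bce), sep = "")
  invisible(x)
}

#' Predict probabilities from a head model
#'
#' @param model a `head_model`.
#' @param X feature matrix with the same columns the head was trained on.
#' @param ... for ETE heads: `population` and `task_table` used to rebuild
#'   representations.
#' @return probability vector in \[0, 1\].
#' @export
predict_proba <- function(model, X, ...) {
  stopifnot(inherits(model, "head_model"))
  if (model$kind == "ete") {
    return(predict_proba_ete(model, ...))
  }
  if (ncol(X) != length(model$weights)) {
    stop("feature width ", ncol(X), " does not match the trained head (",
         length(model$weights), ")")
  }
  if (!is.na(model$feature_hash) && !is.null(colnames(X)) &&
      feature_hash(colnames(X)) != model$feature_hash) {
    stop("feature registry hash mismatch: refusing to predict")
  }
  as.numeric(sigmoid(as.numeric(X %*% model$weights) + model$intercept))
}

#' Train per-year oracle models
#'
#' For each out-of-distribution year, fits a count-feature head on that
#' year's training rows (vocabulary refitted within the year) with
#' hyperparameters selected on the year's validation rows. Years whose
#' training or validation rows lack one of the classes are reported as
#' untrainable without affecting the others.
#'
#' @param task_table task cohort table with assigned `split`.
#' @param feature_sets per-row feature-name sets (aligned with the table).
#' @param task task name.
#' @param ood_years years to fit oracles for.
#' @param min_count vocabulary pruning threshold.
#' @param l2_grid penalty grid.
#' @param seed seed recorded in models.
#' @return named list year -> list(model, vocab) or `NULL` when
#'   untrainable.
#' @export
train_oracles <- function(task_table, feature_sets, task, ood_years,
                          min_count = 25L, l2_grid = DEFAULT_L2_GRID,
                          seed = 1L) {
  lab <- task_table[[paste0("label_", task)]]
  eli <- task_table[[paste0("eligible_", task)]]
  out <- list()
  for (yr in ood_years) {
    in_year <- task_table$year == yr & eli
    tr <- which(in_year & task_table$split == "train")
    va <- which(in_year & task_table$split == "val")
    if (length(tr) < 2 || length(va) < 1 ||
        length(unique(lab[tr])) < 2 || length(unique(lab[va])) < 2) {
      out[[as.character(yr)]] <- NULL
      out[as.character(yr)] <- list(NULL)
      next
    }
    vocab <- fit_vocabulary(feature_sets[tr], min_count = min_count)
    if (nrow(vocab) < 2) {
      out[as.character(yr)] <- list(NULL)
      next
    }
    model <- train_linear_head(encode_matrix(feature_sets[tr], vocab),
                               lab[tr],
                               encode_matrix(feature_sets[va], vocab),
                               lab[va], l2_grid = l2_grid, seed = seed)
    out[[as.character(yr)]] <- list(model = model, vocab = vocab)
  }
  out
}

#' Z-score columns using training-split statistics
#'
#' @param X_train training matrix defining the statistics.
#' @param ... further matrices to transform with the same statistics.
#' @return list with `train` and the transformed matrices.
#' @export
standardize_by_train <- function(X_train, ...) {
  mu <- colMeans(X_train)
  sdv <- apply(X_train, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  tf <- function(X) sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  out <- list(train = tf(X_train))
  extra <- lapply(list(...), tf)
  c(out, extra)
}

# ---------------------------------------------------------------------------
# End-to-end baseline: same encoder architecture, trained directly on task
# labels with a sigmoid head and no next-day objective.

#' Train an end-to-end sequence model on a task
#'
#' Uses the same day encoder architecture as pretraining, with a sigmoid
#' output head on the prediction-day representation, trained on the task's
#' training rows by Adam with early stopping on validation BCE.
#'
#' @param population an `ehr_population`.
#' @param task_table task cohort table with assigned `split`.
#' @param task task name.
#' @param config a [pretrain_config()].
#' @return a `head_model` of kind `ete` containing the trained encoder and
#'   head weights.
#' @export
train_ete <- function(population, task_table, task, config) {
  stopifnot(task %in% TASKS)
  ontology <- population$ontology
  lab <- task_table[[paste0("label_", task)]]
  eli <- task_table[[paste0("eligible_", task)]]
  pred_col <- paste0("predday_", task)
  tr <- which(eli & task_table$split == "train")
  va <- which(eli & task_table$split == "val")
  if (length(unique(lab[tr])) < 2) stop("training labels contain a single class")

  demo <- data.table::as.data.table(population$demographics)
  ev <- data.table::as.data.table(population$events)
  vocab <- clmbr_vocabulary(ontology, demo)
  encoder <- init_encoder(config, vocab)
  ev_by_pat <- split(as.data.frame(ev), ev$patient_id)
  demo_df <- as.data.frame(demo)
  rownames(demo_df) <- demo_df$patient_id

  tok_row <- function(i) {
    id <- task_table$patient_id[i]
    tok <- tokenize_patient(ev_by_pat[[id]], demo_df[id, ], ontology, vocab,
                            config, through_day = task_table[[pred_col]][i],
                            with_targets = FALSE)
    if (!is.null(tok) && config$architecture == "transformer") {
      tok$extras <- positional_extras(tok$days, demo_df[id, "birth_day"],
                                      config$pos_dim)
    }
    tok
  }
  toks <- lapply(seq_len(nrow(task_table)), tok_row)
  usable <- !vapply(toks, is.null, logical(1))
  tr <- tr[usable[tr]]
  va <- va[usable[va]]

  head_w <- stats::rnorm(config$representation_dim, 0, 0.01)
  head_b <- 0

  row_forward <- function(i) {
    X <- day_input_matrix(toks[[i]], encoder$params, config)
    fwd <- forward_encoder(encoder, X)
    list(fwd = fwd, X = X, rep = fwd$reps[nrow(X), ])
  }
  val_bce_now <- function() {
    p <- vapply(va, function(i) {
      sigmoid(sum(row_forward(i)$rep * head_w) + head_b)
    }, numeric(1))
    bce_loss(lab[va], p)
  }

  state <- adam_init(c(encoder$params, list(head_w = head_w,
                                            head_b = head_b)))
  best <- list(loss = Inf, params = encoder$params, head_w = head_w,
               head_b = head_b, epoch = 0L)
  set.seed(derive_seed(config$seed, "ete-train"))
  for (epoch in seq_len(config$max_epochs)) {
    order_rows <- sample(tr)
    batches <- split(order_rows,
                     ceiling(seq_along(order_rows) / config$batch_size))
    for (batch in batches) {
      acc <- NULL
      dE <- encoder$params$E * 0
      d_hw <- numeric(length(head_w))
      d_hb <- 0
      n_ok <- 0L
      for (i in batch) {
        rf <- row_forward(i)
        logit <- sum(rf$rep * head_w) + head_b
        p <- sigmoid(logit)
        dlogit <- p - lab[i]
        d_hw <- d_hw + dlogit * rf$rep
        d_hb <- d_hb + dlogit
        dRep <- matrix(0, nrow(rf$X), config$representation_dim)
        dRep[nrow(rf$X), ] <- dlogit * head_w
        g <- backward_encoder(encoder, rf$fwd, dRep)
        dX <- g$dX
        g$dX <- NULL
        for (t in seq_len(nrow(rf$X))) {
          idx <- toks[[i]]$input_idx[[t]]
          if (length(idx) == 0) next
          dE[idx, ] <- dE[idx, ] +
            matrix(dX[t, seq_len(config$code_embed_dim)] / length(idx),
                   nrow = length(idx), ncol = config$code_embed_dim,
                   byrow = TRUE)
        }
        if (is.null(acc)) acc <- g
        else for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
        n_ok <- n_ok + 1L
      }
      if (n_ok == 0L) next
      acc$E <- dE
      acc$head_w <- d_hw
      acc$head_b <- d_hb
      acc <- lapply(acc, function(g) g / n_ok)
      acc <- clip_grads(acc, config$grad_clip)
      upd <- adam_step(c(encoder$params, list(head_w = head_w,
                                              head_b = head_b)),
                       acc, state, config$learning_rate)
      state <- upd$state
      head_w <- upd$params$head_w
      head_b <- upd$params$head_b
      upd$params$head_w <- NULL
      upd$params$head_b <- NULL
      encoder$params <- upd$params
    }
    vl <- val_bce_now()
    if (!is.finite(vl)) stop("ETE training diverged at epoch ", epoch)
    if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, params = encoder$params, head_w = head_w,
                   head_b = head_b, epoch = epoch)
    } else if (epoch - best$epoch >= config$patience) {
      break
    }
  }
  encoder$params <- best$params
  structure(
    list(kind = "ete", encoder = encoder, head_w = best$head_w,
         head_b = best$head_b, task = task, val_bce = best$loss,
         feature_hash = NA_character_, seed = config$seed),
    class = "head_model"
  )
}

predict_proba_ete <- function(model, population, task_table) {
  reps <- extract_representations(model$encoder, task_table, population,
                                  model$task)
  as.numeric(sigmoid(reps %*% model$head_w + model$head_b))
}
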