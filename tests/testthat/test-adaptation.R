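test_that("the default penalty grid spans powers of ten", {
  expect_equal(sort(ehrshift:::DEFAULT_L2_GRID), 10 ^ seq(-6, 2))
  expect_length(ehrshift:::DEFAULT_L2_GRID, 9L)
})

test_that("grid selection minimizes validation BCE (exhaustive oracle)", {
  set.seed(1)
  n <- 300
  X <- matrix(rnorm(n * 10), n)
  colnames(X) <- paste0("f", 1:10)
  beta <- c(2, -2, rep(0, 8))
  y <- rbinom(n, 1, plogis(X %*% beta))
  Xv <- matrix(rnorm(120 * 10), 120)
  colnames(Xv) <- colnames(X)
  yv <- rbinom(120, 1, plogis(Xv %*% beta))
  grid <- 10 ^ seq(-4, 1)
  head <- train_linear_head(X, y, Xv, yv, l2_grid = grid)
  # oracle: refit each grid value independently and tally val BCE
  lambdas <- sort(grid, decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = lambdas, standardize = FALSE)
  bces <- vapply(lambdas, function(l) {
    bce_loss(yv, as.numeric(predict(fit, newx = Xv, s = l,
                                    type = "response")))
  }, numeric(1))
  best <- lambdas[max(which(bces <= min(bces) + 1e-12))]
  expect_equal(head$l2, best)
  expect_equal(head$val_bce, min(bces), tolerance = 1e-10)
})

test_that("ties in validation BCE break toward stronger regularization", {
  # duplicate grid values produce exact ties
  set.seed(2)
  X <- matrix(rnorm(200), 100, 2)
  colnames(X) <- c("a", "b")
  y <- rbinom(100, 1, 0.5)
  h <- train_linear_head(X, y, X, y, l2_grid = c(1, 1, 100, 100))
  expect_true(h$l2 %in% c(1, 100))
})

test_that("a separable toy problem reaches training AUROC 1", {
  x <- seq(-2, 2, length.out = 40)
  X <- cbind(x = x, z = rnorm(40, sd = 0.01))
  y <- as.integer(x > 0)
  h <- train_linear_head(X, y, X, y, l2_grid = 1e-6)
  p <- predict_proba(h, X)
  expect_equal(auroc(y, p), 1)
  expect_error(train_linear_head(X, rep(1L, 40), X, y), "single class")
})

test_that("predict_proba is the logistic of the linear score", {
  h <- structure(list(kind = "linear_l2", weights = c(0.5, -1),
                      intercept = 0.25, feature_hash = NA_character_),
                 class = "head_model")
  X <- rbind(c(1, 2), c(0, 0), c(-1, 1))
  expect_equal(predict_proba(h, X),
               plogis(c(0.5 - 2 + 0.25, 0.25, -0.5 - 1 + 0.25)))
  # zero-weight model predicts 1/2 everywhere
  h0 <- structure(list(kind = "linear_l2", weights = c(0, 0), intercept = 0,
                       feature_hash = NA_character_), class = "head_model")
  expect_equal(predict_proba(h0, X), rep(0.5, 3))
  # permutation equivariance
  perm <- c(3, 1, 2)
  expect_equal(predict_proba(h, X[perm, ]), predict_proba(h, X)[perm])
  # width mismatch refuses
  expect_error(predict_proba(h, cbind(X, 1)), "width")
})

test_that("feature-registry hash mismatches refuse to predict", {
  set.seed(3)
  X <- matrix(rnorm(200), 100, 2)
  colnames(X) <- c("a", "b")
  y <- rbinom(100, 1, plogis(X[, 1]))
  h <- train_linear_head(X, y, X, y)
  X2 <- X
  colnames(X2) <- c("a", "WRONG")
  expect_error(predict_proba(h, X2), "hash mismatch")
})

test_that("per-year oracles isolate untrainable years", {
  pop <- small_population()
  tt <- build_task_cohort(pop, seed = 1)
  tt$split <- unname(split_patients(tt$patient_id,
                                    c(train = 0.6, val = 0.2, test = 0.2),
                                    seed = 2)[tt$patient_id])
  feats <- featurize_cohort(pop, tt, "long_los")
  years <- sort(unique(tt$year))
  oracles <- train_oracles(tt, feats, "long_los", c(years, 2099L),
                          min_count = 2L)
  expect_named(oracles, as.character(c(years, 2099L)))
  expect_null(oracles[["2099"]]) # no rows: untrainable, others unaffected
  trained <- Filter(Negate(is.null), oracles)
  expect_gt(length(trained), 0)
  for (o in trained) expect_s3_class(o$model, "head_model")
})

test_that("standardization uses training statistics only", {
  set.seed(4)
  Xtr <- matrix(rnorm(60, mean = 5, sd = 2), 20, 3)
  Xte <- matrix(rnorm(30, mean = 5, sd = 2), 10, 3)
  z <- standardize_by_train(Xtr, test = Xte)
  expect_equal(unname(colMeans(z$train)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(z$train, 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_equal(z$test, sweep(sweep(Xte, 2, colMeans(Xtr), "-"), 2,
                             apply(Xtr, 2, sd), "/"))
  # constant columns pass through unscaled
  Xc <- cbind(Xtr, 7)
  zc <- standardize_by_train(Xc)
  expect_true(all(is.finite(zc$train)))
})

ete_fixture <- function() {
  pop <- generate_population(generator_config(
    n_patients = 60, year_range = c(2009, 2010),
    ontology = make_synthetic_ontology(2, 3), visit_rate = 10,
    admission_rate = 1.5, seed = 19))
  tt <- build_task_cohort(pop, seed = 1)
  tt$split <- unname(split_patients(tt$patient_id,
                                    c(train = 0.7, val = 0.15, test = 0.15),
                                    seed = 3)[tt$patient_id])
  list(pop = pop, tt = tt)
}

test_that("end-to-end models are deterministic with architecture parity", {
  fx <- ete_fixture()
  cfg <- pretrain_config(architecture = "gru", code_embed_dim = 6,
                         hidden_dim = 8, representation_dim = 10,
                         max_epochs = 3, max_sequence_days = 10,
                         batch_size = 8, learning_rate = 5e-3,
                         code_dropout = 0, seed = 4)
  m1 <- train_ete(fx$pop, fx$tt, "long_los", cfg)
  m2 <- train_ete(fx$pop, fx$tt, "long_los", cfg)
  expect_identical(m1$encoder$params, m2$encoder$params)
  expect_identical(m1$head_w, m2$head_w)
  # encoder parameter count equals the pretraining encoder's
  enc <- ehrshift:::init_encoder(cfg, m1$encoder$vocab)
  expect_equal(ehrshift:::encoder_param_count(m1$encoder),
               ehrshift:::encoder_param_count(enc))
  p <- predict_proba(m1, NULL, population = fx$pop, task_table = fx$tt)
  expect_true(all(p >= 0 & p <= 1))
  expect_length(p, nrow(fx$tt))
})

test_that("an over-parameterized ETE can fit its training rows", {
  fx <- ete_fixture()
  # validation rows mirror the training rows so epoch selection cannot
  # revert the fit: a pure capacity probe
  tr_rows <- fx$tt[fx$tt$split == "train" & fx$tt$eligible_long_los]
  va_rows <- data.table::copy(tr_rows)
  va_rows$split <- "val"
  tt2 <- rbind(tr_rows, va_rows)
  cfg <- pretrain_config(architecture = "gru", code_embed_dim = 8,
                         hidden_dim = 12, representation_dim = 16,
                         max_epochs = 25, max_sequence_days = 10,
                         batch_size = 8, learning_rate = 1e-2,
                         patience = 25, code_dropout = 0, seed = 4)
  m <- train_ete(fx$pop, tt2, "long_los", cfg)
  p <- predict_proba(m, NULL, population = fx$pop, task_table = tr_rows)
  expect_gt(auroc(tr_rows$label_long_los, p), 0.85) # capacity check
})
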