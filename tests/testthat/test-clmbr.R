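# small deterministic fixture timeline used across encoder tests
clmbr_fixture <- function(architecture = "gru", n_layers = 1L,
                          flat = FALSE) {
  ont <- if (flat) flat_ontology(6) else
    make_synthetic_ontology(2, 3, domains = c("condition", "drug"))
  codes <- ontology_leaves(ont)
  ev <- data.frame(
    patient_id = "P1",
    day = c(0L, 0L, 3L, 3L, 10L, 17L, 30L),
    code = codes[c(1, 4, 2, 5, 3, 6, 1)],
    domain = "condition", abnormal = "none", stringsAsFactors = FALSE)
  demo <- data.frame(patient_id = "P1", birth_day = -20000L, sex = "F",
                     race = "white", ethnicity = "non-hispanic",
                     stringsAsFactors = FALSE)
  cfg <- pretrain_config(architecture = architecture, code_embed_dim = 5,
                         hidden_dim = 7, n_layers = n_layers,
                         representation_dim = 6, max_sequence_days = 10,
                         code_dropout = 0, ontology_init = FALSE, seed = 3)
  vocab <- clmbr_vocabulary(ont, demo)
  enc <- ehrshift:::init_encoder(cfg, vocab)
  tok <- ehrshift:::tokenize_patient(ev, demo, ont, vocab, cfg)
  if (architecture == "transformer") {
    tok$extras <- ehrshift:::positional_extras(tok$days, demo$birth_day,
                                               cfg$pos_dim)
  }
  list(ont = ont, ev = ev, demo = demo, cfg = cfg, enc = enc, tok = tok)
}

test_that("day inputs have the documented structure", {
  fx <- clmbr_fixture(flat = TRUE)
  di <- build_day_inputs(fx$enc, fx$ev, fx$demo, fx$ont)
  expect_equal(ncol(di$X), fx$cfg$code_embed_dim + 5L)
  expect_equal(nrow(di$X), length(unique(fx$ev$day)))
  # first day: is_first = 1, delta = 0, log1p(delta) = 0
  expect_equal(di$X[1, fx$cfg$code_embed_dim + 3L], 1)
  expect_equal(di$X[1, fx$cfg$code_embed_dim + 2L], 0)
  expect_equal(di$X[1, fx$cfg$code_embed_dim + 5L], 0)
  expect_true(all(di$X[-1, fx$cfg$code_embed_dim + 3L] == 0))

  # a later day with codes {a, b} has mean embedding (E[a] + E[b]) / 2
  # (flat ontology: ancestor extension adds nothing, demographics only on
  # day one)
  E <- fx$enc$params$E
  vi <- fx$enc$vocab$input_index
  day2_codes <- sort(unique(fx$ev$code[fx$ev$day == 3L]))
  expected <- colMeans(E[vi[day2_codes], , drop = FALSE])
  expect_equal(unname(di$X[2, seq_len(fx$cfg$code_embed_dim)]),
               unname(expected), tolerance = 1e-12)

  fxt <- clmbr_fixture("transformer", flat = TRUE)
  dit <- build_day_inputs(fxt$enc, fxt$ev, fxt$demo, fxt$ont)
  expect_equal(ncol(dit$X), fxt$cfg$code_embed_dim + 5L + 2L * fxt$cfg$pos_dim)
  expect_error(build_day_inputs(fx$enc, fx$ev, fx$demo, fx$ont,
                                through_day = -5L),
               "no events")
})

test_that("analytic gradients match finite differences", {
  for (arch in c("gru", "transformer")) {
    fx <- clmbr_fixture(arch, n_layers = 2L)
    r <- ehrshift:::patient_loss_grads(fx$enc, fx$tok, train = TRUE)
    dN <- fx$enc$params$N * 0
    dE <- fx$enc$params$E * 0
    dN <- ehrshift:::accumulate_sparse(dN, r$dN_acc)
    dE <- ehrshift:::accumulate_sparse(dE, r$dE_acc)
    g <- r$grads
    g$N <- dN
    g$E <- dE
    eps <- 1e-5
    set.seed(7)
    for (nm in names(g)) {
      p <- fx$enc$params[[nm]]
      for (i in sample(length(p), min(4, length(p)))) {
        e2 <- fx$enc
        e2$params[[nm]][i] <- p[i] + eps
        lp <- ehrshift:::patient_loss_grads(e2, fx$tok, train = FALSE)$loss
        e2$params[[nm]][i] <- p[i] - eps
        lm <- ehrshift:::patient_loss_grads(e2, fx$tok, train = FALSE)$loss
        num <- (lp - lm) / (2 * eps)
        expect_lt(abs(num - g[[nm]][i]) /
                    max(1e-4, abs(num) + abs(g[[nm]][i])),
                  1e-4)
      }
    }
  }
})

test_that("hierarchical probabilities reduce to flat sigmoids at depth 1", {
  fx <- clmbr_fixture(flat = TRUE)
  rep_vec <- rnorm(fx$cfg$representation_dim)
  for (code in ontology_leaves(fx$ont)) {
    flat_p <- plogis(sum(
      fx$enc$params$N[fx$enc$vocab$node_index[[code]], ] * rep_vec))
    expect_equal(code_probability(rep_vec, code, fx$enc, fx$ont), flat_p,
                 tolerance = 1e-15)
  }
})

test_that("code probabilities multiply along the root path", {
  fx <- clmbr_fixture()
  set.seed(5)
  rep_vec <- rnorm(fx$cfg$representation_dim)
  for (code in ontology_codes(fx$ont)) {
    p <- code_probability(rep_vec, code, fx$enc, fx$ont)
    expect_gt(p, 0)
    expect_lt(p, 1)
    path <- path_to_root(code, fx$ont)
    if (length(path) > 1) {
      anc <- code_probability(rep_vec, path[length(path) - 1], fx$enc,
                              fx$ont)
      expect_lte(p, anc)
    }
  }
})

test_that("next-day loss equals hand-computed BCE and stays finite", {
  fx <- clmbr_fixture(flat = TRUE)
  rep_vec <- rnorm(fx$cfg$representation_dim)
  observed <- ontology_leaves(fx$ont)[1:2]
  tgt <- active_node_targets(observed, fx$ont)
  logits <- drop(fx$enc$params$N[fx$enc$vocab$node_index[names(tgt)], ] %*%
                   rep_vec)
  hand <- mean(-(tgt * log(plogis(logits)) +
                   (1 - tgt) * log(1 - plogis(logits))))
  expect_equal(next_day_loss(rep_vec, observed, fx$enc, fx$ont), hand,
               tolerance = 1e-12)

  # extreme logits: finite loss in log-space
  enc_big <- fx$enc
  enc_big$params$N <- enc_big$params$N * 1e6
  l_big <- next_day_loss(rep_vec, observed, enc_big, fx$ont)
  expect_true(is.finite(l_big))

  # logits matching targets perfectly drive the loss to zero
  enc_fit <- fx$enc
  sign_tgt <- ifelse(tgt == 1, 1, -1)
  enc_fit$params$N[fx$enc$vocab$node_index[names(tgt)], ] <-
    outer(sign_tgt * 50, rep_vec / sum(rep_vec^2))
  expect_lt(next_day_loss(rep_vec, observed, enc_fit, fx$ont), 1e-6)
})

test_that("hierarchical loss equals the flat formulation on depth-1", {
  # on a depth-1 ontology the decision nodes are exactly all codes with
  # target = observed indicator: the flat independent-sigmoid objective
  fx <- clmbr_fixture(flat = TRUE)
  rep_vec <- rnorm(fx$cfg$representation_dim)
  observed <- ontology_leaves(fx$ont)[c(1, 3)]
  all_codes <- sort(ontology_leaves(fx$ont))
  y <- as.numeric(all_codes %in% observed)
  logits <- drop(fx$enc$params$N[fx$enc$vocab$node_index[all_codes], ] %*%
                   rep_vec)
  flat_loss <- mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
  expect_equal(next_day_loss(rep_vec, observed, fx$enc, fx$ont), flat_loss,
               tolerance = 1e-14)
})

pretrain_fixture_population <- function(n = 24, seed = 12) {
  generate_population(generator_config(
    n_patients = n, year_range = c(2009, 2010),
    ontology = make_synthetic_ontology(2, 3), visit_rate = 10, seed = seed))
}

test_that("pretraining is deterministic and freezing holds", {
  pop <- pretrain_fixture_population()
  cfg <- pretrain_config(architecture = "gru", code_embed_dim = 6,
                         hidden_dim = 8, representation_dim = 10,
                         max_epochs = 2, max_sequence_days = 10,
                         batch_size = 8, seed = 4)
  e1 <- pretrain(pop, cfg)
  e2 <- pretrain(pop, cfg)
  expect_identical(e1$loss_trace, e2$loss_trace)
  expect_identical(e1$params, e2$params)

  tt <- build_task_cohort(pop, seed = 1)
  before <- ehrshift:::encoder_checksum(e1)
  r1 <- extract_representations(e1, tt, pop, "mortality")
  expect_identical(ehrshift:::encoder_checksum(e1), before)
  r2 <- extract_representations(e1, tt, pop, "mortality")
  expect_identical(r1, r2)
  expect_equal(ncol(r1), cfg$representation_dim)
})

test_that("representations are causal in both architectures", {
  pop <- pretrain_fixture_population()
  tt <- build_task_cohort(pop, seed = 1)
  for (arch in c("gru", "transformer")) {
    cfg <- pretrain_config(architecture = arch, code_embed_dim = 6,
                           hidden_dim = 8, representation_dim = 10,
                           max_epochs = 1, max_sequence_days = 10,
                           batch_size = 8, seed = 4)
    enc <- pretrain(pop, cfg)
    reps <- extract_representations(enc, tt, pop, "mortality")
    # perturb events strictly after each row's prediction day
    pop2 <- pop
    pred <- tt$predday_mortality[match(pop$events$patient_id,
                                       tt$patient_id)]
    future <- !is.na(pred) & pop$events$day > pred
    ev2 <- data.table::copy(pop$events)
    leaves <- ontology_leaves(pop$ontology)
    if (any(future)) {
      set.seed(8)
      ev2$code[future] <- sample(leaves, sum(future), replace = TRUE)
      ev2$day[future] <- ev2$day[future] + 37L
    }
    pop2$events <- ev2
    reps2 <- extract_representations(enc, tt, pop2, "mortality")
    expect_equal(reps, reps2, tolerance = 1e-12)
  }
})

test_that("patients with no visible events get flagged zero representations", {
  pop <- pretrain_fixture_population()
  tt <- build_task_cohort(pop, seed = 1)
  cfg <- pretrain_config(architecture = "gru", code_embed_dim = 6,
                         hidden_dim = 8, representation_dim = 10,
                         max_epochs = 1, max_sequence_days = 10,
                         batch_size = 8, seed = 4)
  enc <- pretrain(pop, cfg)
  tt$predday_mortality[1] <- -1000L # before any event
  reps <- extract_representations(enc, tt, pop, "mortality")
  expect_true(attr(reps, "empty_history")[1])
  expect_equal(unname(reps[1, ]), rep(0, 10))
})

test_that("checkpoints refuse to load against a mismatched ontology", {
  pop <- pretrain_fixture_population()
  cfg <- pretrain_config(architecture = "gru", code_embed_dim = 6,
                         hidden_dim = 8, representation_dim = 10,
                         max_epochs = 1, max_sequence_days = 10,
                         batch_size = 8, seed = 4)
  enc <- pretrain(pop, cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_encoder(enc, path)
  back <- load_encoder(path, pop$ontology)
  expect_identical(back$params, enc$params)
  expect_error(load_encoder(path, make_synthetic_ontology(3, 2)),
               "hash mismatch")
})

test_that("pretraining aborts with a diagnostic on divergence", {
  pop <- pretrain_fixture_population()
  cfg <- pretrain_config(architecture = "gru", code_embed_dim = 6,
                         hidden_dim = 8, representation_dim = 10,
                         max_epochs = 2, max_sequence_days = 10,
                         batch_size = 8, learning_rate = Inf,
                         grad_clip = Inf, seed = 4)
  expect_error(pretrain(pop, cfg), "diverged")
})
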