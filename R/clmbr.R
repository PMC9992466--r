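# Autoregressive day-sequence foundation model over coded patient
# timelines. Each event day is encoded as the mean embedding of its
# (ancestor-extended) code set concatenated with time features; a GRU or a
# causal transformer maps the day sequence to per-day patient
# representations; the next day's code set is predicted through a
# hierarchical-sigmoid objective over ontology decision nodes. Gradients
# are computed analytically (verified against finite differences in the
# test suite).

#' Pretraining configuration for the sequence encoder
#'
#' @param architecture `"gru"` or `"transformer"`.
#' @param code_embed_dim dimension of code embeddings.
#' @param hidden_dim GRU hidden size, or attention/FFN width for the
#'   transformer.
#' @param n_layers number of stacked recurrent/attention layers.
#' @param representation_dim width of the patient representation produced
#'   by the final linear layer (default 800).
#' @param learning_rate Adam step size for encoder parameters.
#' @param output_lr_scale multiplier on the learning rate for the
#'   hierarchical output node embeddings, which receive sparse updates and
#'   tolerate larger steps; small encoder steps preserve the
#'   information-richness of the representations.
#' @param dropout_rate dropout on day-input vectors during training.
#' @param code_dropout probability of dropping an individual input code
#'   token (leaf or ancestor) from a day's code set during training;
#'   encourages the encoder to spread information across a code's
#'   ancestors instead of relying on any single code identity.
#' @param batch_size patients per gradient step.
#' @param max_epochs maximum training epochs.
#' @param max_sequence_days per-patient truncation; the most recent days
#'   are kept.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param grad_clip global gradient-norm clip.
#' @param pos_dim dimensions per sinusoidal encoding (transformer only;
#'   day-offset and age encodings are concatenated).
#' @param ontology_init initialize each code's embedding at its primary
#'   parent's embedding plus a small offset (ontology-informed
#'   initialization).
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return a `pretrain_config` list.
#' @export
pretrain_config <- function(architecture = c("gru", "transformer"),
                            code_embed_dim = 16L,
                            hidden_dim = 32L,
                            n_layers = 1L,
                            representation_dim = 800L,
                            learning_rate = 2e-4,
                            output_lr_scale = 50,
                            dropout_rate = 0,
                            code_dropout = 0.3,
                            batch_size = 16L,
                            max_epochs = 30L,
                            max_sequence_days = 50L,
                            patience = 5L,
                            grad_clip = 1.0,
                            pos_dim = 8L,
                            ontology_init = TRUE,
                            seed = 1L) {
  architecture <- match.arg(architecture)
  stopifnot(representation_dim >= 1, code_embed_dim >= 1, hidden_dim >= 1,
            n_layers >= 1, max_sequence_days >= 2, dropout_rate >= 0,
            dropout_rate < 1, code_dropout >= 0, code_dropout < 1)
  structure(
    list(architecture = architecture,
         code_embed_dim = as.integer(code_embed_dim),
         hidden_dim = as.integer(hidden_dim),
         n_layers = as.integer(n_layers),
         representation_dim = as.integer(representation_dim),
         learning_rate = learning_rate,
         output_lr_scale = output_lr_scale,
         dropout_rate = dropout_rate,
         code_dropout = code_dropout,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         max_sequence_days = as.integer(max_sequence_days),
         patience = as.integer(patience),
         grad_clip = grad_clip,
         pos_dim = as.integer(pos_dim),
         ontology_init = isTRUE(ontology_init),
         seed = as.integer(seed)),
    class = "pretrain_config"
  )
}

N_TIME_FEATURES <- 5L

#' Input and output vocabulary for the sequence encoder
#'
#' Input codes are all ontology codes except the observation domain
#' (mirroring the source tables used for the sequence model), plus
#' synthetic demographic codes injected on the first day of every
#' sequence. Decision nodes for the hierarchical objective are the
#' ontology codes alone.
#'
#' @param ontology an `ehr_ontology`.
#' @param demographics demographics table supplying the categorical
#'   levels for the synthetic demographic codes.
#' @return list with `input_codes`, `node_codes`, index maps and the
#'   ontology hash.
#' @export
clmbr_vocabulary <- function(ontology, demographics) {
  onto_codes <- ontology_codes(ontology)
  onto_codes <- onto_codes[ontology$domain[onto_codes] != "observation"]
  demo_codes <- sort(unique(c(
    paste0("demo|sex|", demographics$sex),
    paste0("demo|race|", demographics$race),
    paste0("demo|ethnicity|", demographics$ethnicity)
  )))
  input_codes <- c(sort(onto_codes), demo_codes)
  node_codes <- sort(onto_codes) # hierarchical decision nodes
  input_index <- stats::setNames(seq_along(input_codes), input_codes)
  parent_ids <- unname(ontology$parent[input_codes])
  parent_ids[!is.na(parent_ids) & startsWith(parent_ids, "root|")] <- NA
  parent_index <- unname(input_index[parent_ids])
  list(input_codes = input_codes, node_codes = node_codes,
       input_index = input_index,
       node_index = stats::setNames(seq_along(node_codes), node_codes),
       parent_index = parent_index,
       ontology_hash = ontology_hash(ontology))
}

sinusoidal_encoding <- function(t, dim) {
  k <- seq_len(dim %/% 2)
  wavelength <- 10000 ^ (2 * (k - 1) / dim)
  enc <- c(rbind(sin(t / wavelength), cos(t / wavelength)))
  enc[seq_len(dim)]
}

time_feature_row <- function(age_days, delta_days, is_first) {
  c(age_days / 36500,
    delta_days / 365,
    as.numeric(is_first),
    log1p(age_days) / 10,
    log1p(delta_days) / 10)
}

# Tokenize one patient: per event day, the ancestor-extended input code
# indices, time features, and (for days 2..T) the hierarchical targets of
# that day's code set.
tokenize_patient <- function(events, demo_row, ontology, vocab, config,
                             through_day = NULL, with_targets = TRUE) {
  ev <- events
  if (!is.null(through_day)) ev <- ev[ev$day <= through_day, , drop = FALSE]
  if (is.null(ev) || nrow(ev) == 0) return(NULL)
  days <- sort(unique(ev$day))
  if (length(days) > config$max_sequence_days) {
    days <- tail(days, config$max_sequence_days) # keep the most recent days
  }
  ev <- ev[ev$day >= days[1], , drop = FALSE]
  codes_by_day <- split(ev$code, factor(ev$day, levels = days))

  demo_codes <- c(paste0("demo|sex|", demo_row$sex),
                  paste0("demo|race|", demo_row$race),
                  paste0("demo|ethnicity|", demo_row$ethnicity))

  T_len <- length(days)
  input_idx <- vector("list", T_len)
  target_idx <- vector("list", T_len)
  target_y <- vector("list", T_len)
  X_time <- matrix(0, nrow = T_len, ncol = N_TIME_FEATURES)
  for (t in seq_len(T_len)) {
    raw <- unique(codes_by_day[[t]])
    known <- raw[raw %in% ontology$nodes]
    known <- known[ontology$domain[known] != "observation"]
    ext <- if (length(known) > 0) add_ancestors(known, ontology) else character(0)
    inp <- ext
    if (t == 1L) inp <- c(inp, demo_codes) # demographics enter on day one
    idx <- unname(vocab$input_index[inp])
    input_idx[[t]] <- idx[!is.na(idx)]
    age_days <- days[t] - demo_row$birth_day
    delta <- if (t == 1L) 0 else days[t] - days[t - 1L]
    X_time[t, ] <- time_feature_row(age_days, delta, t == 1L)
    if (with_targets && t >= 2L) {
      tgt <- active_node_targets(known, ontology)
      target_idx[[t]] <- unname(vocab$node_index[names(tgt)])
      target_y[[t]] <- unname(tgt)
    }
  }
  list(days = days, input_idx = input_idx, X_time = X_time,
       target_idx = target_idx, target_y = target_y)
}

# transformer positional extras for a tokenized patient
positional_extras <- function(days, birth_day, pos_dim) {
  t(vapply(seq_along(days), function(t) {
    c(sinusoidal_encoding(days[t] - days[1], pos_dim),
      sinusoidal_encoding(days[t] - birth_day, pos_dim))
  }, numeric(2L * pos_dim)))
}

encoder_input_dim <- function(config) {
  d <- config$code_embed_dim + N_TIME_FEATURES
  if (config$architecture == "transformer") d <- d + 2L * config$pos_dim
  d
}

init_matrix <- function(nr, nc, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(1 / max(1, nc))
  matrix(stats::rnorm(nr * nc, 0, scale), nr, nc)
}

init_encoder <- function(config, vocab) {
  set.seed(derive_seed(config$seed, "init"))
  d_in <- encoder_input_dim(config)
  d_rep <- config$representation_dim
  h <- config$hidden_dim
  params <- list(
    E = init_matrix(length(vocab$input_codes), config$code_embed_dim, 0.1),
    N = init_matrix(length(vocab$node_codes), d_rep, 0.1)
  )
  if (isTRUE(config$ontology_init) && !is.null(vocab$parent_index)) {
    # ontology-informed initialization: a code starts at its primary
    # parent's embedding plus a small offset, so codes differentiate from
    # their ancestors only as the data demands it
    has_par <- which(!is.na(vocab$parent_index))
    for (i in has_par) {
      params$E[i, ] <- params$E[vocab$parent_index[i], ] +
        stats::rnorm(config$code_embed_dim, 0, 0.02)
    }
  }
  if (config$architecture == "gru") {
    for (l in seq_len(config$n_layers)) {
      din_l <- if (l == 1) d_in else h
      for (g in c("z", "r", "h")) {
        params[[paste0("W", g, l)]] <- init_matrix(h, din_l)
        params[[paste0("U", g, l)]] <- init_matrix(h, h)
        params[[paste0("b", g, l)]] <- numeric(h)
      }
    }
    params$Wp <- init_matrix(h, d_rep)
  } else {
    for (l in seq_len(config$n_layers)) {
      params[[paste0("Wq", l)]] <- init_matrix(d_in, h)
      params[[paste0("Wk", l)]] <- init_matrix(d_in, h)
      params[[paste0("Wv", l)]] <- init_matrix(d_in, h)
      params[[paste0("Wo", l)]] <- init_matrix(h, d_in)
      params[[paste0("W1", l)]] <- init_matrix(d_in, h)
      params[[paste0("b1", l)]] <- numeric(h)
      params[[paste0("W2", l)]] <- init_matrix(h, d_in)
      params[[paste0("b2", l)]] <- numeric(d_in)
    }
    params$Wp <- init_matrix(d_in, d_rep)
  }
  params$bp <- numeric(d_rep)
  structure(list(params = params, config = config, vocab = vocab),
            class = "clmbr_encoder")
}

#' @export
print.clmbr_encoder <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat("<clmbr_encoder> ", x$config$architecture, ", ",
      length(x$vocab$input_codes), " input codes, rep dim ",
      x$config$representation_dim, ", ", np, " parameters\n", sep = "")
  invisible(x)
}

encoder_param_count <- function(encoder) {
  sum(vapply(encoder$params, length, integer(1)))
}

encoder_checksum <- function(encoder) {
  sum(vapply(encoder$params, function(p) sum(abs(p)), numeric(1)))
}

# Day-input matrix: mean code embedding + time features (+ extras).
# Days with no in-vocabulary codes use a zero embedding.
day_input_matrix <- function(tok, params, config) {
  T_len <- length(tok$days)
  M <- matrix(0, T_len, config$code_embed_dim)
  for (t in seq_len(T_len)) {
    idx <- tok$input_idx[[t]]
    if (length(idx) == 1) M[t, ] <- params$E[idx, ]
    else if (length(idx) > 1) M[t, ] <- colMeans(params$E[idx, , drop = FALSE])
  }
  X <- cbind(M, tok$X_time)
  if (config$architecture == "transformer") X <- cbind(X, tok$extras)
  X
}

#' Build per-day encoder inputs for one patient timeline
#'
#' One row per event day up to `through_day`: the arithmetic mean of the
#' day's code embeddings concatenated with the five time features (scaled
#' age, scaled time delta, first-day flag and log transforms) and, for the
#' transformer, sinusoidal encodings of day offset and age.
#'
#' @param encoder a `clmbr_encoder`.
#' @param events event rows for one patient.
#' @param demo_row the patient's demographics row.
#' @param ontology the `ehr_ontology` the encoder was built against.
#' @param through_day last visible day.
#' @return list with `days` and the day-input matrix `X`.
#' @export
build_day_inputs <- function(encoder, events, demo_row, ontology,
                             through_day = NULL) {
  tok <- tokenize_patient(events, demo_row, ontology, encoder$vocab,
                          encoder$config, through_day, with_targets = FALSE)
  if (is.null(tok)) stop("no events at or before the requested day")
  if (encoder$config$architecture == "transformer") {
    tok$extras <- positional_extras(tok$days, demo_row$birth_day,
                                    encoder$config$pos_dim)
  }
  list(days = tok$days, X = day_input_matrix(tok, encoder$params,
                                             encoder$config))
}

# ---------------------------------------------------------------------------
# forward / backward

forward_gru <- function(params, config, X) {
  T_len <- nrow(X)
  h <- config$hidden_dim
  layers <- vector("list", config$n_layers)
  inp <- X
  for (l in seq_len(config$n_layers)) {
    Wz <- params[[paste0("Wz", l)]]; Uz <- params[[paste0("Uz", l)]]
    bz <- params[[paste0("bz", l)]]
    Wr <- params[[paste0("Wr", l)]]; Ur <- params[[paste0("Ur", l)]]
    br <- params[[paste0("br", l)]]
    Wh <- params[[paste0("Wh", l)]]; Uh <- params[[paste0("Uh", l)]]
    bh <- params[[paste0("bh", l)]]
    H <- matrix(0, T_len, h)
    Z <- matrix(0, T_len, h); R <- matrix(0, T_len, h)
    HH <- matrix(0, T_len, h)
    h_prev <- numeric(h)
    for (t in seq_len(T_len)) {
      x <- inp[t, ]
      z <- sigmoid(Wz %*% x + Uz %*% h_prev + bz)[, 1]
      r <- sigmoid(Wr %*% x + Ur %*% h_prev + br)[, 1]
      hh <- tanh(Wh %*% x + Uh %*% (r * h_prev) + bh)[, 1]
      h_t <- (1 - z) * h_prev + z * hh
      Z[t, ] <- z; R[t, ] <- r; HH[t, ] <- hh; H[t, ] <- h_t
      h_prev <- h_t
    }
    layers[[l]] <- list(input = inp, Z = Z, R = R, HH = HH, H = H)
    inp <- H
  }
  reps <- sweep(inp %*% params$Wp, 2, params$bp, "+")
  list(reps = reps, layers = layers, top = inp)
}

backward_gru <- function(params, config, cache, dRep) {
  grads <- list()
  dTop <- dRep %*% t(params$Wp)
  grads$Wp <- t(cache$top) %*% dRep
  grads$bp <- colSums(dRep)
  for (l in rev(seq_len(config$n_layers))) {
    lay <- cache$layers[[l]]
    Wz <- params[[paste0("Wz", l)]]; Uz <- params[[paste0("Uz", l)]]
    Wr <- params[[paste0("Wr", l)]]; Ur <- params[[paste0("Ur", l)]]
    Wh <- params[[paste0("Wh", l)]]; Uh <- params[[paste0("Uh", l)]]
    T_len <- nrow(lay$H)
    h <- ncol(lay$H)
    dWz <- 0 * Wz; dUz <- 0 * Uz; dbz <- numeric(h)
    dWr <- 0 * Wr; dUr <- 0 * Ur; dbr <- numeric(h)
    dWh <- 0 * Wh; dUh <- 0 * Uh; dbh <- numeric(h)
    dInp <- matrix(0, T_len, ncol(lay$input))
    dh_next <- numeric(h)
    for (t in rev(seq_len(T_len))) {
      dh <- dTop[t, ] + dh_next
      z <- lay$Z[t, ]; r <- lay$R[t, ]; hh <- lay$HH[t, ]
      h_prev <- if (t > 1) lay$H[t - 1, ] else numeric(h)
      x <- lay$input[t, ]
      dz <- dh * (hh - h_prev)
      dhh <- dh * z
      dh_prev <- dh * (1 - z)
      da_h <- dhh * (1 - hh^2)
      drh <- drop(t(Uh) %*% da_h)
      dr <- drh * h_prev
      dh_prev <- dh_prev + drh * r
      da_r <- dr * r * (1 - r)
      da_z <- dz * z * (1 - z)
      dWz <- dWz + outer(da_z, x); dUz <- dUz + outer(da_z, h_prev)
      dbz <- dbz + da_z
      dWr <- dWr + outer(da_r, x); dUr <- dUr + outer(da_r, h_prev)
      dbr <- dbr + da_r
      dWh <- dWh + outer(da_h, x); dUh <- dUh + outer(da_h, r * h_prev)
      dbh <- dbh + da_h
      dh_prev <- dh_prev + drop(t(Uz) %*% da_z) + drop(t(Ur) %*% da_r)
      dInp[t, ] <- drop(t(Wz) %*% da_z + t(Wr) %*% da_r + t(Wh) %*% da_h)
      dh_next <- dh_prev
    }
    grads[[paste0("Wz", l)]] <- dWz; grads[[paste0("Uz", l)]] <- dUz
    grads[[paste0("bz", l)]] <- dbz
    grads[[paste0("Wr", l)]] <- dWr; grads[[paste0("Ur", l)]] <- dUr
    grads[[paste0("br", l)]] <- dbr
    grads[[paste0("Wh", l)]] <- dWh; grads[[paste0("Uh", l)]] <- dUh
    grads[[paste0("bh", l)]] <- dbh
    dTop <- dInp
  }
  grads$dX <- dTop
  grads
}

forward_transformer <- function(params, config, X) {
  T_len <- nrow(X)
  layers <- vector("list", config$n_layers)
  inp <- X
  mask <- outer(seq_len(T_len), seq_len(T_len), ">=") # causal: key <= query
  for (l in seq_len(config$n_layers)) {
    Wq <- params[[paste0("Wq", l)]]; Wk <- params[[paste0("Wk", l)]]
    Wv <- params[[paste0("Wv", l)]]; Wo <- params[[paste0("Wo", l)]]
    W1 <- params[[paste0("W1", l)]]; b1 <- params[[paste0("b1", l)]]
    W2 <- params[[paste0("W2", l)]]; b2 <- params[[paste0("b2", l)]]
    a <- ncol(Wq)
    Q <- inp %*% Wq; K <- inp %*% Wk; V <- inp %*% Wv
    S <- Q %*% t(K) / sqrt(a)
    S[!mask] <- -Inf
    S <- S - apply(S, 1, max)
    A <- exp(S)
    A <- A / rowSums(A)
    Z <- A %*% V
    O <- Z %*% Wo
    X1 <- inp + O
    pre1 <- sweep(X1 %*% W1, 2, b1, "+")
    Hf <- pmax(pre1, 0)
    F_ <- sweep(Hf %*% W2, 2, b2, "+")
    X2 <- X1 + F_
    layers[[l]] <- list(input = inp, Q = Q, K = K, V = V, A = A, Z = Z,
                        X1 = X1, pre1 = pre1, Hf = Hf)
    inp <- X2
  }
  reps <- sweep(inp %*% params$Wp, 2, params$bp, "+")
  list(reps = reps, layers = layers, top = inp)
}

backward_transformer <- function(params, config, cache, dRep) {
  grads <- list()
  dX2 <- dRep %*% t(params$Wp)
  grads$Wp <- t(cache$top) %*% dRep
  grads$bp <- colSums(dRep)
  for (l in rev(seq_len(config$n_layers))) {
    lay <- cache$layers[[l]]
    Wq <- params[[paste0("Wq", l)]]; Wk <- params[[paste0("Wk", l)]]
    Wv <- params[[paste0("Wv", l)]]; Wo <- params[[paste0("Wo", l)]]
    W1 <- params[[paste0("W1", l)]]; W2 <- params[[paste0("W2", l)]]
    a <- ncol(Wq)
    dX1 <- dX2
    dF <- dX2
    dHf <- dF %*% t(W2)
    dHf[lay$pre1 <= 0] <- 0
    grads[[paste0("W2", l)]] <- t(lay$Hf) %*% dF
    grads[[paste0("b2", l)]] <- colSums(dF)
    dX1 <- dX1 + dHf %*% t(W1)
    grads[[paste0("W1", l)]] <- t(lay$X1) %*% dHf
    grads[[paste0("b1", l)]] <- colSums(dHf)
    dO <- dX1
    dX <- dX1
    dZ <- dO %*% t(Wo)
    grads[[paste0("Wo", l)]] <- t(lay$Z) %*% dO
    dA <- dZ %*% t(lay$V)
    dV <- t(lay$A) %*% dZ
    # softmax backward per row
    dS <- lay$A * (dA - rowSums(dA * lay$A))
    dQ <- dS %*% lay$K / sqrt(a)
    dK <- t(dS) %*% lay$Q / sqrt(a)
    dX <- dX + dQ %*% t(Wq) + dK %*% t(Wk) + dV %*% t(Wv)
    grads[[paste0("Wq", l)]] <- t(lay$input) %*% dQ
    grads[[paste0("Wk", l)]] <- t(lay$input) %*% dK
    grads[[paste0("Wv", l)]] <- t(lay$input) %*% dV
    dX2 <- dX
  }
  grads$dX <- dX2
  grads
}

forward_encoder <- function(encoder, X) {
  if (encoder$config$architecture == "gru") {
    forward_gru(encoder$params, encoder$config, X)
  } else {
    forward_transformer(encoder$params, encoder$config, X)
  }
}

backward_encoder <- function(encoder, cache, dRep) {
  if (encoder$config$architecture == "gru") {
    backward_gru(encoder$params, encoder$config, cache, dRep)
  } else {
    backward_transformer(encoder$params, encoder$config, cache, dRep)
  }
}

# numerically stable BCE on logits; returns loss vector and dloss/dlogit
bce_with_logits <- function(logits, y) {
  loss <- pmax(logits, 0) - logits * y + log1p(exp(-abs(logits)))
  grad <- sigmoid(logits) - y
  list(loss = loss, grad = grad)
}

# hierarchical loss for one day given the previous day's representation;
# returns mean-per-node loss, gradient wrt rep, and node-embedding grads
hier_day_loss <- function(rep, node_idx, y, N, with_grad = TRUE) {
  Nv <- N[node_idx, , drop = FALSE]
  logits <- drop(Nv %*% rep)
  b <- bce_with_logits(logits, y)
  k <- length(node_idx)
  out <- list(loss = sum(b$loss) / k)
  if (with_grad) {
    g <- b$grad / k
    out$dRep <- drop(t(Nv) %*% g)
    out$dN <- outer(g, rep)
  }
  out
}

#' Hierarchical-sigmoid next-day loss
#'
#' Mean binary cross-entropy over the decision nodes induced by the
#' observed code set (see [active_node_targets()]), with per-node logits
#' given by the dot product of the node embedding and the previous day's
#' patient representation. Computed on logits in log-space, so it stays
#' finite for arbitrarily large logit magnitudes.
#'
#' @param representation_prev representation vector of day i-1.
#' @param observed_codes codes observed on day i.
#' @param encoder a `clmbr_encoder`.
#' @param ontology the matching `ehr_ontology`.
#' @return scalar loss.
#' @export
next_day_loss <- function(representation_prev, observed_codes, encoder,
                          ontology) {
  tgt <- active_node_targets(observed_codes, ontology)
  idx <- unname(encoder$vocab$node_index[names(tgt)])
  hier_day_loss(representation_prev, idx, unname(tgt), encoder$params$N,
                with_grad = FALSE)$loss
}

#' Probability of a code under the hierarchical-sigmoid factorization
#'
#' `p(code | rep)` is the product over the nodes on the code's root path
#' (virtual domain roots excluded) of `sigmoid(<node_embedding, rep>)`.
#' On a depth-1 ontology this reduces to the flat independent-sigmoid
#' formulation.
#'
#' @param representation patient representation vector.
#' @param code code id.
#' @param encoder a `clmbr_encoder`.
#' @param ontology the matching `ehr_ontology`.
#' @return probability in (0, 1).
#' @export
code_probability <- function(representation, code, encoder, ontology) {
  path <- path_to_root(code, ontology)
  idx <- unname(encoder$vocab$node_index[path])
  if (anyNA(idx)) stop("code '", code, "' has no embedding in this encoder")
  logits <- drop(encoder$params$N[idx, , drop = FALSE] %*% representation)
  prod(sigmoid(logits))
}

# loss and parameter gradients for one tokenized patient; dRep rows are
# nonzero for days 1..T-1 (pretraining) unless head_grad overrides
patient_loss_grads <- function(encoder, tok, train = TRUE,
                               dropout_mask = NULL) {
  params <- encoder$params
  config <- encoder$config
  if (train && (config$code_dropout %||% 0) > 0) {
    tok$input_idx <- lapply(tok$input_idx, function(idx) {
      if (length(idx) <= 1) return(idx)
      keep <- stats::runif(length(idx)) >= config$code_dropout
      if (!any(keep)) keep[sample.int(length(idx), 1)] <- TRUE
      idx[keep]
    })
  }
  X <- day_input_matrix(tok, params, config)
  if (!is.null(dropout_mask)) X <- X * dropout_mask
  fwd <- forward_encoder(encoder, X)
  T_len <- nrow(X)
  d_rep <- config$representation_dim
  dRep <- matrix(0, T_len, d_rep)
  dN_acc <- list()
  total <- 0
  n_days <- 0L
  for (t in 2:T_len) {
    idx <- tok$target_idx[[t]]
    if (is.null(idx) || length(idx) == 0) next
    hl <- hier_day_loss(fwd$reps[t - 1, ], idx, tok$target_y[[t]], params$N,
                        with_grad = train)
    total <- total + hl$loss
    n_days <- n_days + 1L
    if (train) {
      dRep[t - 1, ] <- dRep[t - 1, ] + hl$dRep
      dN_acc[[length(dN_acc) + 1L]] <- list(idx = idx, g = hl$dN)
    }
  }
  if (n_days == 0L) return(NULL)
  loss <- total / n_days
  if (!train) return(list(loss = loss))

  scale <- 1 / n_days
  dRep <- dRep * scale
  grads <- backward_encoder(encoder, fwd, dRep)
  # embedding gradients through the mean pooling
  dX <- grads$dX
  if (!is.null(dropout_mask)) dX <- dX * dropout_mask
  dE <- list()
  for (t in seq_len(T_len)) {
    idx <- tok$input_idx[[t]]
    if (length(idx) == 0) next
    dE[[length(dE) + 1L]] <-
      list(idx = idx,
           g = matrix(dX[t, seq_len(config$code_embed_dim)] / length(idx),
                      nrow = length(idx), ncol = config$code_embed_dim,
                      byrow = TRUE))
  }
  grads$dX <- NULL
  # per-day node grads also carry the 1/n_days scale
  dN_acc <- lapply(dN_acc, function(a) list(idx = a$idx, g = a$g * scale))
  list(loss = loss, grads = grads, dN_acc = dN_acc, dE_acc = dE)
}

# ---------------------------------------------------------------------------
# Adam optimizer over the named parameter list

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, lr_scale = NULL) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1 ^ state$t
  bc2 <- 1 - beta2 ^ state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    lr_nm <- lr * (lr_scale[[nm]] %||% 1)
    params[[nm]] <- params[[nm]] - lr_nm * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

clip_grads <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}

# fold per-patient sparse embedding/node grads into dense accumulators
accumulate_sparse <- function(dense, acc_list) {
  for (a in acc_list) {
    dense[a$idx, ] <- dense[a$idx, ] + a$g
  }
  dense
}

# ---------------------------------------------------------------------------

#' Pretrain the sequence encoder on patient timelines
#'
#' Patients are split 80/20 (seeded, patient-level) into pretraining train
#' and validation sets. Training minimizes the hierarchical-sigmoid
#' next-day loss over days 2..T of each timeline with Adam, gradient-norm
#' clipping and early stopping on validation loss.
#'
#' @param population an `ehr_population` (events + demographics + ontology).
#' @param config a [pretrain_config()].
#' @param patient_ids optional subset of patients to pretrain on.
#' @param ontology override the population's ontology.
#' @param verbose print per-epoch losses.
#' @return a `clmbr_encoder` with `loss_trace` (per-epoch train/validation
#'   loss) and the ontology hash it was trained against.
#' @export
pretrain <- function(population, config, patient_ids = NULL,
                     ontology = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pretrain_config"))
  ontology <- ontology %||% population$ontology
  demo <- data.table::as.data.table(population$demographics)
  ev <- data.table::as.data.table(population$events)
  if (!is.null(patient_ids)) {
    demo <- demo[demo$patient_id %in% patient_ids, ]
    ev <- ev[ev$patient_id %in% patient_ids, ]
  }
  ids <- sort(unique(intersect(demo$patient_id, ev$patient_id)))
  if (length(ids) < 2) stop("pretraining needs at least 2 patients with events")

  vocab <- clmbr_vocabulary(ontology, demo)
  encoder <- init_encoder(config, vocab)

  # tokenize all patients once
  ev_by_pat <- split(as.data.frame(ev), ev$patient_id)
  demo_by_pat <- split(as.data.frame(demo), demo$patient_id)
  toks <- lapply(ids, function(id) {
    tok <- tokenize_patient(ev_by_pat[[id]], demo_by_pat[[id]][1, ],
                            ontology, vocab, config)
    if (!is.null(tok) && config$architecture == "transformer") {
      tok$extras <- positional_extras(tok$days,
                                      demo_by_pat[[id]][1, ]$birth_day,
                                      config$pos_dim)
    }
    tok
  })
  names(toks) <- ids
  keep <- !vapply(toks, is.null, logical(1)) &
    vapply(toks, function(x) length(x$days) >= 2, logical(1))
  toks <- toks[keep]
  ids <- names(toks)
  if (length(ids) < 2) stop("pretraining needs at least 2 usable timelines")

  # 80/20 patient-level split
  set.seed(derive_seed(config$seed, "pretrain-split"))
  n_val <- max(1L, round(0.2 * length(ids)))
  val_ids <- sample(ids, n_val)
  train_ids <- setdiff(ids, val_ids)

  val_loss <- function() {
    ls <- vapply(toks[val_ids], function(tok) {
      r <- patient_loss_grads(encoder, tok, train = FALSE)
      if (is.null(r)) NA_real_ else r$loss
    }, numeric(1))
    mean(ls, na.rm = TRUE)
  }

  state <- adam_init(encoder$params)
  trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))
  best <- list(loss = Inf, params = encoder$params, epoch = 0L)
  set.seed(derive_seed(config$seed, "train"))
  for (epoch in seq_len(config$max_epochs)) {
    order_ids <- sample(train_ids)
    batches <- split(order_ids,
                     ceiling(seq_along(order_ids) / config$batch_size))
    ep_loss <- 0
    ep_n <- 0L
    for (batch in batches) {
      acc <- NULL
      dN <- encoder$params$N * 0
      dE <- encoder$params$E * 0
      n_ok <- 0L
      for (id in batch) {
        tok <- toks[[id]]
        mask <- NULL
        if (config$dropout_rate > 0) {
          d_in <- encoder_input_dim(config)
          mask <- matrix(
            stats::rbinom(length(tok$days) * d_in, 1,
                          1 - config$dropout_rate) /
              (1 - config$dropout_rate),
            nrow = length(tok$days))
        }
        r <- patient_loss_grads(encoder, tok, train = TRUE,
                                dropout_mask = mask)
        if (is.null(r)) next
        n_ok <- n_ok + 1L
        ep_loss <- ep_loss + r$loss
        ep_n <- ep_n + 1L
        if (is.null(acc)) {
          acc <- r$grads
        } else {
          for (nm in names(r$grads)) acc[[nm]] <- acc[[nm]] + r$grads[[nm]]
        }
        dN <- accumulate_sparse(dN, r$dN_acc)
        dE <- accumulate_sparse(dE, r$dE_acc)
      }
      if (n_ok == 0L) next
      acc$dX <- NULL
      acc$N <- dN
      acc$E <- dE
      acc <- lapply(acc, function(g) g / n_ok)
      acc <- clip_grads(acc, config$grad_clip)
      if (any(vapply(acc, function(g) any(!is.finite(g)), logical(1)))) {
        stop("pretraining diverged: non-finite gradient at epoch ", epoch)
      }
      upd <- adam_step(encoder$params, acc, state, config$learning_rate,
                       lr_scale = list(N = config$output_lr_scale %||% 1))
      encoder$params <- upd$params
      state <- upd$state
    }
    tr <- ep_loss / max(1L, ep_n)
    vl <- val_loss()
    if (!is.finite(tr) || !is.finite(vl)) {
      stop("pretraining diverged: non-finite loss at epoch ", epoch)
    }
    trace <- rbind(trace, data.frame(epoch = epoch, train_loss = tr,
                                     val_loss = vl))
    if (verbose) {
      message(sprintf("epoch %d: train %.4f val %.4f", epoch, tr, vl))
    }
    if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, params = encoder$params, epoch = epoch)
    } else if (epoch - best$epoch >= config$patience) {
      break
    }
  }
  encoder$params <- best$params
  encoder$loss_trace <- trace
  encoder$best_val_loss <- best$loss
  encoder$ontology_hash <- vocab$ontology_hash
  encoder$train_ids <- train_ids
  encoder$val_ids <- val_ids
  encoder
}

# marginal-frequency baseline: per decision node, the training frequency
# of target 1; evaluated with the same aggregation as the model loss
marginal_baseline_loss <- function(population, encoder, ids_train, ids_val,
                                   ontology = NULL) {
  ontology <- ontology %||% population$ontology
  ev <- data.table::as.data.table(population$events)
  demo <- data.table::as.data.table(population$demographics)
  config <- encoder$config
  vocab <- encoder$vocab
  tok_for <- function(id) {
    tokenize_patient(as.data.frame(ev[ev$patient_id == id, ]),
                     as.data.frame(demo[demo$patient_id == id, ])[1, ],
                     ontology, vocab, config)
  }
  pos <- numeric(length(vocab$node_codes))
  tot <- numeric(length(vocab$node_codes))
  for (id in ids_train) {
    tok <- tok_for(id)
    if (is.null(tok)) next
    for (t in seq_along(tok$days)) {
      if (t < 2 || length(tok$target_idx[[t]]) == 0) next
      idx <- tok$target_idx[[t]]
      pos[idx] <- pos[idx] + tok$target_y[[t]]
      tot[idx] <- tot[idx] + 1
    }
  }
  phat <- clip_probs(ifelse(tot > 0, pos / pmax(tot, 1), 0.5), 1e-6)
  losses <- vapply(ids_val, function(id) {
    tok <- tok_for(id)
    if (is.null(tok)) return(NA_real_)
    day_losses <- c()
    for (t in seq_along(tok$days)) {
      if (t < 2 || length(tok$target_idx[[t]]) == 0) next
      p <- phat[tok$target_idx[[t]]]
      y <- tok$target_y[[t]]
      day_losses <- c(day_losses, -mean(y * log(p) + (1 - y) * log1p(-p)))
    }
    if (length(day_losses) == 0) NA_real_ else mean(day_losses)
  }, numeric(1))
  mean(losses, na.rm = TRUE)
}

#' Extract frozen patient representations for a task cohort
#'
#' For each cohort row, runs the encoder over the patient's event days up
#' to the task's prediction day and returns the representation of the last
#' visible day. No parameters are updated. Patients with no visible events
#' receive a zero representation and are flagged.
#'
#' @param encoder a trained `clmbr_encoder`.
#' @param task_table task cohort table.
#' @param population the `ehr_population`.
#' @param task task name selecting the prediction day.
#' @return numeric matrix, rows aligned with `task_table`; attribute
#'   `empty_history` flags rows with no visible events.
#' @export
extract_representations <- function(encoder, task_table, population,
                                    task = "mortality") {
  stopifnot(task %in% TASKS)
  ontology <- population$ontology
  if (!is.null(encoder$ontology_hash) &&
      encoder$ontology_hash != ontology_hash(ontology)) {
    stop("encoder was trained against a different ontology")
  }
  ev <- data.table::as.data.table(population$events)
  demo <- data.table::as.data.table(population$demographics)
  pred_col <- paste0("predday_", task)
  n <- nrow(task_table)
  out <- matrix(0, n, encoder$config$representation_dim)
  empty <- logical(n)
  ev_by_pat <- split(as.data.frame(ev), ev$patient_id)
  demo_df <- as.data.frame(demo)
  rownames(demo_df) <- demo_df$patient_id
  for (i in seq_len(n)) {
    id <- task_table$patient_id[i]
    tok <- tokenize_patient(ev_by_pat[[id]], demo_df[id, ], ontology,
                            encoder$vocab, encoder$config,
                            through_day = task_table[[pred_col]][i],
                            with_targets = FALSE)
    if (is.null(tok)) {
      empty[i] <- TRUE
      next
    }
    if (encoder$config$architecture == "transformer") {
      tok$extras <- positional_extras(tok$days, demo_df[id, "birth_day"],
                                      encoder$config$pos_dim)
    }
    X <- day_input_matrix(tok, encoder$params, encoder$config)
    fwd <- forward_encoder(encoder, X)
    out[i, ] <- fwd$reps[nrow(X), ]
  }
  attr(out, "empty_history") <- empty
  out
}

#' Save / load an encoder checkpoint
#'
#' The checkpoint stores the configuration, parameters and the hash of the
#' ontology vocabulary; loading against a mismatched ontology fails.
#'
#' @param encoder a `clmbr_encoder`.
#' @param path file path.
#' @export
save_encoder <- function(encoder, path) {
  saveRDS(encoder, path)
  invisible(path)
}

#' @rdname save_encoder
#' @param ontology the ontology the encoder will be used with.
#' @export
load_encoder <- function(path, ontology) {
  encoder <- readRDS(path)
  if (!is.null(encoder$ontology_hash) &&
      encoder$ontology_hash != ontology_hash(ontology)) {
    stop("checkpoint ontology hash mismatch: refusing to load")
  }
  encoder
}
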