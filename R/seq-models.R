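# Dual-branch sequence networks: a structured-input branch over the six
# layout features and a sequence branch over the 21-word context window,
# encoded by a 2-layer BiLSTM (with corpus-trained CBOW embeddings) or a
# small transformer encoder, concatenated into shared classifier layers
# with three sigmoid outputs.

#' Pretrain CBOW word2vec embeddings on training windows
#'
#' Continuous bag-of-words with negative sampling, trained on the
#' (lowercased, whitespace-tokenized) training context windows.
#' Out-of-vocabulary tokens map to the zero vector at lookup time.
#'
#' @param segments Character vector of training windows.
#' @param dim Embedding width (default 100).
#' @param window Context half-width within a segment (default 5).
#' @param epochs Passes over the corpus (default 3).
#' @param negative Negative samples per position (default 5).
#' @param lr Initial learning rate, decayed linearly (default 0.025).
#' @param seed Integer seed.
#' @return Object of class `w2v_embeddings`: list with `vocab`,
#'   `vectors` (V x dim matrix), `dim`.
#' @export
pretrain_embeddings <- function(segments, dim = 100, window = 5, epochs = 3,
                                negative = 5, lr = 0.025, seed = 1L) {
  assert_that(length(segments) > 0, "cannot pretrain embeddings on an empty corpus")
  toks <- lapply(segments, tokenize_segment)
  vocab <- sort(unique(unlist(toks)))
  V <- length(vocab)
  ids <- lapply(toks, function(x) match(x, vocab))
  freq <- tabulate(unlist(ids), nbins = V)
  neg_prob <- freq^0.75 / sum(freq^0.75)

  with_seed(seed, {
    Win <- matrix(runif(V * dim, -0.5, 0.5) / dim, V, dim)
    Wout <- matrix(0, V, dim)
    n_pos_total <- sum(lengths(ids)) * epochs
    step <- 0
    for (ep in seq_len(epochs)) {
      for (s in seq_along(ids)) {
        seq_ids <- ids[[s]]
        L <- length(seq_ids)
        if (L < 2) next
        negs <- matrix(sample.int(V, L * negative, replace = TRUE,
                                  prob = neg_prob), L, negative)
        for (t in seq_len(L)) {
          ctx <- seq_ids[max(1, t - window):min(L, t + window)][-(t - max(1, t - window) + 1)]
          if (length(ctx) == 0) next
          step <- step + 1
          cur_lr <- lr * max(1e-4, 1 - step / n_pos_total)
          h <- colMeans(Win[ctx, , drop = FALSE])
          targets <- c(seq_ids[t], negs[t, ])
          labels <- c(1, rep(0, negative))
          sc <- Wout[targets, , drop = FALSE] %*% h
          gsc <- 1 / (1 + exp(-sc)) - labels
          gh <- crossprod(Wout[targets, , drop = FALSE], gsc)[, 1]
          Wout[targets, ] <- Wout[targets, , drop = FALSE] -
            cur_lr * (gsc %*% rbind(h))
          upd <- cur_lr * gh / length(ctx)
          for (c in ctx) Win[c, ] <- Win[c, ] - upd
        }
      }
    }
    structure(list(vocab = vocab, vectors = Win, dim = dim),
              class = "w2v_embeddings")
  })
}

#' @export
print.w2v_embeddings <- function(x, ...) {
  cat("<w2v_embeddings> ", length(x$vocab), " tokens x ", x$dim,
      " dimensions\n", sep = "")
  invisible(x)
}

#' Look up embedding vectors (zero vector for OOV)
#'
#' @param emb A `w2v_embeddings`.
#' @param tokens Character tokens.
#' @return length(tokens) x dim matrix.
#' @export
embedding_lookup <- function(emb, tokens) {
  idx <- match(tolower(tokens), emb$vocab)
  out <- matrix(0, length(tokens), emb$dim)
  ok <- !is.na(idx)
  out[ok, ] <- emb$vectors[idx[ok], , drop = FALSE]
  out
}

#' Encode a context window as a padded token-id sequence
#'
#' Whitespace tokenization (lowercased), truncation to `max_len` tokens,
#' right padding, and a mask marking real tokens. Ids index `vocab`;
#' out-of-vocabulary tokens get id 0.
#'
#' @param segment The window as a space-joined string.
#' @param vocab Character vector of known tokens (may be `NULL`; then all
#'   ids are 0).
#' @param max_len Sequence cap (default 32).
#' @return List with `ids` (length `max_len` integer) and `mask`
#'   (0/1 vector).
#' @export
encode_segment <- function(segment, vocab = NULL, max_len = 32) {
  toks <- tokenize_segment(segment)
  toks <- toks[nzchar(toks)]
  toks <- head(toks, max_len)
  ids <- if (is.null(vocab)) rep(0L, length(toks)) else {
    i <- match(toks, vocab)
    ifelse(is.na(i), 0L, i)
  }
  ids <- c(ids, rep(0L, max_len - length(ids)))
  mask <- c(rep(1, length(toks)), rep(0, max_len - length(toks)))
  list(ids = as.integer(ids), mask = mask)
}

encode_batch <- function(segments, vocab, max_len) {
  enc <- lapply(segments, encode_segment, vocab = vocab, max_len = max_len)
  list(ids = do.call(rbind, lapply(enc, `[[`, "ids")),
       mask = do.call(rbind, lapply(enc, `[[`, "mask")))
}

#' Specify the dual-branch network architecture
#'
#' Defaults mirror the canonical configuration: 32-token sequence cap,
#' 100-d embeddings, 2-layer BiLSTM with 100 units per direction,
#' 2 x 100-unit structured branch, 200-unit classifier layer, 20% dropout,
#' 3 sigmoid outputs. `d_model`/`n_layers` size the transformer encoder
#' (kept small by default; the encoder is pluggable and carries no
#' pretrained weights).
#'
#' @param encoder `"bilstm"` or `"transformer"`.
#' @param use_structured Include the structured-input branch?
#' @param max_len Token cap (default 32).
#' @param emb_dim BiLSTM embedding width (default 100).
#' @param hidden LSTM hidden units per direction (default 100).
#' @param n_layers Encoder depth (default 2).
#' @param d_model Transformer model width (default 32).
#' @param ffnn_struct,ffnn_seq,ffnn_head Dense widths of the structured
#'   branch, sequence-branch projection, and classifier layer.
#' @param dropout Dropout rate in \[0, 1).
#' @param loss `"bce"` (per-class sigmoid binary cross-entropy, default)
#'   or `"ce"` (softmax categorical).
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(encoder = c("bilstm", "transformer"),
                         use_structured = TRUE, max_len = 32,
                         emb_dim = 100, hidden = 100, n_layers = 2,
                         d_model = 32, ffnn_struct = 100, ffnn_seq = 100,
                         ffnn_head = 200, dropout = 0.2,
                         loss = c("bce", "ce")) {
  encoder <- match.arg(encoder)
  loss <- match.arg(loss)
  assert_that(max_len >= 1, "max_len must be >= 1")
  assert_that(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  structure(list(encoder = encoder, use_structured = isTRUE(use_structured),
                 max_len = as.integer(max_len), emb_dim = as.integer(emb_dim),
                 hidden = as.integer(hidden), n_layers = as.integer(n_layers),
                 d_model = as.integer(d_model),
                 ffnn_struct = as.integer(ffnn_struct),
                 ffnn_seq = as.integer(ffnn_seq),
                 ffnn_head = as.integer(ffnn_head),
                 dropout = dropout, out_units = 3L, loss = loss),
            class = "network_spec")
}

#' Training configuration for the sequence models
#'
#' Canonical settings: batch size 64, Adam, 100 epochs, learning rate
#' 2e-4 (BiLSTM) or 2e-6 (fine-tuning a pretrained transformer). Training
#' runs the full epoch budget (no early stopping); the returned model is
#' the checkpoint minimizing validation cross-entropy.
#'
#' @param batch_size Minibatch size.
#' @param lr Learning rate; `NULL` selects the encoder default.
#' @param epochs Epoch budget.
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 64, lr = NULL, epochs = 100, seed = 1L) {
  assert_that(epochs >= 1, "epochs must be >= 1")
  assert_that(is.null(lr) || lr > 0, "lr must be positive")
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

default_lr <- function(encoder) if (encoder == "bilstm") 2e-4 else 2e-6

init_mat <- function(nr, nc, fan_in = nr) {
  r <- 1 / sqrt(max(1, fan_in))
  matrix(runif(nr * nc, -r, r), nr, nc)
}

# Initialize the parameter list for a spec. vocab_size is the sequence
# tokenizer vocabulary size (transformer trains its own token embeddings;
# ids are shifted by 1 so id 0 = PAD/OOV maps to row 1).
init_params <- function(spec, vocab_size, emb_dim_in) {
  p <- list()
  if (spec$use_structured) {
    f <- spec$ffnn_struct
    p$Ws1 <- init_mat(6, f); p$bs1 <- matrix(0, 1, f)
    p$Ws2 <- init_mat(f, f); p$bs2 <- matrix(0, 1, f)
  }
  if (spec$encoder == "bilstm") {
    h <- spec$hidden
    for (l in seq_len(spec$n_layers)) {
      d_in <- if (l == 1) emb_dim_in else 2 * h
      for (dir in c("f", "b")) {
        key <- paste0("l", l, dir)
        p[[paste0("W_", key)]] <- init_mat(d_in, 4 * h)
        p[[paste0("U_", key)]] <- init_mat(h, 4 * h, fan_in = h)
        b <- matrix(0, 1, 4 * h)
        b[1, (h + 1):(2 * h)] <- 1  # forget-gate bias
        p[[paste0("b_", key)]] <- b
      }
    }
    flat_dim <- 2 * h
  } else {
    d <- spec$d_model
    p$Emb <- init_mat(vocab_size + 1L, d, fan_in = d)
    p$Pos <- matrix(rnorm(spec$max_len * d, 0, 0.01), spec$max_len, d)
    for (l in seq_len(spec$n_layers)) {
      key <- paste0("l", l)
      p[[paste0("ln1g_", key)]] <- matrix(1, 1, d)
      p[[paste0("ln1b_", key)]] <- matrix(0, 1, d)
      for (w in c("Wq", "Wk", "Wv", "Wo")) {
        p[[paste0(w, "_", key)]] <- init_mat(d, d)
        p[[paste0(sub("W", "b", w), "_", key)]] <- matrix(0, 1, d)
      }
      p[[paste0("ln2g_", key)]] <- matrix(1, 1, d)
      p[[paste0("ln2b_", key)]] <- matrix(0, 1, d)
      p[[paste0("Wf1_", key)]] <- init_mat(d, 4 * d)
      p[[paste0("bf1_", key)]] <- matrix(0, 1, 4 * d)
      p[[paste0("Wf2_", key)]] <- init_mat(4 * d, d)
      p[[paste0("bf2_", key)]] <- matrix(0, 1, d)
    }
    p$lnfg <- matrix(1, 1, d); p$lnfb <- matrix(0, 1, d)
    flat_dim <- spec$max_len * d
  }
  p$Wseq <- init_mat(flat_dim, spec$ffnn_seq)
  p$bseq <- matrix(0, 1, spec$ffnn_seq)
  head_in <- spec$ffnn_seq + if (spec$use_structured) spec$ffnn_struct else 0L
  p$Wh <- init_mat(head_in, spec$ffnn_head)
  p$bh <- matrix(0, 1, spec$ffnn_head)
  p$Wout <- init_mat(spec$ffnn_head, spec$out_units)
  p$bout <- matrix(0, 1, spec$out_units)
  p
}

dense <- function(tape, x, W, b, act = NULL) {
  z <- ad_add(tape, ad_mm(tape, x, W), b)
  if (is.null(act)) z else act(tape, z)
}

lstm_direction <- function(tape, xs, leaf, key, h, m, reverse = FALSE) {
  W <- leaf[[paste0("W_", key)]]
  U <- leaf[[paste0("U_", key)]]
  b <- leaf[[paste0("b_", key)]]
  Tlen <- length(xs)
  hs <- vector("list", Tlen)
  hprev <- ad_leaf(tape, matrix(0, m, h))
  cprev <- ad_leaf(tape, matrix(0, m, h))
  order_t <- if (reverse) rev(seq_len(Tlen)) else seq_len(Tlen)
  for (t in order_t) {
    z <- ad_add(tape, ad_add(tape, ad_mm(tape, xs[[t]], W),
                             ad_mm(tape, hprev, U)), b)
    ig <- ad_sigmoid(tape, ad_cols(tape, z, 1:h))
    fg <- ad_sigmoid(tape, ad_cols(tape, z, (h + 1):(2 * h)))
    gg <- ad_tanh(tape, ad_cols(tape, z, (2 * h + 1):(3 * h)))
    og <- ad_sigmoid(tape, ad_cols(tape, z, (3 * h + 1):(4 * h)))
    cprev <- ad_add(tape, ad_mul(tape, fg, cprev), ad_mul(tape, ig, gg))
    hprev <- ad_mul(tape, og, ad_tanh(tape, cprev))
    hs[[t]] <- hprev
  }
  hs  # per-timestep hidden states; final state is hs[[T]] (fwd) / hs[[1]] (bwd)
}

# Forward pass. batch: list(struct (m x 6, already standardized), ids
# (m x T), mask (m x T), emb_input (list of T m x emb matrices, BiLSTM),
# y (one-hot, optional)). Returns list(leaf, logits, loss).
seq_forward <- function(params, spec, batch, train = FALSE) {
  tape <- ad_tape()
  leaf <- lapply(params, function(v) ad_leaf(tape, v))
  m <- nrow(batch$mask)
  Tlen <- spec$max_len

  if (spec$encoder == "bilstm") {
    h <- spec$hidden
    xs <- lapply(batch$emb_input, function(x) ad_leaf(tape, x))
    for (l in seq_len(spec$n_layers)) {
      hf <- lstm_direction(tape, xs, leaf, paste0("l", l, "f"), h, m)
      hb <- lstm_direction(tape, xs, leaf, paste0("l", l, "b"), h, m,
                           reverse = TRUE)
      if (l < spec$n_layers) {
        xs <- lapply(seq_len(Tlen), function(t) {
          ad_cbind(tape, list(hf[[t]], hb[[t]]))
        })
      } else {
        enc_out <- ad_cbind(tape, list(hf[[Tlen]], hb[[1]]))
      }
    }
  } else {
    d <- spec$d_model
    ids_flat <- as.integer(t(batch$ids)) + 1L  # sample-major; 0 -> PAD row 1
    x <- ad_gather(tape, leaf$Emb, ids_flat)
    x <- ad_add(tape, x, ad_tile_rows(tape, leaf$Pos, m))
    for (l in seq_len(spec$n_layers)) {
      key <- paste0("l", l)
      xn <- ad_layernorm(tape, x, leaf[[paste0("ln1g_", key)]],
                         leaf[[paste0("ln1b_", key)]])
      q <- dense(tape, xn, leaf[[paste0("Wq_", key)]], leaf[[paste0("bq_", key)]])
      k <- dense(tape, xn, leaf[[paste0("Wk_", key)]], leaf[[paste0("bk_", key)]])
      v <- dense(tape, xn, leaf[[paste0("Wv_", key)]], leaf[[paste0("bv_", key)]])
      att <- ad_attention(tape, q, k, v, m, Tlen, batch$mask)
      att <- dense(tape, att, leaf[[paste0("Wo_", key)]], leaf[[paste0("bo_", key)]])
      att <- ad_dropout(tape, att, spec$dropout, train)
      x <- ad_add(tape, x, att)
      xn <- ad_layernorm(tape, x, leaf[[paste0("ln2g_", key)]],
                         leaf[[paste0("ln2b_", key)]])
      ff <- dense(tape, xn, leaf[[paste0("Wf1_", key)]],
                  leaf[[paste0("bf1_", key)]], ad_relu)
      ff <- dense(tape, ff, leaf[[paste0("Wf2_", key)]], leaf[[paste0("bf2_", key)]])
      ff <- ad_dropout(tape, ff, spec$dropout, train)
      x <- ad_add(tape, x, ff)
    }
    x <- ad_layernorm(tape, x, leaf$lnfg, leaf$lnfb)
    enc_out <- ad_flatten_tokens(tape, x, m, Tlen)
  }

  seq_feat <- dense(tape, enc_out, leaf$Wseq, leaf$bseq, ad_relu)
  seq_feat <- ad_dropout(tape, seq_feat, spec$dropout, train)

  if (spec$use_structured) {
    s <- ad_leaf(tape, batch$struct)
    s <- dense(tape, s, leaf$Ws1, leaf$bs1, ad_relu)
    s <- ad_dropout(tape, s, spec$dropout, train)
    s <- dense(tape, s, leaf$Ws2, leaf$bs2, ad_relu)
    s <- ad_dropout(tape, s, spec$dropout, train)
    joint <- ad_cbind(tape, list(s, seq_feat))
  } else {
    joint <- seq_feat
  }
  hd <- dense(tape, joint, leaf$Wh, leaf$bh, ad_relu)
  hd <- ad_dropout(tape, hd, spec$dropout, train)
  logits <- dense(tape, hd, leaf$Wout, leaf$bout)

  loss <- NULL
  if (!is.null(batch$y)) {
    loss <- if (spec$loss == "bce") ad_bce_logits(tape, logits, batch$y)
            else ad_ce_logits(tape, logits, batch$y)
  }
  list(tape = tape, leaf = leaf, logits = logits, loss = loss)
}

# Assemble the numeric inputs for a set of candidate rows.
make_batch <- function(model, cands, with_y = TRUE) {
  spec <- model$spec
  enc <- encode_batch(cands$segment, model$vocab, spec$max_len)
  struct <- cbind(cands$left, cands$top, cands$width, cands$height,
                  cands$page_num, cands$value)
  struct <- sweep(sweep(struct, 2, model$struct_norm$mu), 2,
                  model$struct_norm$sd, `/`)
  b <- list(struct = struct, ids = enc$ids, mask = enc$mask)
  if (spec$encoder == "bilstm") {
    toks <- lapply(cands$segment, function(s) {
      head(tokenize_segment(s), spec$max_len)
    })
    b$emb_input <- lapply(seq_len(spec$max_len), function(t) {
      tok_t <- vapply(toks, function(x) if (length(x) >= t) x[t] else "", "")
      embedding_lookup(model$embeddings, tok_t)
    })
  }
  if (with_y) {
    y <- matrix(0, nrow(cands), 3,
                dimnames = list(NULL, class_labels()))
    y[cbind(seq_len(nrow(cands)), match(cands$label, class_labels()))] <- 1
    b$y <- y
  }
  b
}

adam_step <- function(state, params, grads, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

eval_loss <- function(model, cands, chunk = 256L) {
  n <- nrow(cands)
  tot <- 0
  for (s in seq(1, n, by = chunk)) {
    rows <- s:min(n, s + chunk - 1)
    b <- make_batch(model, cands[rows, , drop = FALSE])
    fw <- seq_forward(model$params, model$spec, b, train = FALSE)
    tot <- tot + fw$loss$value[1] * length(rows)
  }
  tot / n
}

#' Fit a dual-branch sequence model
#'
#' Builds the tokenizer from the training windows, pretrains CBOW
#' embeddings for the BiLSTM path (unless supplied), standardizes the
#' structured features on training statistics, trains with Adam for the
#' full epoch budget saving a checkpoint per epoch, and returns the
#' checkpoint minimizing validation cross-entropy (ties broken by the
#' earliest epoch).
#'
#' @param train_cands,val_cands Labelled candidate tibbles
#'   (report-disjoint).
#' @param spec A [network_spec()].
#' @param cfg A [train_config()].
#' @param embeddings Optional pre-trained `w2v_embeddings` (BiLSTM path).
#' @param checkpoint_dir Optional directory for epoch-numbered checkpoint
#'   files.
#' @return Object of class `seq_model` with the selected parameters,
#'   training `log` (epoch, train_loss, val_loss) and `best_epoch`.
#' @export
fit_sequence_model <- function(train_cands, val_cands,
                               spec = network_spec(),
                               cfg = train_config(),
                               embeddings = NULL,
                               checkpoint_dir = NULL) {
  assert_that(nrow(train_cands) > 0 && nrow(val_cands) > 0,
              "train and validation sets must be non-empty")
  assert_that(!any(train_cands$report_id %in% val_cands$report_id),
              "train and validation sets must be report-disjoint")
  lr <- cfg$lr %||% default_lr(spec$encoder)

  vocab <- sort(unique(unlist(lapply(train_cands$segment, tokenize_segment))))
  if (spec$encoder == "bilstm" && is.null(embeddings)) {
    embeddings <- pretrain_embeddings(train_cands$segment, dim = spec$emb_dim,
                                      seed = child_seed(cfg$seed, "w2v"))
  }
  struct_mat <- cbind(train_cands$left, train_cands$top, train_cands$width,
                      train_cands$height, train_cands$page_num,
                      train_cands$value)
  mu <- colMeans(struct_mat)
  sg <- apply(struct_mat, 2, sd)
  sg[!is.finite(sg) | sg == 0] <- 1

  model <- structure(
    list(spec = spec, cfg = cfg, vocab = vocab, embeddings = embeddings,
         struct_norm = list(mu = mu, sd = sg), params = NULL,
         log = NULL, best_epoch = NA_integer_),
    class = "seq_model")

  with_seed(cfg$seed, {
    model$params <- init_params(spec, length(vocab),
                                emb_dim_in = spec$emb_dim)
    state <- list(m = lapply(model$params, function(x) x * 0),
                  v = lapply(model$params, function(x) x * 0))
    n <- nrow(train_cands)
    step <- 0
    best_val <- Inf
    best_params <- model$params
    log_rows <- vector("list", cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (s in seq(1, n, by = cfg$batch_size)) {
        rows <- ord[s:min(n, s + cfg$batch_size - 1)]
        b <- make_batch(model, train_cands[rows, , drop = FALSE])
        fw <- seq_forward(model$params, spec, b, train = TRUE)
        grads_all <- ad_backward(fw$tape, fw$loss)
        grads <- lapply(fw$leaf, function(nd) grads_all[[nd$id]])
        step <- step + 1
        upd <- adam_step(state, model$params, grads, lr, step)
        state <- upd$state
        model$params <- upd$params
        ep_loss <- ep_loss + fw$loss$value[1] * length(rows)
      }
      val_loss <- eval_loss(model, val_cands)
      if (!is.null(checkpoint_dir)) {
        dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
        saveRDS(model$params,
                file.path(checkpoint_dir, sprintf("epoch_%03d.rds", ep)))
      }
      if (val_loss < best_val) {  # strict: ties keep the earliest epoch
        best_val <- val_loss
        best_params <- model$params
        model$best_epoch <- ep
      }
      log_rows[[ep]] <- tibble(epoch = ep, train_loss = ep_loss / n,
                               val_loss = val_loss)
    }
    model$params <- best_params
    model$log <- dplyr::bind_rows(log_rows)
  })
  model
}

#' @export
predict_scores.seq_model <- function(object, x, ...) {
  cands <- x
  n <- nrow(cands)
  out <- matrix(0, n, 3, dimnames = list(NULL, class_labels()))
  chunk <- 256L
  for (s in seq(1, n, by = chunk)) {
    rows <- s:min(n, s + chunk - 1)
    b <- make_batch(object, cands[rows, , drop = FALSE], with_y = FALSE)
    fw <- seq_forward(object$params, object$spec, b, train = FALSE)
    z <- fw$logits$value
    out[rows, ] <- if (object$spec$loss == "bce") {
      1 / (1 + exp(-z))
    } else {
      sm <- exp(z - apply(z, 1, max))
      sm / rowSums(sm)
    }
  }
  out
}

#' @export
print.seq_model <- function(x, ...) {
  cat("<seq_model> encoder '", x$spec$encoder, "'",
      if (!x$spec$use_structured) " (sequence branch only)",
      ", best epoch ", x$best_epoch, "\n", sep = "")
  invisible(x)
}

#' Count the trainable parameters of a network spec
#'
#' Closed-form parameter count; the difference between a spec with and
#' without the structured branch equals the structured branch's own
#' parameter count plus the widening of the classifier input.
#'
#' @param spec A [network_spec()].
#' @param vocab_size Sequence-tokenizer vocabulary size.
#' @return Integer number of scalar parameters.
#' @export
count_parameters <- function(spec, vocab_size = 0L) {
  p <- with_seed(1L, init_params(spec, vocab_size, spec$emb_dim))
  sum(vapply(p, length, 0L))
}
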