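test_that("CBOW embeddings have the requested width, seeded determinism and zero OOV", {
  segs <- c("apnea hypopnea index was high", "saturation nadir was low",
            "apnea hypopnea index was low")
  emb <- pretrain_embeddings(segs, dim = 12, epochs = 2, seed = 3)
  expect_equal(emb$dim, 12)
  expect_equal(ncol(emb$vectors), 12)
  expect_setequal(emb$vocab, unique(unlist(strsplit(tolower(segs), " "))))
  emb2 <- pretrain_embeddings(segs, dim = 12, epochs = 2, seed = 3)
  expect_identical(emb$vectors, emb2$vectors)
  look <- embedding_lookup(emb, c("apnea", "unseen-token"))
  expect_equal(look[2, ], rep(0, 12))
  expect_false(all(look[1, ] == 0))
  expect_error(pretrain_embeddings(character(0)), "empty")
})

test_that("words sharing contexts embed closer than unrelated words", {
  tpl <- "the %s index was measured during overnight testing tonight"
  segs <- c(sprintf(tpl, rep(c("apnea", "hypopnea"), each = 30)),
            rep("completely different filler sentence about scheduling follow up visits", 30))
  emb <- pretrain_embeddings(segs, dim = 16, epochs = 10, seed = 5)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  v <- function(w) emb$vectors[match(w, emb$vocab), ]
  expect_gt(cosine(v("apnea"), v("hypopnea")),
            cosine(v("apnea"), v("scheduling")))
})

test_that("segment encoding truncates to the cap and masks padding", {
  long <- paste(sprintf("w%d", 1:40), collapse = " ")
  enc <- encode_segment(long, vocab = sprintf("w%d", 1:40))
  expect_length(enc$ids, 32)
  expect_equal(sum(enc$mask), 32)
  empty <- encode_segment("", vocab = c("a"))
  expect_equal(sum(empty$mask), 0)
  expect_equal(empty$ids, rep(0L, 32))
  win21 <- paste(rep("apnea", 21), collapse = " ")
  expect_equal(sum(encode_segment(win21, vocab = "apnea")$mask), 21)
  # OOV tokens get id 0 but still count as real tokens
  enc2 <- encode_segment("apnea unknown", vocab = "apnea")
  expect_equal(enc2$ids[1:2], c(1L, 0L))
  expect_equal(sum(enc2$mask), 2)
})

test_that("forward pass emits (batch, 3) scores and the structured branch takes 6 inputs", {
  cands <- fixture_seq_cands(8)
  for (enc in c("bilstm", "transformer")) {
    spec <- tiny_network_spec(enc)
    vocab <- sort(unique(unlist(strsplit(cands$segment, " "))))
    emb <- if (enc == "bilstm") tiny_embeddings(vocab) else NULL
    model <- structure(list(spec = spec, vocab = vocab, embeddings = emb,
                            struct_norm = list(mu = rep(0, 6), sd = rep(1, 6)),
                            params = withr::with_seed(2, sleepscan:::init_params(
                              spec, length(vocab), 5))),
                       class = "seq_model")
    b <- sleepscan:::make_batch(model, cands)
    fw <- sleepscan:::seq_forward(model$params, spec, b)
    expect_equal(dim(fw$logits$value), c(8, 3))
    expect_equal(ncol(b$struct), 6)
    p <- predict_scores(model, cands)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("autodiff gradients agree with numerical differentiation", {
  cands <- fixture_seq_cands(6)
  for (enc in c("bilstm", "transformer")) {
    spec <- tiny_network_spec(enc)
    vocab <- sort(unique(unlist(strsplit(cands$segment, " "))))
    emb <- if (enc == "bilstm") tiny_embeddings(vocab) else NULL
    model <- structure(list(spec = spec, vocab = vocab, embeddings = emb,
                            struct_norm = list(mu = rep(0, 6), sd = rep(1, 6)),
                            params = withr::with_seed(3, sleepscan:::init_params(
                              spec, length(vocab), 5))),
                       class = "seq_model")
    b <- sleepscan:::make_batch(model, cands)
    fw <- sleepscan:::seq_forward(model$params, spec, b)
    g <- sleepscan:::ad_backward(fw$tape, fw$loss)
    grads <- lapply(fw$leaf, function(nd) g[[nd$id]])
    eps <- 1e-5
    loss_at <- function(p) sleepscan:::seq_forward(p, spec, b)$loss$value[1]
    withr::with_seed(4, {
      for (nm in sample(names(model$params), 8)) {
        i <- sample(length(model$params[[nm]]), 1)
        p2 <- model$params
        p2[[nm]][i] <- p2[[nm]][i] + eps
        up <- loss_at(p2)
        p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
        dn <- loss_at(p2)
        num <- (up - dn) / (2 * eps)
        ana <- if (is.null(grads[[nm]])) 0 else grads[[nm]][i]
        expect_lt(abs(num - ana), 1e-4 + 1e-3 * abs(num))
      }
    })
    # gradient flows to both branches: some structured and some encoder
    # parameter receives a nonzero gradient
    expect_gt(sum(abs(grads$Ws1)), 0)
    enc_par <- if (enc == "bilstm") "W_l1f" else "Wq_l1"
    expect_gt(sum(abs(grads[[enc_par]])), 0)
  }
})

test_that("toggling the structured branch changes the parameter count in closed form", {
  for (enc in c("bilstm", "transformer")) {
    with_s <- tiny_network_spec(enc, use_structured = TRUE)
    without <- tiny_network_spec(enc, use_structured = FALSE)
    diff <- count_parameters(with_s, vocab_size = 50) -
      count_parameters(without, vocab_size = 50)
    f <- with_s$ffnn_struct
    # structured branch itself plus the widened classifier input rows
    expected <- (6 * f + f) + (f * f + f) + f * with_s$ffnn_head
    expect_equal(diff, expected)
  }
})

test_that("training overfits a tiny fixture, checkpoints on validation loss, and is seeded", {
  corp <- fixture_corpus()
  cands <- fixture_candidates(corp)
  ids <- unique(cands$report_id)
  tr <- cands[cands$report_id %in% ids[1:6], ]
  va <- cands[cands$report_id %in% ids[7:9], ]
  tr <- tr[seq_len(min(40, nrow(tr))), ]
  spec <- network_spec("transformer", d_model = 8, n_layers = 1,
                       ffnn_struct = 8, ffnn_seq = 8, ffnn_head = 12)
  cfg <- train_config(batch_size = 16, lr = 3e-3, epochs = 6, seed = 11)
  m <- fit_sequence_model(tr, va, spec = spec, cfg = cfg)
  expect_lt(dplyr::last(m$log$train_loss), m$log$train_loss[1])
  expect_equal(m$best_epoch, which.min(m$log$val_loss))
  expect_equal(nrow(m$log), 6)
  m2 <- fit_sequence_model(tr, va, spec = spec, cfg = cfg)
  expect_identical(m$params, m2$params)
  expect_identical(m$log, m2$log)
  expect_equal(m$best_epoch, m2$best_epoch)
  # batching invariance of inference
  p1 <- predict_scores(m, va)
  p2 <- do.call(rbind, lapply(seq_len(nrow(va)), function(i) {
    predict_scores(m, va[i, , drop = FALSE])
  }))
  expect_equal(p1, p2, tolerance = 1e-12)
  # report-overlapping train/val is rejected
  expect_error(fit_sequence_model(tr, tr, spec = spec, cfg = cfg),
               "disjoint")
})

test_that("sequence-only specs reject no one and omit the structured branch", {
  spec <- tiny_network_spec("transformer", use_structured = FALSE)
  p <- withr::with_seed(1, sleepscan:::init_params(spec, 20, 5))
  expect_false("Ws1" %in% names(p))
  expect_equal(nrow(p$Wh), spec$ffnn_seq)
})
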