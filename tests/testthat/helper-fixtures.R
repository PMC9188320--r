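# Shared fixtures, generated in code (no stored data).

# Small-page geometry so rendering-based tests stay fast.
small_geom <- function() {
  list(width = 600, height = 800, margin = 30, char_w = 6, word_h = 10,
       line_h = 14, space_w = 4)
}

# A small default-template corpus; memoised per (n, seed) within a run.
fixture_corpus <- local({
  cache <- list()
  function(n = 30, seed = 11, ...) {
    key <- paste(n, seed, ...)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- generate_corpus(corpus_spec(
        n_reports = n, seed = seed,
        numerics_per_page = list(mean = 15, sd = 3, min = 5, max = 25),
        pages_per_report = list(values = 1:2, prob = c(.6, .4)), ...))
    }
    cache[[key]]
  }
})

fixture_candidates <- function(corpus) {
  segment_corpus(deid_corpus(corpus$words, corpus$phi), corpus$gold)
}

# A one-page word plan laid out on the small geometry.
fixture_plan <- function(texts, geom = small_geom()) {
  n <- length(texts)
  w <- nchar(texts) * geom$char_w
  x <- geom$margin
  left <- integer(n)
  for (i in seq_len(n)) {
    left[i] <- x
    x <- x + w[i] + geom$space_w
  }
  tibble::tibble(text = texts, left = left, top = geom$margin,
                 width = w, height = geom$word_h, conf = 99)
}

# Random candidate rows for exercising the sequence models.
fixture_seq_cands <- function(n, seed = 42) {
  withr::with_seed(seed, tibble::tibble(
    report_id = rep(sprintf("R%02d", seq_len(ceiling(n / 4))), each = 4)[1:n],
    cand_idx = 0:(n - 1), token = "1", value = runif(n, 0, 100),
    left = runif(n, 0, 2000), top = runif(n, 0, 3000),
    width = runif(n, 20, 200), height = runif(n, 20, 60),
    page_num = sample(1:3, n, TRUE),
    segment = replicate(n, paste(sample(
      c("ahi", "was", "lowest", "desaturation", "index", "sleep", "the",
        "total", "apnea", "hour"), sample(5:12, 1), TRUE), collapse = " ")),
    label = sample(class_labels(), n, TRUE)))
}

tiny_network_spec <- function(encoder, ...) {
  network_spec(encoder, max_len = 6, emb_dim = 5, hidden = 4, n_layers = 2,
               d_model = 6, ffnn_struct = 5, ffnn_seq = 5, ffnn_head = 7,
               dropout = 0, ...)
}

tiny_embeddings <- function(vocab, dim = 5, seed = 1) {
  withr::with_seed(seed, structure(
    list(vocab = vocab, vectors = matrix(rnorm(length(vocab) * dim), ncol = dim),
         dim = dim), class = "w2v_embeddings"))
}
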