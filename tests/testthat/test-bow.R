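test_that("vocabulary keeps the top terms by frequency without stopwords", {
  segs <- c(rep("apnea hypopnea index", 5), rep("apnea saturation", 3),
            "the was and of nadir")
  v <- build_vocab(segs)
  expect_s3_class(v, "bow_vocab")
  expect_equal(v$terms[1], "apnea")  # highest frequency
  expect_false(any(v$terms %in% english_stopwords()))
  expect_false("the" %in% v$terms)
  expect_true("nadir" %in% v$terms)
  expect_length(v$terms, 5)  # fewer distinct terms than the cap
  expect_true(all(is.finite(v$idf)))
  expect_error(build_vocab(character(0)), "empty")
})

test_that("vocabulary caps at 400 terms with lexicographic tie-breaks", {
  segs <- vapply(1:450, function(i) paste0("term", sprintf("%03d", i)), "")
  v <- build_vocab(c(segs, segs))  # every term has frequency 2 (tied)
  expect_length(v$terms, 400)
  expect_equal(v$terms, sort(v$terms))
  expect_equal(v$terms[1], "term001")
  # smoothed idf: ln((1+n)/(1+df)) + 1
  n <- 900
  expect_equal(v$idf[1], log((1 + n) / (1 + 2)) + 1)
})

test_that("vocabulary is built from training windows only (no leakage)", {
  corp <- fixture_corpus()
  cands <- fixture_candidates(corp)
  sp <- split_documents(corp$gold$report_id, 1)
  dev <- cands[cands$report_id %in% sp$dev_ids, ]
  v1 <- build_vocab(dev$segment)
  # shuffling or dropping test data leaves the vocabulary unchanged
  v2 <- build_vocab(dev$segment[sample.int(nrow(dev))])
  expect_identical(v1$terms, v2$terms)
})

test_that("featurization yields structured block plus unit-norm tf-idf", {
  segs <- c("apnea index value", "unrelated words here")
  v <- build_vocab(c("apnea index", "apnea value"))
  cands <- tibble::tibble(report_id = "R1", cand_idx = 0:1,
                          token = c("19.5.", "26"), value = c(19.5, 26),
                          left = c(1048, 735), top = c(385, 388),
                          width = c(111, 61), height = c(50, 26),
                          page_num = c(1L, 1L), segment = segs)
  x <- featurize(cands, v)
  expect_equal(ncol(x), 6 + length(v$terms))
  # the canonical structured row: left, top, width, height, page, value
  expect_equal(unname(x[1, 1:6]), c(1048, 385, 111, 50, 1, 19.5))
  tfidf1 <- x[1, -(1:6)]
  expect_equal(sqrt(sum(tfidf1^2)), 1)     # unit L2 norm
  expect_equal(unname(x[2, -(1:6)]), rep(0, length(v$terms)))  # no vocab terms
  # deterministic given vocab
  expect_identical(x, featurize(cands, v))
})

test_that("separable fixtures are fit exactly and degenerate input errors", {
  withr::local_seed(1)
  n <- 60
  y <- rep(class_labels(), each = n / 3)
  # markers dwarf the 6 standardized noise columns in any distance metric
  x <- cbind(matrix(runif(n * 6), n, 6),
             ahi_marker = 10 * as.numeric(y == "AHI"),
             sao2_marker = 10 * as.numeric(y == "SaO2"))
  for (clf in c("rf", "knn")) {
    m <- train_bow(x, y, clf, seed = 1)
    p <- predict_scores(m, x)
    expect_equal(colnames(p), class_labels())
    expect_equal(colnames(p)[max.col(p)], y)  # training accuracy 1.0
  }
  expect_error(train_bow(x[y == "AHI", ], y[y == "AHI"], "rf"), "2 classes")
})

test_that("kNN with k = 3 follows the neighbour majority", {
  x <- matrix(c(0, 0, 0.1, 0, 0, 0.1, 5, 5, 5.1, 5, 5, 5.1), ncol = 2,
              byrow = TRUE)
  y <- c("AHI", "AHI", "AHI", "SaO2", "SaO2", "SaO2")
  m <- train_bow(x, y, "knn")
  p <- predict_scores(m, matrix(c(0.03, 0.03), 1))
  expect_equal(colnames(p)[which.max(p)], "AHI")
  expect_equal(unname(p[1, "AHI"]), 1)  # all 3 neighbours agree
})

test_that("multinomial NB with alpha = 0.5 smooths unseen terms", {
  x <- rbind(c(3, 0, 1), c(2, 0, 1), c(0, 4, 1), c(0, 3, 1))
  y <- c("AHI", "AHI", "SaO2", "SaO2")
  fit <- sleepscan:::fit_multinomial_nb(x, factor(y, levels = class_labels()),
                                        alpha = 0.5)
  # feature 2 unseen in class AHI still has positive smoothed likelihood
  expect_true(is.finite(fit$loglik["AHI", 2]))
  expect_equal(unname(exp(fit$loglik["AHI", 2])),
               0.5 / (sum(c(5, 0, 2)) + 0.5 * 3), tolerance = 1e-12)
  p <- sleepscan:::predict_multinomial_nb(fit, rbind(c(4, 0, 1)))
  expect_gt(p[1, "AHI"], p[1, "SaO2"])
})

test_that("every classifier emits calibrated-shape probability matrices", {
  corp <- fixture_corpus()
  cands <- fixture_candidates(corp)
  sp <- split_documents(corp$gold$report_id, 1)
  dev <- cands[cands$report_id %in% sp$dev_ids, ]
  te <- cands[cands$report_id %in% sp$test_ids, ]
  v <- build_vocab(dev$segment)
  x <- featurize(dev, v)
  xt <- featurize(te, v)
  for (clf in c("lr", "lasso", "ridge", "svm", "knn", "nb", "rf")) {
    m <- train_bow(x, dev$label, clf, seed = 1)
    p <- predict_scores(m, xt)
    expect_equal(dim(p), c(nrow(te), 3))
    expect_equal(colnames(p), class_labels())
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("cross-validation selects by mean fold accuracy over report folds", {
  corp <- fixture_corpus()
  cands <- fixture_candidates(corp)
  cands <- cands[cands$report_id %in% unique(cands$report_id)[1:30], ]
  v <- build_vocab(cands$segment)
  x <- featurize(cands, v)
  grid <- list(list(k = 3), list(k = 9))
  cv <- cross_validate(x, cands$label, cands$report_id, "knn", grid,
                       k = 5, seed = 6)
  # brute-force fold accounting with the same fold assignment
  fold <- cv$folds[cands$report_id]
  acc <- vapply(grid, function(g) {
    mean(vapply(1:5, function(f) {
      m <- train_bow(x[fold != f, ], cands$label[fold != f], "knn", g, seed = 6)
      p <- predict_scores(m, x[fold == f, , drop = FALSE])
      mean(colnames(p)[max.col(p, ties.method = "first")] ==
             cands$label[fold == f])
    }, 0))
  }, 0)
  expect_equal(cv$cv$mean_accuracy, acc)
  expect_equal(cv$best_params, grid[[which.max(acc)]])
  # every report sits in exactly one fold
  expect_length(cv$folds, 30)
  expect_true(all(table(cv$folds) >= 1))
  # single grid point: that point is selected
  cv1 <- cross_validate(x, cands$label, cands$report_id, "nb",
                        grid = list(list(alpha = 0.5)), seed = 1)
  expect_equal(cv1$best_params, list(alpha = 0.5))
  expect_error(cross_validate(x, cands$label, rep("R1", nrow(x)), "nb",
                              list(list())), "fewer reports")
})
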