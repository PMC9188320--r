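# The canonical example segment: candidates "19.5." and "0" are the only
# words fully matching [0-9.,%]+.
table1_segment <- c("The", "Medicare", "scoring", "rule.", "The", "total",
                    "APNEA/HYPOPNEA", "INDEX", "(AHI)", "was", "19.5.",
                    "The", "patient", "also", "had", "0", "respiratory",
                    "event", "related", "arousals", "(RERA)")

mk_report_words <- function(texts, report_id = "R1") {
  tibble::tibble(report_id = report_id, page_num = 1L,
                 order_idx = seq_along(texts) - 1L, text = texts,
                 left = (seq_along(texts) - 1L) * 30L, top = 10L,
                 width = 25L, height = 10L, conf = 99)
}

test_that("candidate detection applies the anchored pattern and drops unparseable tokens", {
  w <- mk_report_words(table1_segment)
  cands <- find_candidates(w)
  expect_equal(cands$token, c("19.5.", "0"))
  expect_equal(cands$value, c(19.5, 0))
  expect_equal(nrow(find_candidates(mk_report_words(c("(AHI)", "was")))), 0)
  expect_equal(nrow(find_candidates(mk_report_words(c("%", ".,")))), 0)
})

test_that("numeric parsing strips percent, trailing punctuation and thousands commas", {
  expect_equal(parse_numeric("19.5."), 19.5)
  expect_equal(parse_numeric("87"), 87.0)
  expect_equal(parse_numeric("95%"), 95.0)
  expect_equal(parse_numeric("1,024"), 1024)
  expect_equal(parse_numeric("12,345,678"), 12345678)
  expect_equal(parse_numeric("7,"), 7)
  expect_true(is.na(parse_numeric("%")))
  expect_true(is.na(parse_numeric(".,")))
  expect_true(is.na(parse_numeric("1,23")))
  expect_true(is.na(parse_numeric("1.2.3")))
})

test_that("context windows hold 10 words a side and truncate only at report bounds", {
  w <- mk_report_words(table1_segment)
  idx <- which(w$text == "19.5.")
  win <- build_window(w, idx)
  expect_length(win, 21)
  expect_equal(win[11], "19.5.")
  expect_equal(win, table1_segment)  # the printed segment is the window
  short <- mk_report_words(c("5", "words", "only", "here", "now"))
  expect_equal(build_window(short, 1), short$text[1:5])
  expect_length(build_window(short, 1), 5)
})

test_that("windows cross page boundaries within a report", {
  w <- mk_report_words(sprintf("w%02d", 1:30))
  w$page_num <- rep(1:2, each = 15)
  w$text[20] <- "42"
  cands <- segment_corpus(w)
  seg <- strsplit(cands$segment, " ")[[1]]
  expect_length(seg, 21)
  expect_equal(seg[1], "w10")  # window reaches back onto page 1
})

test_that("labels match gold values with AHI precedence on double matches", {
  gold <- tibble::tibble(report_id = "R1", ahi = 19.5, sao2 = 87)
  expect_equal(assign_labels(c(19.5, 87, 26), gold),
               c("AHI", "SaO2", "Other"))
  both <- tibble::tibble(report_id = "R1", ahi = 50, sao2 = 50)
  expect_equal(assign_labels(50, both), "AHI")
  expect_equal(assign_labels(numeric(0), gold), character(0))
  # tolerance flag for rounded gold values
  expect_equal(assign_labels(19.4, gold, tol = 0.2), "AHI")
})

test_that("label assignment reproduces planted roles exactly on collision-suppressed corpora", {
  corp <- fixture_corpus()
  words <- deid_corpus(corp$words, corp$phi)
  cands <- segment_corpus(words, corp$gold)
  planted <- words
  planted$label_from_role <- c(AHI = "AHI", SaO2 = "SaO2",
                               distractor = "Other",
                               prose = "Other")[planted$role]
  key <- merge(cands, planted[, c("report_id", "left", "top", "page_num",
                                  "label_from_role")],
               by = c("report_id", "left", "top", "page_num"))
  expect_equal(nrow(key), nrow(cands))
  expect_true(all(key$label == key$label_from_role))
})

test_that("document splits reproduce the canonical 70/30 and 6:1 sizes", {
  ids <- sprintf("R%04d", 1:955)
  sp <- split_documents(ids, seed = 4)
  expect_length(sp$dev_ids, 669)
  expect_length(sp$test_ids, 286)
  expect_length(sp$train_ids, 574)
  expect_length(sp$val_ids, 95)
  sp10 <- split_documents(sprintf("R%02d", 1:10), seed = 1)
  expect_length(sp10$dev_ids, 7)
  expect_length(sp10$test_ids, 3)
  expect_error(split_documents(sprintf("R%d", 1:9), 1), "at least 10")
})

test_that("splits partition reports disjointly and exhaustively", {
  ids <- sprintf("R%03d", 1:137)
  sp <- split_documents(ids, seed = 99)
  expect_setequal(c(sp$dev_ids, sp$test_ids), ids)
  expect_length(intersect(sp$dev_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$val_ids), sp$dev_ids)
  expect_length(intersect(sp$train_ids, sp$val_ids), 0)
  # deterministic given seed
  expect_identical(sp, split_documents(ids, seed = 99))
})

test_that("training subsets are seeded, unique and size-checked", {
  train <- sprintf("R%03d", 1:120)
  subs <- subsample_training(train, seed = 7)
  expect_named(subs, c("10", "25", "50", "100"))
  for (nm in names(subs)) {
    expect_length(subs[[nm]], as.integer(nm))
    expect_length(unique(subs[[nm]]), as.integer(nm))
    expect_true(all(subs[[nm]] %in% train))
  }
  expect_identical(subs, subsample_training(train, seed = 7))
  expect_setequal(subsample_training(train, sizes = 120, seed = 1)[["120"]],
                  train)
  expect_error(subsample_training(train, sizes = 121, seed = 1), "sizes")
})
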