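test_that("the perfect backend recovers exactly the planted words", {
  plan <- fixture_plan(c("The", "total", "AHI", "was", "19.5.", "with", "0",
                         "arousals", "noted", "last", "night", "overall"))
  img <- render_page(plan, small_geom(), report_id = "R1", page_num = 2)
  words <- run_ocr(img, "perfect")
  expect_equal(nrow(words), 12)
  expect_equal(words$text, plan$text)
  expect_equal(words$left, plan$left)
  expect_equal(words$width, plan$width)
  expect_equal(words$page_num, rep(2L, 12))
  expect_equal(words$order_idx, 0:11)
  # all bboxes inside the page
  g <- small_geom()
  expect_true(all(words$left >= 0 & words$top >= 0 &
                    words$left + words$width <= g$width &
                    words$top + words$height <= g$height))
})

test_that("a blank page yields an empty word sequence", {
  img <- render_page(fixture_plan(character(0)), small_geom())
  expect_equal(nrow(run_ocr(img, "perfect")), 0)
})

test_that("the tesseract backend errors by name when the engine is absent", {
  skip_if(Sys.which("tesseract") != "", "engine present")
  img <- render_page(fixture_plan("hi"), small_geom())
  expect_error(run_ocr(img, "tesseract"), "Tesseract")
})

test_that("OCR TSV writing and parsing round-trip, including the canonical row", {
  words <- tibble::tibble(page_num = 1L, order_idx = 0L, text = "19.5.",
                          conf = 96.0, left = 1048L, top = 385L,
                          width = 111L, height = 50L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ocr_tsv(words, path)
  back <- parse_ocr_tsv(path)
  expect_equal(back$left, 1048L)
  expect_equal(back$top, 385L)
  expect_equal(back$width, 111L)
  expect_equal(back$height, 50L)
  expect_equal(back$text, "19.5.")
  expect_equal(back[, names(words)], words)
})

test_that("TSV parsing handles header-only input, conf floors, and bad rows", {
  hdr <- "page_num\tleft\ttop\twidth\theight\tconf\ttext"
  expect_equal(nrow(parse_ocr_tsv(hdr)), 0)
  two <- c(hdr, "1\t0\t0\t5\t5\t20\tlow", "1\t10\t0\t5\t5\t90\thigh")
  expect_equal(parse_ocr_tsv(two, conf_floor = 50)$text, "high")
  expect_error(parse_ocr_tsv(c(hdr, "1\t2\t3")), "line 2")
  expect_error(parse_ocr_tsv(c(hdr, "1\tx\t3\t4\t5\t6\tw")), "line 2")
  expect_error(parse_ocr_tsv("left\ttop"), "header")
})

test_that("overlay drawing touches only rectangle perimeters", {
  plan <- fixture_plan(c("alpha", "beta"))
  img <- render_page(plan, small_geom())
  words <- run_ocr(img, "perfect")
  out <- draw_overlay(img, words)
  expect_identical(draw_overlay(img, words[0, ]), img)  # 0 words: unchanged
  # pixels off the perimeters are untouched
  perim <- matrix(FALSE, nrow(img), ncol(img))
  for (i in seq_len(nrow(words))) {
    r <- (words$top[i] + 1):(words$top[i] + words$height[i])
    cc <- (words$left[i] + 1):(words$left[i] + words$width[i])
    perim[range(r), cc] <- TRUE
    perim[r, range(cc)] <- TRUE
  }
  expect_true(all(out[!perim] == img[!perim]))
  expect_true(all(out[perim] == 0))
  # a word outside the page is an error
  bad <- words
  bad$left[1] <- 10000L
  expect_error(draw_overlay(img, bad), "outside")
})

test_that("confusion noise is seeded, rate-0 inert, and geometry-preserving", {
  words <- tibble::tibble(page_num = 1L, order_idx = 0:2,
                          text = c("III", "Ole", "Safe"), conf = 99,
                          left = c(0L, 50L, 100L), top = 0L,
                          width = 30L, height = 10L)
  expect_identical(inject_ocr_noise(words, 0), words)
  forced <- inject_ocr_noise(words, 1, seed = 1, table = list(I = "!"))
  expect_equal(forced$text[1], "!!!")
  expect_equal(forced$text[3], "Safe")  # no table entry for its letters
  a <- inject_ocr_noise(words, 0.5, seed = 42)
  b <- inject_ocr_noise(words, 0.5, seed = 42)
  expect_identical(a, b)
  expect_equal(a[, c("left", "top", "width", "height", "order_idx")],
               words[, c("left", "top", "width", "height", "order_idx")])
  expect_equal(nrow(a), nrow(words))
})

test_that("the degraded backend gets cleaner as preprocessing removes speckle", {
  plan <- fixture_plan(c("IlIlIl", "OscOsc", "IlSOIl", "SIOlSI"))
  img <- withr::with_seed(3, render_page(plan, small_geom(), noise_n = 400))
  raw_words <- withr::with_seed(1, run_ocr(img, "degraded", seed = 5))
  prepped <- apply_method(img, "gray_de_c20")
  clean_words <- withr::with_seed(1, run_ocr(prepped, "degraded", seed = 5))
  n_sub <- function(w) sum(w$text != plan$text)
  expect_gt(n_sub(raw_words), 0)
  expect_lt(n_sub(clean_words), n_sub(raw_words))
})
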