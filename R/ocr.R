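# OCR adapter layer: engine-free synthetic backends, the word-position TSV
# dialect, QA overlays, and seeded character-confusion noise.

ocr_tsv_cols <- c("page_num", "left", "top", "width", "height", "conf", "text")

default_confusion_table <- function() {
  list(I = c("!", ")"), l = "1", O = "0", S = "5")
}

#' Run OCR on a page image
#'
#' Backends:
#' * `"perfect"` returns exactly the planted word plan carried by a
#'   rendered synthetic page (word recognition from pixels is out of
#'   scope; the plan is ground truth).
#' * `"perfect-noise"` is the perfect backend followed by
#'   [inject_ocr_noise()] at `noise_rate`.
#' * `"degraded"` couples the character error rate to image quality: the
#'   rate is proportional to the fraction of dark pixels lying outside any
#'   planted word box (residual speckle), so better preprocessing yields
#'   cleaner text. rate = min(0.5, 200 * residual dark fraction).
#' * `"tesseract"` shells out to an external Tesseract binary if one is on
#'   the PATH, mapping its word-level TSV into the package dialect, and
#'   fails with an explicit error naming the engine otherwise.
#'
#' @param img A `page_image` carrying a `plan` attribute (for the
#'   synthetic backends).
#' @param backend One of `"perfect"`, `"perfect-noise"`, `"degraded"`,
#'   `"tesseract"`.
#' @param noise_rate Per-character substitution probability for
#'   `"perfect-noise"`.
#' @param seed Seed for the noise backends.
#' @return A tibble of OCR words (`page_num`, `order_idx`, `text`, `conf`,
#'   `left`, `top`, `width`, `height`), in reading order, with empty and
#'   whitespace-only tokens dropped.
#' @export
run_ocr <- function(img, backend = c("perfect", "perfect-noise", "degraded",
                                     "tesseract"),
                    noise_rate = 0.02, seed = NULL) {
  backend <- match.arg(backend)
  if (backend == "tesseract") {
    if (Sys.which("tesseract") == "") {
      abort("OCR backend 'tesseract' requires the Tesseract engine, which is not installed on this system")
    }
    return(run_tesseract(img))
  }
  plan <- attr(img, "plan")
  assert_that(!is.null(plan), "synthetic OCR backends need a page_image with a word plan")
  words <- tibble(
    page_num = as.integer(attr(img, "page_num") %||% 1L),
    order_idx = seq_len(nrow(plan)) - 1L,
    text = plan$text,
    conf = if ("conf" %in% names(plan)) plan$conf else 99,
    left = plan$left, top = plan$top,
    width = plan$width, height = plan$height)
  words <- words[!grepl("^\\s*$", words$text), , drop = FALSE]
  words$order_idx <- seq_len(nrow(words)) - 1L

  if (backend == "perfect-noise") {
    words <- inject_ocr_noise(words, noise_rate, seed)
  } else if (backend == "degraded") {
    gray <- to_grayscale(img)
    dark <- gray < 128
    inside <- matrix(FALSE, nrow(gray), ncol(gray))
    for (i in seq_len(nrow(plan))) {
      inside[(plan$top[i] + 1):(plan$top[i] + plan$height[i]),
             (plan$left[i] + 1):(plan$left[i] + plan$width[i])] <- TRUE
    }
    resid_frac <- sum(dark & !inside) / length(gray)
    rate <- min(0.5, 200 * resid_frac)
    words <- inject_ocr_noise(words, rate, seed)
  }
  words
}

# Adapter for the external engine's native word-level TSV: keeps rows at
# word level and maps its columns into the package dialect.
run_tesseract <- function(img, dpi = 300) {
  tmp_png <- tempfile(fileext = ".png")
  tmp_out <- tempfile()
  write_page_png(to_grayscale(img), tmp_png)
  system2("tesseract", c(tmp_png, tmp_out, "--dpi", dpi, "tsv"),
          stdout = FALSE, stderr = FALSE)
  raw <- read.delim(paste0(tmp_out, ".tsv"), quote = "", stringsAsFactors = FALSE)
  raw <- raw[raw$level == 5 & !grepl("^\\s*$", raw$text), , drop = FALSE]
  tibble(page_num = as.integer(attr(img, "page_num") %||% 1L),
         order_idx = seq_len(nrow(raw)) - 1L,
         text = raw$text, conf = raw$conf,
         left = raw$left, top = raw$top,
         width = raw$width, height = raw$height)
}

#' Parse the word-position TSV dialect
#'
#' The dialect has a header line `page_num left top width height conf text`
#' (tab-separated). `order_idx` is assigned from row order; rows below the
#' confidence floor are dropped.
#'
#' @param path Path to a TSV file (or a character vector of lines).
#' @param conf_floor Drop words with confidence below this value; the
#'   default -1 keeps everything.
#' @return A tibble of OCR words.
#' @export
parse_ocr_tsv <- function(path, conf_floor = -1) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  assert_that(length(lines) >= 1, "empty OCR TSV")
  hdr <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  assert_that(identical(hdr, ocr_tsv_cols),
              paste0("bad OCR TSV header: ", paste(hdr, collapse = ",")))
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(tibble(page_num = integer(), order_idx = integer(),
                  text = character(), conf = numeric(), left = integer(),
                  top = integer(), width = integer(), height = integer()))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 7L)) {
    bad <- which(nfield != 7L)[1]
    abort(paste0("malformed OCR TSV row at line ", bad + 1L,
                 ": expected 7 fields, got ", nfield[bad]))
  }
  m <- do.call(rbind, parts)
  num <- suppressWarnings(apply(m[, 1:6, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 6)
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0)[1]
    abort(paste0("malformed OCR TSV row at line ", bad + 1L,
                 ": non-numeric coordinate or confidence"))
  }
  out <- tibble(page_num = as.integer(num[, 1]),
                order_idx = seq_len(nrow(m)) - 1L,
                text = m[, 7], conf = num[, 6],
                left = as.integer(num[, 2]), top = as.integer(num[, 3]),
                width = as.integer(num[, 4]), height = as.integer(num[, 5]))
  out <- out[out$conf >= conf_floor, , drop = FALSE]
  out$order_idx <- seq_len(nrow(out)) - 1L
  out
}

#' Write OCR words in the TSV dialect
#'
#' @param words OCR word tibble.
#' @param path Output path.
#' @export
write_ocr_tsv <- function(words, path) {
  df <- as.data.frame(words[, ocr_tsv_cols])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Draw word-outline overlays for OCR quality inspection
#'
#' Draws a 1-px black rectangle along the perimeter of each word's bounding
#' box; pixels outside the perimeters are untouched.
#'
#' @param img A gray `page_image`.
#' @param words OCR word tibble for this page.
#' @return The image with outlines drawn.
#' @export
draw_overlay <- function(img, words) {
  assert_that(is.matrix(img), "draw_overlay expects a gray image matrix")
  H <- nrow(img); W <- ncol(img)
  out <- img
  for (i in seq_len(nrow(words))) {
    l <- words$left[i]; t <- words$top[i]
    r <- l + words$width[i]; b <- t + words$height[i]
    assert_that(l >= 0 && t >= 0 && r <= W && b <= H,
                paste0("word ", i, " lies outside the page"))
    rows <- (t + 1):b; cols <- (l + 1):r
    out[c(t + 1, b), cols] <- 0L
    out[rows, c(l + 1, r)] <- 0L
  }
  keep_img_attrs(out, img)
}

#' Inject character-confusion OCR noise
#'
#' Per character, with probability `rate`, substitutes from a confusion
#' table (default: I to ! or ), l to 1, O to 0, S to 5 — the substitution
#' patterns seen in real engine output). Word count, order and bounding
#' boxes are unchanged; seeded for reproducibility.
#'
#' @param words OCR word tibble.
#' @param rate Per-character substitution probability in \[0, 1\].
#' @param seed Optional integer seed.
#' @param table Named list mapping characters to replacement candidates.
#' @return The word tibble with noisy text.
#' @export
inject_ocr_noise <- function(words, rate, seed = NULL,
                             table = default_confusion_table()) {
  assert_that(is_prob(rate), "rate must be in [0, 1]")
  if (rate == 0 || nrow(words) == 0) return(words)
  with_seed(seed, {
    words$text <- vapply(words$text, function(w) {
      ch <- strsplit(w, "", fixed = TRUE)[[1]]
      for (j in seq_along(ch)) {
        if (!is.null(table[[ch[j]]]) && runif(1) < rate) {
          repl <- table[[ch[j]]]
          ch[j] <- repl[sample.int(length(repl), 1)]
        }
      }
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    words
  })
}
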