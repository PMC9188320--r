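#' Rasterise a page plan into a synthetic scanned-page image
#'
#' Draws each planted word inside its recorded bounding box as a row of
#' filled character blocks (an abstract, synthetic glyph: recognition is
#' performed by the plan-reading perfect-OCR backend, not from pixels, so
#' glyph shape only matters for the image-preprocessing path). Optional
#' speckle noise plants isolated dark pixels away from any ink, recording
#' their positions so preprocessing can be scored against the known noise
#' mask.
#'
#' @param plan Tibble of words for one page with columns `text`, `left`,
#'   `top`, `width`, `height` (pixel coordinates, top-left origin).
#' @param geom Page geometry list (see [corpus_spec()]); `width`/`height`
#'   give the page size in pixels.
#' @param ink,bg Ink and background gray levels (0-255).
#' @param noise_n Number of isolated dark noise pixels to plant.
#' @param noise_value Gray level of noise pixels.
#' @param color If `TRUE`, return an H x W x 3 color array (a lightly
#'   tinted scan) instead of a gray matrix.
#' @param report_id,page_num Identifiers carried on the image.
#' @return An integer matrix (or 3-channel array) of class `page_image`
#'   with attributes `report_id`, `page_num`, `plan` and `noise`
#'   (a 2-column matrix of planted noise pixel row/col indices).
#' @export
render_page <- function(plan, geom = NULL, ink = 40, bg = 255,
                        noise_n = 0, noise_value = 30, color = FALSE,
                        report_id = NA_character_, page_num = 1L) {
  geom <- geom %||% list(width = 2550, height = 3300, char_w = 22)
  H <- geom$height; W <- geom$width
  n <- nrow(plan)
  if (n > 0) {
    bad <- plan$left < 0 | plan$top < 0 |
      plan$left + plan$width > W | plan$top + plan$height > H
    assert_that(!any(bad), "plan contains words outside the page bounds")
    # overlapping boxes are a layout error
    if (n > 1) {
      o <- order(plan$top, plan$left)
      l <- plan$left[o]; t <- plan$top[o]
      r <- l + plan$width[o]; b <- t + plan$height[o]
      for (i in seq_len(n - 1)) {
        j <- (i + 1):n
        hit <- l[j] < r[i] & r[j] > l[i] & t[j] < b[i] & b[j] > t[i]
        assert_that(!any(hit), "plan contains overlapping bounding boxes")
      }
    }
  }

  img <- matrix(as.integer(bg), H, W)
  if (n > 0) {
    for (i in seq_len(n)) {
      nch <- nchar(plan$text[i])
      cw <- plan$width[i] / nch
      # keep stroke blocks at least 3 px wide so a 3x3 morphological
      # opening restores them exactly
      char_gap <- max(1L, min(4L, floor(cw) - 3L))
      rows <- (plan$top[i] + 1):(plan$top[i] + plan$height[i])
      for (k in seq_len(nch)) {
        c0 <- round(plan$left[i] + (k - 1) * cw) + 1L
        c1 <- round(plan$left[i] + k * cw) - char_gap
        if (c1 >= c0) img[rows, c0:c1] <- as.integer(ink)
      }
    }
  }

  noise <- matrix(integer(0), 0, 2)
  if (noise_n > 0) {
    # isolated: full 3x3 neighborhood must be background and not touch
    # previously planted noise
    occupied <- img < bg
    cand_r <- sample(2:(H - 1), noise_n * 4, replace = TRUE)
    cand_c <- sample(2:(W - 1), noise_n * 4, replace = TRUE)
    placed <- 0L
    keep <- matrix(0L, noise_n, 2)
    for (i in seq_along(cand_r)) {
      r <- cand_r[i]; cc <- cand_c[i]
      if (!any(occupied[(r - 1):(r + 1), (cc - 1):(cc + 1)])) {
        placed <- placed + 1L
        keep[placed, ] <- c(r, cc)
        occupied[(r - 1):(r + 1), (cc - 1):(cc + 1)] <- TRUE
        if (placed == noise_n) break
      }
    }
    noise <- keep[seq_len(placed), , drop = FALSE]
    img[noise] <- as.integer(noise_value)
  }

  if (color) {
    # lightly blue-tinted scan; luma of the tint rounds back to the gray level
    arr <- array(0L, dim = c(H, W, 3))
    arr[, , 1] <- img
    arr[, , 2] <- img
    arr[, , 3] <- img
    img <- arr
  }
  structure(img, class = "page_image", report_id = report_id,
            page_num = as.integer(page_num), plan = plan, noise = noise)
}

# Render every page of a corpus (used when spec$render is TRUE).
render_corpus_pages <- function(corpus, noise_n = 0) {
  geom <- corpus$spec$page_geometry
  keys <- corpus$words %>% distinct(.data$report_id, .data$page_num)
  purrr::pmap(keys, function(report_id, page_num) {
    plan <- corpus$words %>%
      filter(.data$report_id == !!report_id, .data$page_num == !!page_num)
    render_page(plan, geom, noise_n = noise_n,
                report_id = report_id, page_num = page_num)
  })
}

#' @export
print.page_image <- function(x, ...) {
  d <- dim(x)
  cat("<page_image> ", d[1], "x", d[2],
      if (length(d) == 3) " x3 (color)" else " (gray)",
      ", report ", attr(x, "report_id"), " page ", attr(x, "page_num"),
      "\n", sep = "")
  invisible(x)
}

#' Write a page image to PNG
#'
#' @param img A `page_image`.
#' @param path Output file.
#' @export
write_page_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("the 'png' package is required to write PNG images")
  }
  x <- unclass(img) / 255
  png::writePNG(x, path)
  invisible(path)
}
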