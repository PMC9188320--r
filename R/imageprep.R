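# Image preprocessing: the six-method matrix applied to scanned pages
# before OCR. All operations keep pixel values in [0, 255] and the image
# dimensions unchanged.

#' The six canonical preprocessing methods
#'
#' Gray-scaling alone or combined with one iteration of dilate/erode and a
#' 20% or 60% contrast gain. `"gray_de_c20"` is the pipeline default.
#'
#' @return Character vector of method names.
#' @export
prep_methods <- function() {
  c("gray", "gray_de", "gray_c20", "gray_c60", "gray_de_c20", "gray_de_c60")
}

keep_img_attrs <- function(new, old) {
  attributes(new) <- c(attributes(new)[c("dim")],
                       attributes(old)[c("class", "report_id", "page_num",
                                         "plan", "noise")])
  new
}

#' Convert a color page image to gray-scale
#'
#' Standard luma weighting (0.299 R + 0.587 G + 0.114 B), rounded to
#' integer. A 1-channel input is returned unchanged.
#'
#' @param img A `page_image` (H x W gray matrix or H x W x 3 color array).
#' @return A gray `page_image` matrix.
#' @export
to_grayscale <- function(img) {
  if (is.matrix(img)) return(img)
  assert_that(length(dim(img)) == 3 && dim(img)[3] == 3,
              "expected an H x W x 3 color image")
  g <- round(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  keep_img_attrs(matrix(as.integer(g), dim(img)[1], dim(img)[2]), img)
}

# 3x3 max / min filters with edge-replicated borders (equivalent to
# clipping the structuring element at the page edge).
filter3 <- function(m, fun) {
  H <- nrow(m); W <- ncol(m)
  P <- matrix(0, H + 2, W + 2)
  P[2:(H + 1), 2:(W + 1)] <- m
  P[1, ] <- P[2, ]; P[H + 2, ] <- P[H + 1, ]
  P[, 1] <- P[, 2]; P[, W + 2] <- P[, W + 1]
  out <- P[2:(H + 1), 2:(W + 1)]
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      out <- fun(out, P[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)])
    }
  }
  out
}

#' One iteration of dilate then erode
#'
#' Grayscale dilation (3 x 3 square kernel, bright regions grow) followed
#' by one erosion. With dark text on a light background this is a
#' morphological opening with respect to the dark strokes: isolated dark
#' noise dots up to 2 px across are removed while strokes of 3 px and wider
#' are restored to their original extent.
#'
#' @param img A gray `page_image` matrix.
#' @return The filtered image, same dimensions.
#' @export
dilate_erode <- function(img) {
  assert_that(is.matrix(img), "dilate_erode expects a gray image matrix")
  out <- filter3(filter3(img, pmax), pmin)
  keep_img_attrs(matrix(as.integer(out), nrow(img), ncol(img)), img)
}

#' Multiplicative contrast gain
#'
#' Each pixel is mapped to `clip(round((1 + pct/100) * pixel), 0, 255)`.
#' On a light background the gain saturates near-white pixels to 255,
#' removing faint scanning noise. The canonical gains are 20% and 60%;
#' other values are accepted but flagged with a warning.
#'
#' @param img A gray `page_image` matrix.
#' @param pct Percent gain (canonical: 20 or 60).
#' @return The contrast-adjusted image.
#' @export
adjust_contrast <- function(img, pct = 20) {
  assert_that(is.matrix(img), "adjust_contrast expects a gray image matrix")
  if (!pct %in% c(20, 60)) {
    warn(paste0("contrast gain ", pct, "% is non-canonical (expected 20 or 60)"))
  }
  out <- pmin(pmax(round((1 + pct / 100) * img), 0), 255)
  keep_img_attrs(matrix(as.integer(out), nrow(img), ncol(img)), img)
}

#' Count 4-connected components of a binary mask
#'
#' Iterative label propagation (each pass spreads the maximum label to
#' 4-neighbours inside the mask until stable). Used to verify that
#' preprocessing preserves the connectivity of planted word strokes while
#' removing isolated noise.
#'
#' @param mask Logical matrix (`TRUE` = foreground).
#' @return Number of connected components.
#' @export
count_components <- function(mask) {
  if (!any(mask)) return(0L)
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0, H, W)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    up <- rbind(lab[-1, , drop = FALSE], 0)
    dn <- rbind(0, lab[-H, , drop = FALSE])
    lf <- cbind(lab[, -1, drop = FALSE], 0)
    rt <- cbind(0, lab[, -W, drop = FALSE])
    new <- pmax(lab, up, dn, lf, rt)
    new[!mask] <- 0
    if (identical(new, lab)) break
    lab <- new
  }
  length(unique(lab[mask]))
}

#' Apply one of the six preprocessing methods
#'
#' Stages compose in the order gray-scale, then dilate/erode (if selected),
#' then contrast gain (if selected).
#'
#' @param img A `page_image` (color or gray).
#' @param method One of [prep_methods()]; default `"gray_de_c20"`.
#' @return A gray `page_image`.
#' @export
apply_method <- function(img, method = "gray_de_c20") {
  method <- match.arg(tolower(method), prep_methods())
  out <- to_grayscale(img)
  if (grepl("_de", method)) out <- dilate_erode(out)
  if (grepl("_c20", method)) out <- adjust_contrast(out, 20)
  if (grepl("_c60", method)) out <- adjust_contrast(out, 60)
  out
}
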