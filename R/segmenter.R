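# Numeric-candidate segmentation: find candidate words, parse their
# values, build 21-word context windows, assign labels by gold-value
# matching, and produce document-level splits.

#' The numeric-candidate pattern
#'
#' A word is a candidate when its entire text matches `[0-9.,%]+`.
#' @return The anchored regular expression string.
#' @export
candidate_regex <- function() "^[0-9.,%]+$"

#' Canonical class labels
#' @return `c("AHI", "SaO2", "Other")`.
#' @export
class_labels <- function() c("AHI", "SaO2", "Other")

#' Parse a candidate token to its numeric value
#'
#' Percent signs are stripped, trailing periods/commas removed (sentence
#' punctuation attached to the word by OCR), and commas between digit
#' triplets treated as thousands separators. Tokens with no parseable
#' number return `NA` (signalling exclusion, not an error).
#'
#' @param token Candidate token string.
#' @return A double, or `NA_real_` if nothing parses.
#' @export
parse_numeric <- function(token) {
  s <- gsub("%", "", token, fixed = TRUE)
  s <- sub("[.,]+$", "", s)
  s <- gsub("(?<=\\d),(?=\\d{3}(?!\\d))", "", s, perl = TRUE)
  if (!grepl("^[0-9.]+$", s)) return(NA_real_)
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v) || !is.finite(v)) NA_real_ else v
}

#' Find numeric candidates among OCR words
#'
#' Returns every word whose entire text matches [candidate_regex()] and
#' parses to a finite number, in reading order.
#'
#' @param words OCR word tibble in reading order.
#' @return Tibble with `idx` (row index into `words`), `token`, `value`.
#' @export
find_candidates <- function(words) {
  hit <- which(grepl(candidate_regex(), words$text))
  vals <- vapply(words$text[hit], parse_numeric, 0.0, USE.NAMES = FALSE)
  ok <- !is.na(vals)
  tibble(idx = hit[ok], token = words$text[hit][ok], value = vals[ok])
}

#' Build the context window around a candidate
#'
#' Up to 10 words on each side of the candidate (21 words total),
#' concatenated across page boundaries in reading order and truncated only
#' at report boundaries.
#'
#' @param words OCR word tibble for one report, in reading order.
#' @param idx Row index of the candidate in `words`.
#' @return Character vector of window words (the candidate included).
#' @export
build_window <- function(words, idx) {
  assert_that(idx >= 1 && idx <= nrow(words), "candidate index out of range")
  words$text[max(1, idx - 10):min(nrow(words), idx + 10)]
}

#' Assign labels by gold-value matching
#'
#' A candidate whose value is within `tol` of the gold AHI is labelled
#' `"AHI"`; otherwise within `tol` of the gold SaO2, `"SaO2"`; otherwise
#' `"Other"`. When a value matches both gold values, AHI takes precedence
#' (documented tie-break).
#'
#' @param values Numeric candidate values.
#' @param gold One-row gold record with `ahi` and `sao2`.
#' @param tol Matching tolerance; default 0 (exact).
#' @return Character vector of labels.
#' @export
assign_labels <- function(values, gold, tol = 0) {
  out <- rep("Other", length(values))
  out[abs(values - gold$sao2) <= tol] <- "SaO2"
  out[abs(values - gold$ahi) <= tol] <- "AHI"
  out
}

#' Segment a corpus into labelled candidates
#'
#' Runs candidate detection, value parsing and window construction over
#' every report, and (when a gold table is supplied) assigns labels by
#' value matching.
#'
#' @param words OCR word tibble with `report_id`, in reading order within
#'   each report.
#' @param gold Optional gold tibble (`report_id`, `ahi`, `sao2`).
#' @param tol Label-matching tolerance.
#' @return Candidate tibble: `report_id`, `cand_idx` (0-based within
#'   report), `token`, `value`, `left`, `top`, `width`, `height`,
#'   `page_num`, `segment` (space-joined window), and `label` when gold is
#'   given. Mirrors the analytic layout columns Left/Top/Width/Height/
#'   Page/Numeric value/Segment/Label.
#' @export
segment_corpus <- function(words, gold = NULL, tol = 0) {
  ids <- unique(words$report_id)
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    w <- words[words$report_id == ids[k], , drop = FALSE]
    w <- w[order(w$order_idx), , drop = FALSE]
    cands <- find_candidates(w)
    if (nrow(cands) == 0) {
      out[[k]] <- NULL
      next
    }
    segs <- vapply(cands$idx, function(i) paste(build_window(w, i), collapse = " "),
                   character(1))
    tb <- tibble(report_id = ids[k],
                 cand_idx = seq_len(nrow(cands)) - 1L,
                 token = cands$token, value = cands$value,
                 left = w$left[cands$idx], top = w$top[cands$idx],
                 width = w$width[cands$idx], height = w$height[cands$idx],
                 page_num = w$page_num[cands$idx],
                 segment = segs)
    if (!is.null(gold)) {
      g <- gold[gold$report_id == ids[k], , drop = FALSE]
      assert_that(nrow(g) == 1, paste0("gold record missing for ", ids[k]))
      tb$label <- assign_labels(tb$value, g, tol)
    }
    out[[k]] <- tb
  }
  dplyr::bind_rows(out)
}

#' Split reports into development/test and train/validation sets
#'
#' Reports are shuffled with the given seed; the development set takes a
#' 70% share (rounded half-up) and the remainder is the test set. The
#' development set is further split 6:1 into training and validation
#' (validation = floor(dev / 7)). With 955 reports this reproduces the
#' canonical 669/286 and 574/95 sizes. Splitting is always at report
#' level, never at segment level.
#'
#' @param report_ids Character vector of unique report ids (>= 10).
#' @param seed Integer seed for the shuffle.
#' @return A list of class `split_plan` with `dev_ids`, `test_ids`,
#'   `train_ids`, `val_ids`, `seed`.
#' @export
split_documents <- function(report_ids, seed = 1L) {
  report_ids <- unique(report_ids)
  n <- length(report_ids)
  assert_that(n >= 10, "need at least 10 reports to split")
  n_dev <- round_half_up(0.7 * n)
  n_val <- floor(n_dev / 7)
  with_seed(seed, {
    shuffled <- sample(report_ids)
    dev <- shuffled[seq_len(n_dev)]
    test <- shuffled[(n_dev + 1):n]
    val <- dev[seq_len(n_val)]
    train <- dev[(n_val + 1):n_dev]
    structure(list(dev_ids = dev, test_ids = test, train_ids = train,
                   val_ids = val, seed = as.integer(seed)),
              class = "split_plan")
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan> dev ", length(x$dev_ids), " (train ", length(x$train_ids),
      " / val ", length(x$val_ids), "), test ", length(x$test_ids),
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Subsample the training set at fixed sizes
#'
#' Draws one independent seeded sample without replacement per requested
#' size, for training-set-size effect studies.
#'
#' @param train_ids Training report ids.
#' @param sizes Subset sizes (default 10, 25, 50, 100).
#' @param seed Integer seed.
#' @return Named list of id vectors, one per size.
#' @export
subsample_training <- function(train_ids, sizes = c(10, 25, 50, 100),
                               seed = 1L) {
  assert_that(all(sizes >= 1) && all(sizes <= length(train_ids)),
              "subset sizes must be between 1 and the training set size")
  out <- lapply(seq_along(sizes), function(i) {
    with_seed(child_seed(seed, paste0("subsample", sizes[i])), {
      sample(train_ids, sizes[i])
    })
  })
  setNames(out, as.character(sizes))
}
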