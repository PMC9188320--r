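# Bag-of-words featurization: top-400 tf-idf vocabulary over context
# windows plus the six structured layout features.

tokenize_segment <- function(s) {
  strsplit(tolower(s), "\\s+")[[1]]
}

#' Build the tf-idf vocabulary from training windows
#'
#' Lowercases, drops English stopwords (vendored list), ranks terms by raw
#' corpus term frequency, keeps the top `max_terms` (ties broken
#' lexicographically), and computes smoothed inverse document frequency
#' `ln((1 + n) / (1 + df)) + 1` over the training windows.
#'
#' @param segments Character vector of training context windows
#'   (space-joined).
#' @param max_terms Vocabulary cap (default 400).
#' @return Object of class `bow_vocab`: list with `terms`, `idf`,
#'   `stopword_list_id`, `n_docs`.
#' @export
build_vocab <- function(segments, max_terms = 400) {
  assert_that(length(segments) > 0, "cannot build a vocabulary from an empty corpus")
  sw <- english_stopwords()
  toks <- lapply(segments, tokenize_segment)
  all_tok <- unlist(toks)
  all_tok <- all_tok[!all_tok %in% sw & nzchar(all_tok)]
  tf <- table(all_tok)
  ord <- order(-as.integer(tf), names(tf))
  terms <- names(tf)[ord][seq_len(min(max_terms, length(tf)))]
  n <- length(segments)
  df <- vapply(terms, function(t) {
    sum(vapply(toks, function(x) t %in% x, TRUE))
  }, 0)
  idf <- log((1 + n) / (1 + df)) + 1
  structure(list(terms = terms, idf = unname(idf),
                 stopword_list_id = "vendored-english-v1", n_docs = n),
            class = "bow_vocab")
}

#' @export
print.bow_vocab <- function(x, ...) {
  cat("<bow_vocab> ", length(x$terms), " terms from ", x$n_docs,
      " training windows\n", sep = "")
  invisible(x)
}

#' Featurize candidates for the bag-of-words classifiers
#'
#' Builds the feature matrix: six structured columns (the four bounding-box
#' position indicators, the page number, and the parsed numeric value)
#' followed by the L2-normalized tf-idf block over the vocabulary terms in
#' each candidate's context window.
#'
#' @param candidates Candidate tibble from [segment_corpus()].
#' @param vocab A [build_vocab()] result.
#' @return Numeric matrix with `6 + length(vocab$terms)` columns.
#' @export
featurize <- function(candidates, vocab) {
  n <- nrow(candidates)
  V <- length(vocab$terms)
  toks <- lapply(candidates$segment, tokenize_segment)
  ii <- rep.int(seq_len(n), lengths(toks))
  jj <- match(unlist(toks), vocab$terms)
  keep <- !is.na(jj)
  tf <- matrix(0, n, V)
  if (any(keep)) {
    tf <- matrix(as.numeric(tabulate((jj[keep] - 1L) * n + ii[keep],
                                     nbins = n * V)), n, V)
  }
  tfidf <- sweep(tf, 2, vocab$idf, `*`)
  nrm <- sqrt(rowSums(tfidf^2))
  nrm[nrm == 0] <- 1
  tfidf <- tfidf / nrm
  x <- cbind(left = candidates$left, top = candidates$top,
             width = candidates$width, height = candidates$height,
             page = candidates$page_num, value = candidates$value,
             tfidf)
  colnames(x) <- c("left", "top", "width", "height", "page", "value",
                   paste0("t_", vocab$terms))
  x
}

n_structured_features <- function() 6L
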