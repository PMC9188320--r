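# Segment- and document-level evaluation: one-vs-rest AUROC with DeLong
# variance/CI/test, document-level argmax extraction and accuracy,
# chi-squared accuracy comparison, and Bonferroni adjustment.

#' Segment-level recall, precision and F1 for one class
#'
#' One-vs-rest counts against the predicted labels. Precision with zero
#' predicted positives is reported as 0 with a warning.
#'
#' @param pred,truth Aligned label vectors.
#' @param class The positive class.
#' @return Named numeric vector `recall`, `precision`, `f1`.
#' @export
segment_metrics <- function(pred, truth, class) {
  assert_that(length(pred) == length(truth),
              "pred and truth must have the same length")
  tp <- sum(pred == class & truth == class)
  fp <- sum(pred == class & truth != class)
  fn <- sum(pred != class & truth == class)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (tp + fp == 0) {
    warn(paste0("no predicted positives for class '", class,
                "'; precision reported as 0"))
    precision <- 0
  } else {
    precision <- tp / (tp + fp)
  }
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(recall = recall, precision = precision, f1 = f1)
}

#' Area under the ROC curve
#'
#' The Mann-Whitney concordance probability with ties counted one half,
#' computed by the rank formula.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param truth Binary truth (logical or 0/1).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, truth) {
  truth <- as.logical(truth)
  m <- sum(truth); n <- sum(!truth)
  assert_that(m > 0 && n > 0, "AUROC needs both classes present")
  r <- rank(scores)
  (sum(r[truth]) - m * (m + 1) / 2) / (m * n)
}

# Placement values: V10[i] = P(score of positive i exceeds a random
# negative), ties counted 1/2; V01 analogous for negatives.
placement_values <- function(scores, truth) {
  x <- scores[truth]; y <- scores[!truth]
  v10 <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / length(y), 0)
  v01 <- vapply(y, function(yj) (sum(yj < x) + 0.5 * sum(yj == x)) / length(x), 0)
  list(v10 = v10, v01 = v01)
}

#' DeLong comparison of two correlated AUROCs
#'
#' The placement-value covariance estimator on paired scores, giving each
#' model's AUROC with a 95% CI (auc +/- 1.96 SE) and a two-sided z-test of
#' the difference. With degenerate variance (for example perfect
#' separation by both models) the CI collapses and p is reported as 1 with
#' a warning.
#'
#' @param scores_a,scores_b Paired score vectors on identical instances.
#' @param truth Binary truth.
#' @return List with `auc_a`, `auc_b`, `ci_a`, `ci_b`, `se_a`, `se_b`,
#'   `se_diff`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, truth) {
  truth <- as.logical(truth)
  assert_that(length(scores_a) == length(scores_b) &&
                length(scores_a) == length(truth),
              "DeLong needs paired scores on identical instances")
  m <- sum(truth); n <- sum(!truth)
  assert_that(m > 0 && n > 0, "DeLong needs both classes present")
  pa <- placement_values(scores_a, truth)
  pb <- placement_values(scores_b, truth)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  se_a <- sqrt(S[1, 1]); se_b <- sqrt(S[2, 2])
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (!is.finite(var_diff) || var_diff < 1e-16) {
    warn("degenerate DeLong variance; p reported as 1")
    z <- 0; p <- 1
  } else {
    z <- (auc_a - auc_b) / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  list(auc_a = auc_a, auc_b = auc_b,
       ci_a = pmin(pmax(auc_a + c(-1, 1) * stats::qnorm(0.975) * se_a, 0), 1),
       ci_b = pmin(pmax(auc_b + c(-1, 1) * stats::qnorm(0.975) * se_b, 0), 1),
       se_a = se_a, se_b = se_b,
       se_diff = sqrt(max(var_diff, 0)), z = z, p = p)
}

# single-model DeLong standard error and CI
auroc_ci <- function(scores, truth) {
  truth <- as.logical(truth)
  p <- placement_values(scores, truth)
  a <- mean(p$v10)
  se <- sqrt(stats::var(p$v10) / sum(truth) + stats::var(p$v01) / sum(!truth))
  list(auc = a, se = se, ci = pmin(pmax(a + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1))
}

#' Document-level value extraction
#'
#' For each document, the candidate with the highest score for the class
#' is selected (ties resolved by earliest reading order); the document is
#' correctly extracted when the chosen value is within `tol` of the gold
#' value. Documents with no candidates count as incorrect with the
#' denominator unchanged.
#'
#' @param cands Candidate tibble (reading order within report).
#' @param scores Score matrix from [predict_scores()] aligned with
#'   `cands`.
#' @param class `"AHI"` or `"SaO2"`.
#' @param gold Gold tibble (`report_id`, `ahi`, `sao2`).
#' @param report_ids Documents to evaluate (default: all in `gold`);
#'   reports absent from `cands` count as extraction failures.
#' @param tol Value-match tolerance (default 0).
#' @return Tibble `report_id`, `chosen_value`, `gold_value`, `correct`.
#' @export
extract_document <- function(cands, scores, class, gold,
                             report_ids = gold$report_id, tol = 0) {
  gcol <- if (class == "AHI") "ahi" else "sao2"
  sc <- scores[, class]
  out <- vector("list", length(report_ids))
  for (k in seq_along(report_ids)) {
    rid <- report_ids[k]
    rows <- which(cands$report_id == rid)
    gv <- gold[[gcol]][gold$report_id == rid]
    if (length(rows) == 0) {
      out[[k]] <- tibble(report_id = rid, chosen_value = NA_real_,
                         gold_value = gv, correct = FALSE)
      next
    }
    rows <- rows[order(cands$cand_idx[rows])]
    best <- rows[which.max(sc[rows])]  # first maximum = earliest in order
    out[[k]] <- tibble(report_id = rid, chosen_value = cands$value[best],
                       gold_value = gv,
                       correct = abs(cands$value[best] - gv) <= tol)
  }
  dplyr::bind_rows(out)
}

#' Document accuracy with confidence interval
#'
#' Accuracy = correctly extracted documents / documents evaluated. The
#' 95% CI is the Wald normal approximation by default; `method =
#' "wilson"` selects the Wilson score interval.
#'
#' @param correct Logical flags, one per document.
#' @param method `"wald"` or `"wilson"`.
#' @return List `accuracy`, `ci`, `n`.
#' @export
document_accuracy <- function(correct, method = c("wald", "wilson")) {
  method <- match.arg(method)
  n <- length(correct)
  p <- mean(correct)
  if (method == "wald") {
    half <- 1.96 * sqrt(p * (1 - p) / n)
    ci <- c(p - half, p + half)
  } else {
    z <- 1.96
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    ci <- c(ctr - half, ctr + half)
  }
  list(accuracy = p, ci = pmin(pmax(ci, 0), 1), n = n)
}

#' Chi-squared comparison of two document accuracies
#'
#' Pearson chi-squared without continuity correction on the 2 x 2
#' correct/incorrect-by-model table. A zero-margin table returns p = 1
#' with a warning. (Documents are paired across models; a McNemar variant
#' is available via `method = "mcnemar"` given paired flags.)
#'
#' @param acc_a,acc_b Lists or vectors `c(correct, n)` of correct counts
#'   and totals.
#' @return List `statistic`, `p`.
#' @export
chi2_compare <- function(acc_a, acc_b) {
  tab <- rbind(c(acc_a[[1]], acc_a[[2]] - acc_a[[1]]),
               c(acc_b[[1]], acc_b[[2]] - acc_b[[1]]))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("zero-margin table in chi-squared comparison; p reported as 1")
    return(list(statistic = 0, p = 1))
  }
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' McNemar comparison of paired document-extraction flags
#'
#' @param correct_a,correct_b Paired logical flags on the same documents.
#' @return List `statistic`, `p`.
#' @export
mcnemar_compare <- function(correct_a, correct_b) {
  b <- sum(correct_a & !correct_b)
  c <- sum(!correct_a & correct_b)
  if (b + c == 0) return(list(statistic = 0, p = 1))
  stat <- (b - c)^2 / (b + c)
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Bonferroni family-wise adjustment
#'
#' Each p-value is multiplied by the explicit family size `m` and capped
#' at 1. `m` must be at least the number of comparisons; it is never
#' inferred silently.
#'
#' @param ps Raw p-values.
#' @param m Family size.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(ps, m) {
  assert_that(m >= length(ps), "family size m must cover all comparisons")
  pmin(1, m * ps)
}

#' Full evaluation report for one model's scores
#'
#' Segment-level recall/precision/F1 and one-vs-rest AUROC with DeLong
#' 95% CI for each target class, plus document-level extraction accuracy
#' with its CI.
#'
#' @param cands Labelled candidate tibble for the evaluation documents.
#' @param scores Score matrix aligned with `cands`.
#' @param gold Gold tibble.
#' @param report_ids Documents to evaluate (default: those in `cands`).
#' @param tol Document value-match tolerance.
#' @return Tibble, one row per class in `c("AHI", "SaO2")`.
#' @export
eval_report <- function(cands, scores, gold,
                        report_ids = unique(cands$report_id), tol = 0) {
  pred <- colnames(scores)[max.col(scores, ties.method = "first")]
  rows <- lapply(c("AHI", "SaO2"), function(cl) {
    sm <- segment_metrics(pred, cands$label, cl)
    ac <- auroc_ci(scores[, cl], cands$label == cl)
    doc <- extract_document(cands, scores, cl, gold, report_ids, tol)
    da <- document_accuracy(doc$correct)
    tibble(class = cl,
           recall = unname(sm["recall"]), precision = unname(sm["precision"]),
           f1 = unname(sm["f1"]),
           auroc = ac$auc, auroc_lo = ac$ci[1], auroc_hi = ac$ci[2],
           doc_accuracy = da$accuracy, doc_lo = da$ci[1], doc_hi = da$ci[2],
           n_segments = nrow(cands), n_documents = da$n)
  })
  dplyr::bind_rows(rows)
}
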