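test_that("segment metrics match hand counts and a brute-force confusion tally", {
  expect_equal(unname(segment_metrics(c("AHI", "SaO2"), c("AHI", "SaO2"), "AHI")),
               c(1, 1, 1))
  pred <- c("AHI", "AHI", "Other")
  truth <- c("AHI", "Other", "AHI")  # TP=1 FP=1 FN=1
  expect_equal(unname(segment_metrics(pred, truth, "AHI")), c(0.5, 0.5, 0.5))
  expect_error(segment_metrics("AHI", c("AHI", "AHI"), "AHI"), "length")
  expect_warning(segment_metrics(rep("Other", 3), c("AHI", "Other", "Other"),
                                 "AHI"), "precision")
  # random 50-item fixture vs independent confusion-matrix computation
  withr::with_seed(8, {
    pred <- sample(class_labels(), 50, TRUE)
    truth <- sample(class_labels(), 50, TRUE)
  })
  for (cl in c("AHI", "SaO2")) {
    m <- segment_metrics(pred, truth, cl)
    cm <- table(factor(pred == cl, c(FALSE, TRUE)),
                factor(truth == cl, c(FALSE, TRUE)))
    r <- cm[2, 2] / sum(cm[, 2])
    p <- cm[2, 2] / sum(cm[2, ])
    expect_equal(unname(m["f1"]), 2 * p * r / (p + r))
  }
})

test_that("AUROC equals the pairwise concordance probability", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)  # all ties
  expect_equal(auroc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
  # brute-force oracle over random fixtures
  brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  withr::with_seed(21, {
    for (i in 1:20) {
      n <- sample(10:120, 1)
      y <- rbinom(n, 1, 0.4)
      if (length(unique(y)) < 2) next
      s <- round(rnorm(n, y), sample(c(1, 2), 1))  # rounding induces ties
      expect_equal(auroc(s, y), brute(s, y))
    }
  })
})

test_that("DeLong handles identical models, nests the point estimate, and matches pROC", {
  withr::with_seed(31, {
    y <- rbinom(80, 1, 0.5)
    a <- rnorm(80, y)
    b <- 0.5 * a + rnorm(80, 0.5 * y)
  })
  same <- suppressWarnings(delong_test(a, a, y))
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  dl <- delong_test(a, b, y)
  expect_true(dl$ci_a[1] <= dl$auc_a && dl$auc_a <= dl$ci_a[2])
  expect_true(dl$ci_b[1] <= dl$auc_b && dl$auc_b <= dl$ci_b[2])
  expect_equal(dl$auc_a, auroc(a, y))
  skip_if_not_installed("pROC")
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                        pROC::roc(y, b, quiet = TRUE), method = "delong")
  expect_equal(dl$p, ref$p.value, tolerance = 1e-9)
  ci_ref <- pROC::ci.auc(pROC::roc(y, a, quiet = TRUE), method = "delong")
  expect_equal(dl$ci_a, as.numeric(ci_ref[c(1, 3)]), tolerance = 1e-9)
  # degenerate variance: both models separate perfectly
  ysep <- rep(c(0, 1), each = 5)
  ssep <- rep(c(0, 1), each = 5)
  expect_warning(out <- delong_test(ssep, ssep + 0, ysep), "degenerate")
  expect_equal(out$p, 1)
})

test_that("document extraction takes the argmax with earliest-order ties", {
  cands <- tibble::tibble(report_id = rep(c("R1", "R2"), each = 2),
                          cand_idx = c(0L, 1L, 0L, 1L),
                          value = c(10, 20, 30, 40))
  gold <- tibble::tibble(report_id = c("R1", "R2", "R3"),
                         ahi = c(20, 30, 5), sao2 = c(90, 91, 92))
  scores <- cbind(AHI = c(0.1, 0.9, 0.7, 0.7), SaO2 = 0, Other = 0)
  out <- extract_document(cands, scores, "AHI", gold)
  expect_equal(out$chosen_value, c(20, 30, NA))  # tie in R2 -> earliest
  expect_equal(out$correct, c(TRUE, TRUE, FALSE))  # R3 has no candidates
  # oracle scoring (indicator of truth) extracts correctly
  oracle <- cbind(AHI = as.numeric(cands$value %in% c(20, 30)), SaO2 = 0,
                  Other = 0)
  out2 <- extract_document(cands, oracle, "AHI", gold,
                           report_ids = c("R1", "R2"))
  expect_true(all(out2$correct))
  # invariant to candidate ordering when scores are distinct
  perm <- c(2, 1, 4, 3)
  out3 <- extract_document(cands[perm, ], scores[perm, , drop = FALSE],
                           "AHI", gold, report_ids = c("R1", "R2"))
  expect_equal(out3$chosen_value, c(20, 30))
})

test_that("document accuracy is the mean flag with a shrinking Wald interval", {
  expect_equal(document_accuracy(c(TRUE, TRUE, FALSE, FALSE))$accuracy, 0.5)
  expect_equal(document_accuracy(rep(TRUE, 4))$accuracy, 1)
  da <- document_accuracy(rep(c(TRUE, FALSE), 50))
  expect_equal(unname(diff(da$ci)), 2 * 1.96 * sqrt(0.25 / 100))
  da4 <- document_accuracy(rep(c(TRUE, FALSE), 200))
  expect_equal(unname(diff(da$ci) / diff(da4$ci)), 2)  # width ~ 1/sqrt(n)
  w <- document_accuracy(rep(c(TRUE, FALSE), 50), method = "wilson")
  expect_true(w$ci[1] > 0 && w$ci[2] < 1)
  expect_true(w$ci[1] <= 0.5 && 0.5 <= w$ci[2])
})

test_that("chi-squared comparison is Pearson without continuity correction", {
  same <- chi2_compare(c(50, 100), c(50, 100))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  out <- chi2_compare(c(90, 100), c(70, 100))
  # hand Pearson sum over the 2x2 table [[90,10],[70,30]]
  expect_equal(out$statistic, 12.5)
  expect_equal(out$p, stats::pchisq(12.5, 1, lower.tail = FALSE))
  # symmetric in model order
  expect_equal(chi2_compare(c(70, 100), c(90, 100))$statistic, out$statistic)
  expect_warning(zero <- chi2_compare(c(0, 10), c(0, 10)), "zero-margin")
  expect_equal(zero$p, 1)
})

test_that("Bonferroni multiplies by the explicit family size and caps at 1", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.4, 6), 1)
  expect_equal(bonferroni(c(0.2, 0.5), 2), c(0.4, 1))
  expect_equal(bonferroni(0.3, 1), 0.3)
  expect_error(bonferroni(c(0.1, 0.2), 1), "family size")
})

test_that("McNemar comparison uses the discordant pairs", {
  a <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  b <- c(TRUE, FALSE, FALSE, TRUE, FALSE)
  out <- mcnemar_compare(a, b)
  expect_equal(out$statistic, (2 - 1)^2 / 3)
  expect_equal(mcnemar_compare(a, a)$p, 1)
})

test_that("evaluation reports carry coherent metrics for both classes", {
  corp <- fixture_corpus()
  cands <- fixture_candidates(corp)
  # oracle scores from the labels give a perfect report
  scores <- cbind(AHI = as.numeric(cands$label == "AHI"),
                  SaO2 = as.numeric(cands$label == "SaO2"),
                  Other = as.numeric(cands$label == "Other"))
  er <- eval_report(cands, scores, corp$gold)
  expect_equal(er$class, c("AHI", "SaO2"))
  expect_equal(er$recall, c(1, 1))
  expect_equal(er$f1, c(1, 1))
  expect_equal(er$doc_accuracy, c(1, 1))
  expect_true(all(er$auroc_lo <= er$auroc & er$auroc <= er$auroc_hi))
})
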