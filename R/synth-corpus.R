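#' Specify a synthetic sleep-report corpus
#'
#' Builds the configuration object for [generate_corpus()]. The defaults
#' emulate the published summary statistics of a real scanned sleep-study
#' corpus: a median of 2 pages per report (support 1-6), a median of 44
#' numeric values per page, apnea-hypopnea index (AHI) values with mean 34.9
#' and SD 31.3 (truncated at 0), minimum oxygen saturation (SaO2) values
#' with mean 76.5 and SD 15.6 (truncated to (0, 100]), and multiple-mention
#' probabilities of 0.528 (AHI) and 0.459 (SaO2).
#'
#' `ahi_dist` / `sao2_dist` give the *target* mean and SD of the truncated
#' value distribution; the parent normal parameters are solved by moment
#' matching at construction time so the generated values actually realise
#' the requested moments.
#'
#' @param n_reports Number of reports to generate.
#' @param seed Integer seed; identical spec + seed gives a bit-identical
#'   corpus.
#' @param pages_per_report List with `values` (page counts) and `prob`.
#' @param numerics_per_page List with `mean`, `sd`, `min`, `max`; page
#'   numeric counts are rounded truncated normals.
#' @param ahi_dist,sao2_dist Lists with `mean`, `sd`, `lower`, `upper`.
#' @param p_multi_ahi,p_multi_sao2 Probability that a report carries more
#'   than one mention of the gold value.
#' @param suppress_collisions If `TRUE` (default), distractor values that
#'   collide with either gold value are resampled, so label assignment by
#'   value matching is exact.
#' @param ambiguous_text If `TRUE`, gold sentences and decoy distractors use
#'   the identical sentence template and the gold value is always planted at
#'   the top of page 1, so only layout features can separate the classes.
#'   Used for structured-input ablation studies.
#' @param render If `TRUE`, [generate_corpus()] also rasterises each page
#'   (see [render_page()]).
#' @param page_geometry List of pixel geometry: `width`, `height` (default
#'   2550 x 3300, a 300-dpi US-Letter scan), `margin`, `char_w`, `word_h`,
#'   `line_h`, `space_w`.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_reports = 100,
                        seed = 1L,
                        pages_per_report = list(values = 1:6,
                                                prob = c(.20, .35, .15, .15, .10, .05)),
                        numerics_per_page = list(mean = 44, sd = 9, min = 5, max = 90),
                        ahi_dist = list(mean = 34.9, sd = 31.3, lower = 0, upper = Inf),
                        sao2_dist = list(mean = 76.5, sd = 15.6, lower = 0, upper = 100),
                        p_multi_ahi = 0.528,
                        p_multi_sao2 = 0.459,
                        suppress_collisions = TRUE,
                        ambiguous_text = FALSE,
                        render = FALSE,
                        page_geometry = NULL) {
  assert_that(is_count(n_reports), "n_reports must be a positive integer")
  assert_that(is_prob(p_multi_ahi), "p_multi_ahi must be in [0, 1]")
  assert_that(is_prob(p_multi_sao2), "p_multi_sao2 must be in [0, 1]")
  assert_that(length(pages_per_report$values) == length(pages_per_report$prob) &&
                all(pages_per_report$prob >= 0) && sum(pages_per_report$prob) > 0,
              "pages_per_report must give matching values and non-negative prob")
  assert_that(all(pages_per_report$values >= 1),
              "pages_per_report values must be >= 1")
  for (d in list(ahi_dist, sao2_dist)) {
    assert_that(is.numeric(d$mean) && is.numeric(d$sd) && d$sd > 0,
                "value distributions need numeric mean and positive sd")
  }
  assert_that(ahi_dist$lower >= 0, "AHI support must be non-negative")
  assert_that(sao2_dist$lower >= 0 && sao2_dist$upper <= 100,
              "SaO2 support must lie in (0, 100]")
  assert_that(numerics_per_page$min >= 1 &&
                numerics_per_page$max >= numerics_per_page$min,
              "numerics_per_page min/max invalid")

  geom <- page_geometry %||% list(width = 2550, height = 3300, margin = 150,
                                  char_w = 22, word_h = 50, line_h = 70,
                                  space_w = 14)

  spec <- list(
    n_reports = as.integer(n_reports),
    seed = as.integer(seed),
    pages_per_report = pages_per_report,
    numerics_per_page = numerics_per_page,
    ahi_dist = c(ahi_dist, list(parent = match_truncnorm_moments(
      ahi_dist$mean, ahi_dist$sd, ahi_dist$lower, ahi_dist$upper))),
    sao2_dist = c(sao2_dist, list(parent = match_truncnorm_moments(
      sao2_dist$mean, sao2_dist$sd, sao2_dist$lower, sao2_dist$upper))),
    p_multi_ahi = p_multi_ahi,
    p_multi_sao2 = p_multi_sao2,
    suppress_collisions = isTRUE(suppress_collisions),
    ambiguous_text = isTRUE(ambiguous_text),
    render = isTRUE(render),
    page_geometry = geom
  )
  structure(spec, class = "corpus_spec")
}

# Solve for parent normal (mu, sigma) whose [lower, upper]-truncation has the
# requested mean and sd. Needed because truncating N(34.9, 31.3^2) at zero
# would inflate the mean to ~42.7.
match_truncnorm_moments <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (is.infinite(lower) && is.infinite(upper)) {
    return(list(mu = mean, sigma = sd))
  }
  obj <- function(p) {
    mu <- p[1]; s <- exp(p[2])
    a <- (lower - mu) / s; b <- (upper - mu) / s
    z <- pnorm(b) - pnorm(a)
    if (z < 1e-12) return(1e6)
    da <- if (is.finite(a)) dnorm(a) else 0
    db <- if (is.finite(b)) dnorm(b) else 0
    aa <- if (is.finite(a)) a * da else 0
    bb <- if (is.finite(b)) b * db else 0
    m <- mu + s * (da - db) / z
    v <- s^2 * (1 + (aa - bb) / z - ((da - db) / z)^2)
    if (v <= 0) return(1e6)
    (m - mean)^2 + (sqrt(v) - sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj,
               control = list(reltol = 1e-14, maxit = 10000))
  if (fit$value > 1e-4) {
    abort("cannot match the requested truncated-normal moments; check mean/sd/support")
  }
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Exact inverse-CDF sampler for the truncated normal (no rejection).
rtruncnorm <- function(n, mu, sigma, lower = -Inf, upper = Inf) {
  pa <- pnorm(lower, mu, sigma)
  pb <- pnorm(upper, mu, sigma)
  qnorm(pa + runif(n) * (pb - pa), mu, sigma)
}

sample_pool_value <- function(pool) {
  switch(pool,
         count    = sample(0:300, 1),
         rate     = round(runif(1, 0, 60), 1),
         percent  = sample(50:99, 1),
         duration = sample(30:480, 1),
         abort(paste0("unknown distractor pool '", pool, "'")))
}

format_pool_value <- function(v, pool) {
  if (pool == "rate") sprintf("%.1f", v) else sprintf("%d", v)
}

# Instantiate one template: returns list(tokens, roles, values).
# gold_value / gold_fmt fill "{V}" slots; "{D:pool}" slots draw distractors,
# resampled away from the gold values when collisions are suppressed.
fill_template <- function(tpl, gold_role = NULL, gold_value = NA_real_,
                          gold_fmt = NULL, avoid = numeric(0),
                          suppress = TRUE) {
  tokens <- character(length(tpl))
  roles <- rep("prose", length(tpl))
  values <- rep(NA_real_, length(tpl))
  for (i in seq_along(tpl)) {
    tok <- tpl[[i]]
    m <- regmatches(tok, regexec("^\\{(V|D:([a-z]+))\\}(.*)$", tok))[[1]]
    if (length(m) == 0) {
      tokens[i] <- tok
      next
    }
    suffix <- m[4]
    if (m[2] == "V") {
      tokens[i] <- paste0(gold_fmt, suffix)
      roles[i] <- gold_role
      values[i] <- gold_value
    } else {
      pool <- m[3]
      v <- sample_pool_value(pool)
      if (suppress && length(avoid)) {
        tries <- 0
        while (any(abs(v - avoid) < 1e-9) && tries < 200) {
          v <- sample_pool_value(pool)
          tries <- tries + 1
        }
      }
      tokens[i] <- paste0(format_pool_value(v, pool), suffix)
      roles[i] <- "distractor"
      values[i] <- v
    }
  }
  list(tokens = tokens, roles = roles, values = values)
}

# Greedy left-to-right, top-to-bottom layout of a page's tokens.
# Returns left/top/width/height per token; tokens that would run past the
# bottom margin are dropped (the caller plants gold sentences early).
layout_page <- function(tokens, geom) {
  n <- length(tokens)
  left <- integer(n); top <- integer(n); keep <- logical(n)
  x <- geom$margin; y <- geom$margin
  widths <- nchar(tokens) * geom$char_w
  max_x <- geom$width - geom$margin
  max_y <- geom$height - geom$margin - geom$word_h
  for (i in seq_len(n)) {
    if (x + widths[i] > max_x) {
      x <- geom$margin
      y <- y + geom$line_h
    }
    if (y > max_y) break
    left[i] <- x; top[i] <- y; keep[i] <- TRUE
    x <- x + widths[i] + geom$space_w
  }
  list(left = left, top = top, width = widths,
       height = rep(geom$word_h, n), keep = keep)
}

#' Generate a synthetic scanned-report corpus with known ground truth
#'
#' Produces multi-page sleep-study-like reports as OCR word tables (and
#' optionally rendered page images), together with a gold table of the true
#' AHI and SaO2 value per report and a PHI lookup table for
#' deidentification. Every report plants its gold values verbatim in at
#' least one word whose parsed value equals the recorded gold value.
#'
#' @param spec A [corpus_spec()].
#' @return A list of class `sleepscan_corpus` with elements
#'   * `words`: tibble of planted OCR words (`report_id`, `page_num`,
#'     `order_idx`, `text`, `role`, `left`, `top`, `width`, `height`,
#'     `conf`),
#'   * `gold`: tibble (`report_id`, `ahi`, `sao2`, `n_ahi_mentions`,
#'     `n_sao2_mentions`),
#'   * `phi`: tibble (`report_id`, `name`, `mrn`),
#'   * `pages`: list of rendered [render_page()] images if `spec$render`,
#'     else `NULL`,
#'   * `spec`: the spec used.
#' @export
generate_corpus <- function(spec) {
  assert_that(inherits(spec, "corpus_spec"), "spec must be a corpus_spec")
  geom <- spec$page_geometry
  with_seed(spec$seed, {
    word_rows <- vector("list", spec$n_reports)
    gold_rows <- vector("list", spec$n_reports)
    phi_rows <- vector("list", spec$n_reports)

    for (r in seq_len(spec$n_reports)) {
      rid <- sprintf("R%04d", r)
      n_pages <- sample(spec$pages_per_report$values, 1,
                        prob = spec$pages_per_report$prob)
      ahi <- round(rtruncnorm(1, spec$ahi_dist$parent$mu,
                              spec$ahi_dist$parent$sigma,
                              spec$ahi_dist$lower, spec$ahi_dist$upper), 1)
      sao2 <- round(rtruncnorm(1, spec$sao2_dist$parent$mu,
                               spec$sao2_dist$parent$sigma,
                               max(spec$sao2_dist$lower, 1),
                               spec$sao2_dist$upper))
      if (spec$suppress_collisions) {
        # keep the two gold values distinct so value-match labelling is
        # exact (the AHI-precedence tie-break never has to fire)
        tries <- 0
        while (sao2 == ahi && tries < 100) {
          sao2 <- round(rtruncnorm(1, spec$sao2_dist$parent$mu,
                                   spec$sao2_dist$parent$sigma,
                                   max(spec$sao2_dist$lower, 1),
                                   spec$sao2_dist$upper))
          tries <- tries + 1
        }
      }
      ahi_fmt <- sprintf("%.1f", ahi)
      sao2_fmt <- sprintf("%d", as.integer(sao2))
      gold_vals <- c(ahi, sao2)

      n_ahi <- 1L + if (runif(1) < spec$p_multi_ahi) sample(1:2, 1, prob = c(.8, .2)) else 0L
      n_sao2 <- 1L + if (runif(1) < spec$p_multi_sao2) sample(1:2, 1, prob = c(.8, .2)) else 0L

      npp <- pmin(pmax(round(rnorm(n_pages, spec$numerics_per_page$mean,
                                   spec$numerics_per_page$sd)),
                       spec$numerics_per_page$min),
                  spec$numerics_per_page$max)

      # allocate gold mentions: first AHI and SaO2 mention on page 1, extras
      # on random pages
      gold_page <- list(ahi = c(1L, if (n_ahi > 1) sample(n_pages, n_ahi - 1L, replace = TRUE)),
                        sao2 = c(1L, if (n_sao2 > 1) sample(n_pages, n_sao2 - 1L, replace = TRUE)))

      dtpl <- distractor_templates()
      dtpl_single <- dtpl[vapply(dtpl, function(t) sum(grepl("^\\{D", t)) == 1L,
                                 TRUE)]
      ptpl <- prose_templates()
      atpl <- ahi_templates()
      stpl <- sao2_templates()

      page_tokens <- vector("list", n_pages)
      page_roles <- vector("list", n_pages)
      for (pg in seq_len(n_pages)) {
        sentences <- list()
        n_num <- 0L
        gold_here <- list()
        for (k in seq_len(sum(gold_page$ahi == pg))) {
          tpl <- if (spec$ambiguous_text) ambiguous_template("ahi") else atpl[[sample(length(atpl), 1)]]
          gold_here <- c(gold_here, list(fill_template(
            tpl, "AHI", ahi, ahi_fmt, avoid = gold_vals,
            suppress = spec$suppress_collisions)))
        }
        for (k in seq_len(sum(gold_page$sao2 == pg))) {
          tpl <- if (spec$ambiguous_text) ambiguous_template("sao2") else stpl[[sample(length(stpl), 1)]]
          gold_here <- c(gold_here, list(fill_template(
            tpl, "SaO2", sao2, sao2_fmt, avoid = gold_vals,
            suppress = spec$suppress_collisions)))
        }
        n_num <- n_num + sum(vapply(gold_here, function(s) sum(s$roles != "prose"), 0L))

        filler <- list()
        while (n_num < npp[pg]) {
          if (runif(1) < 0.25) {
            s <- list(tokens = ptpl[[sample(length(ptpl), 1)]],
                      roles = NULL, values = NULL)
            s$roles <- rep("prose", length(s$tokens))
          } else if (spec$ambiguous_text) {
            # every numeric filler is a decoy with the identical sentence
            # shape as the gold, so word context carries no class signal
            which_c <- sample(c("ahi", "sao2"), 1)
            pool <- if (which_c == "ahi") "rate" else "percent"
            tpl <- ambiguous_template(which_c)
            tpl[tpl == "{V}"] <- paste0("{D:", pool, "}")
            s <- fill_template(tpl, avoid = gold_vals,
                               suppress = spec$suppress_collisions)
          } else {
            # when one numeric remains to place, draw a single-slot template
            # so page counts land on target
            pool_tpl <- if (npp[pg] - n_num == 1L) dtpl_single else dtpl
            s <- fill_template(pool_tpl[[sample(length(pool_tpl), 1)]],
                               avoid = gold_vals,
                               suppress = spec$suppress_collisions)
          }
          n_new <- sum(s$roles != "prose")
          filler <- c(filler, list(s))
          n_num <- n_num + n_new
        }

        # gold sentences go near the top of the page (always first in
        # ambiguous mode; otherwise shuffled into the first few slots)
        if (length(gold_here)) {
          if (spec$ambiguous_text) {
            # buffer sentence so the gold window holds no header tokens and
            # only layout separates gold from the identically-worded decoys
            buf <- list(list(tokens = ptpl[[sample(length(ptpl), 1)]],
                             roles = NULL, values = NULL))
            buf[[1]]$roles <- rep("prose", length(buf[[1]]$tokens))
            sentences <- c(buf, gold_here, filler)
          } else {
            k <- length(filler)
            pos <- sort(sample(seq_len(min(4, k + 1)), length(gold_here),
                               replace = TRUE))
            sentences <- filler
            for (j in rev(seq_along(gold_here))) {
              sentences <- append(sentences, gold_here[j], after = pos[j] - 1)
            }
          }
        } else {
          sentences <- filler
        }

        toks <- unlist(lapply(sentences, `[[`, "tokens"))
        rols <- unlist(lapply(sentences, `[[`, "roles"))

        if (pg == 1L) {
          # PHI header
          first <- sample(phi_first_names(), 1)
          last <- sample(phi_last_names(), 1)
          mrn <- sprintf("%07d", sample(0:9999999, 1))
          dob <- sprintf("%02d/%02d/%d", sample(1:12, 1), sample(1:28, 1),
                         sample(1940:2000, 1))
          sdt <- sprintf("%02d/%02d/%d", sample(1:12, 1), sample(1:28, 1),
                         sample(2015:2018, 1))
          hdr <- c("Patient:", first, last, "MRN:", mrn, "DOB:", dob,
                   "Study", "Date:", sdt)
          toks <- c(hdr, toks)
          rols <- c(rep("prose", length(hdr)), rols)
          phi_rows[[r]] <- tibble(report_id = rid,
                                  name = paste(first, last), mrn = mrn)
        }
        page_tokens[[pg]] <- toks
        page_roles[[pg]] <- rols
      }

      # layout + assemble
      rep_rows <- vector("list", n_pages)
      for (pg in seq_len(n_pages)) {
        lay <- layout_page(page_tokens[[pg]], geom)
        keep <- lay$keep
        rep_rows[[pg]] <- tibble(
          report_id = rid, page_num = pg,
          text = page_tokens[[pg]][keep],
          role = page_roles[[pg]][keep],
          left = lay$left[keep], top = lay$top[keep],
          width = lay$width[keep], height = lay$height[keep],
          conf = round(runif(sum(keep), 90, 99), 1))
      }
      rep_tbl <- dplyr::bind_rows(rep_rows)
      rep_tbl$order_idx <- seq_len(nrow(rep_tbl)) - 1L
      word_rows[[r]] <- rep_tbl
      gold_rows[[r]] <- tibble(report_id = rid, ahi = ahi, sao2 = sao2,
                               n_ahi_mentions = sum(rep_tbl$role == "AHI"),
                               n_sao2_mentions = sum(rep_tbl$role == "SaO2"))
    }

    words <- dplyr::bind_rows(word_rows)
    words <- words[, c("report_id", "page_num", "order_idx", "text", "role",
                       "left", "top", "width", "height", "conf")]
    corpus <- structure(
      list(words = words,
           gold = dplyr::bind_rows(gold_rows),
           phi = dplyr::bind_rows(phi_rows),
           pages = NULL,
           spec = spec),
      class = "sleepscan_corpus")
    if (spec$render) {
      corpus$pages <- render_corpus_pages(corpus)
    }
    corpus
  })
}

#' @export
print.sleepscan_corpus <- function(x, ...) {
  cat("<sleepscan_corpus> ", nrow(x$gold), " reports, ",
      nrow(x$words), " planted words",
      if (!is.null(x$pages)) paste0(", ", length(x$pages), " rendered pages"),
      "\n", sep = "")
  invisible(x)
}

#' Summary statistics of a synthetic corpus
#'
#' Recomputes, from the planted words and gold table, the summary statistics
#' the generator is calibrated to: pages per report (median and quartiles),
#' numeric values per page, gold value means/SDs, and the fraction of
#' reports with multiple AHI / SaO2 mentions.
#'
#' @param corpus A `sleepscan_corpus` (or a list with `words` and `gold`).
#' @return A tibble with columns `stat` and `value`.
#' @export
corpus_stats <- function(corpus) {
  words <- corpus$words
  gold <- corpus$gold
  assert_that(!is.null(words) && nrow(words) > 0 && nrow(gold) > 0,
              "corpus_stats needs a non-empty corpus")
  pages <- words %>% group_by(.data$report_id) %>%
    summarise(n_pages = max(.data$page_num), .groups = "drop")
  is_num <- grepl("^[0-9.,%]+$", words$text)
  is_num[is_num] <- !is.na(vapply(words$text[is_num], parse_numeric, 0.0,
                                  USE.NAMES = FALSE))
  npp <- words[is_num, ] %>%
    group_by(.data$report_id, .data$page_num) %>%
    summarise(n = n(), .groups = "drop")
  q <- function(x, p) unname(quantile(x, p, type = 7))
  tibble(
    stat = c("n_reports", "pages_median", "pages_q1", "pages_q3",
             "numerics_per_page_median", "numerics_per_page_q1",
             "numerics_per_page_q3",
             "ahi_mean", "ahi_sd", "sao2_mean", "sao2_sd",
             "frac_multi_ahi", "frac_multi_sao2"),
    value = c(nrow(gold),
              median(pages$n_pages), q(pages$n_pages, .25), q(pages$n_pages, .75),
              median(npp$n), q(npp$n, .25), q(npp$n, .75),
              mean(gold$ahi), sd(gold$ahi), mean(gold$sao2), sd(gold$sao2),
              mean(gold$n_ahi_mentions > 1), mean(gold$n_sao2_mentions > 1)))
}
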