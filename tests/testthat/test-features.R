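test_that("feature tables mark any-overlap presence including boundary spans", {
  win <- make_windows(4)
  iv <- tibble::tibble(chrom = "chr1", start = 39000, end = 41000, feature = "ctcf")
  tab <- build_feature_table(iv, win)
  expect_equal(tab$ctcf, c(1L, 1L, 0L, 0L))
  none <- build_feature_table(iv[0, ], win)
  expect_equal(setdiff(names(none), c("chrom", "start", "end")), character(0))
  # counts mode equals brute-force interval counting
  withr::with_seed(4, {
    ivs <- tibble::tibble(chrom = "chr1",
                          start = sample(0:(4 * 40000 - 1000), 30),
                          feature = "x") |>
      dplyr::mutate(end = .data$start + sample(500:20000, 30, replace = TRUE))
    ivs$end <- pmin(ivs$end, 160000)
  })
  cnt <- build_feature_table(ivs, win, mode = "count")
  brute <- vapply(seq_len(4), function(w) {
    lo <- (w - 1) * 40000; hi <- w * 40000
    sum(ivs$start < hi & ivs$end > lo)
  }, numeric(1))
  expect_equal(cnt$x, brute)
})

test_that("feature pair enumeration counts n(n+1)/2 including homotypic", {
  expect_equal(nrow(enumerate_feature_pairs(paste0("f", 1:14))), 105)
  expect_equal(nrow(enumerate_feature_pairs("solo")), 1)
  expect_equal(nrow(enumerate_feature_pairs(c("a", "b", "c"))), 6)
})

test_that("contact annotation follows the either-orientation rule", {
  win <- make_windows(3)
  tab <- dplyr::bind_cols(win, tibble::tibble(
    ctcf = c(1L, 1L, 0L), enhancer = c(0L, 1L, 0L)))
  contacts <- tibble::tibble(chrom = "chr1",
                             bin_a = c(0, 0, 40000),
                             bin_b = c(40000, 2 * 40000, 0))
  ann <- annotate_contacts(contacts, tab)
  c1 <- sort(ann$pair[ann$contact_id == 1])
  expect_equal(c1, c("ctcf--ctcf", "ctcf--enhancer"))
  # contact 2 (anchors ctcf-only and featureless) dropped
  expect_false(2 %in% ann$contact_id)
  expect_equal(attr(ann, "n_dropped"), 1)
  # symmetric under anchor swap: contact 3 is contact 1 reversed
  expect_equal(sort(ann$pair[ann$contact_id == 3]), c1)
})

test_that("matched backgrounds preserve distance histograms and exclude the foreground", {
  withr::with_seed(15, {
    uni <- tidyr::crossing(chrom = c("chr1", "chr2"), bin_a = (0:25) * 4e4,
                           d = (1:10) * 4e4) |>
      dplyr::mutate(bin_b = .data$bin_a + .data$d) |>
      dplyr::select("chrom", "bin_a", "bin_b")
    fg <- dplyr::slice_sample(uni, n = 60)
  })
  bg <- matched_background(fg, uni, n_perm = 3, seed = 7)
  expect_equal(sort(unique(bg$perm)), 1:3)
  hist_of <- function(d) dplyr::count(dplyr::mutate(d, dd = .data$bin_b - .data$bin_a),
                                      .data$chrom, .data$dd)
  for (p in 1:3) {
    expect_equal(hist_of(bg[bg$perm == p, ]), hist_of(fg), ignore_attr = TRUE)
  }
  expect_false(any(paste(bg$chrom, bg$bin_a, bg$bin_b) %in%
                     paste(fg$chrom, fg$bin_a, fg$bin_b)))
  bg2 <- matched_background(fg, uni, n_perm = 3, seed = 7)
  expect_identical(bg$bin_a, bg2$bin_a)
  expect_error(matched_background(uni, uni), "strictly exceed")
})

test_that("pair frequencies match a hand tally and need not sum to one", {
  ann <- tibble::tibble(
    contact_id = c(1, 1, 2, 3, 3, 3, 4),
    pair = c("a--a", "a--b", "a--a", "a--a", "a--b", "b--b", "b--b"))
  fr <- pair_frequency_stats(list(gam = ann, hic = ann))
  expect_equal(fr$freq_gam[fr$pair == "a--a"], 3 / 4)
  expect_equal(fr$freq_gam[fr$pair == "a--b"], 2 / 4)
  expect_equal(fr$freq_gam[fr$pair == "b--b"], 2 / 4)
  expect_gt(sum(fr$freq_gam), 1)
  expect_equal(fr$amplification_gam, rep(1, 3))
})

test_that("the random forest ranks a perfectly discriminative pair first", {
  withr::with_seed(30, {
    n <- 120
    mk <- function(ids, sep_present) {
      purrr::map_dfr(ids, function(i) {
        pairs <- c(if (sep_present) "sep--sep",
                   sample(c("x--x", "x--y", "y--y"), sample(1:2, 1)))
        tibble::tibble(contact_id = i, pair = unique(pairs))
      })
    }
    gam <- mk(1:n, TRUE)
    hic <- mk(1:n, FALSE)
  })
  rf <- rank_pairs_random_forest(gam, hic, n_trees = 120, seed = 5)
  expect_equal(rf$importance$pair[1], "sep--sep")
  rf2 <- rank_pairs_random_forest(gam, hic, n_trees = 120, seed = 5)
  expect_identical(rf$importance, rf2$importance)
  expect_equal(glance(rf)$cv_accuracy, 1)
  expect_s3_class(tidy(rf), "tbl_df")
  expect_error(rank_pairs_random_forest(gam, gam[0, ], n_trees = 10), "non-empty")
})

test_that("co-occurrence groups partition annotated contacts", {
  ann <- tibble::tibble(
    contact_id = c(1, 1, 2, 3, 4),
    pair = c("a--a", "b--b", "a--a", "c--c", "b--b"))
  out <- cooccurrence_counts(ann, c("a--a", "b--b"))
  expect_equal(out$n[out$group == "a--a+b--b"], 1)
  expect_equal(out$n[out$group == "a--a"], 1)
  expect_equal(out$n[out$group == "(none)"], 1)
  expect_equal(sum(out$n), 4)
  empty_sel <- cooccurrence_counts(ann, character(0))
  expect_equal(empty_sel$group, "(none)")
  expect_equal(empty_sel$n, 4)
})

test_that("class enrichment flags a planted excess of active-active pairs", {
  withr::with_seed(44, {
    win <- make_windows(80)
    classes <- tibble::tibble(chrom = "chr1", start = win$start,
                              class = sample(c("active", "inactive"), 80,
                                             replace = TRUE, prob = c(0.5, 0.5)))
    active <- classes$start[classes$class == "active"]
    inter <- dplyr::bind_rows(
      tibble::tibble(chrom = "chr1",
                     bin_a = sample(active, 60, TRUE),
                     bin_b = sample(active, 60, TRUE)),
      tibble::tibble(chrom = "chr1",
                     bin_a = sample(win$start, 20, TRUE),
                     bin_b = sample(win$start, 20, TRUE)))
    inter <- dplyr::filter(inter, .data$bin_a != .data$bin_b)
  })
  res <- class_enrichment(inter, classes, n_rand = 300, seed = 2)
  expect_equal(res$direction[res$combo == "active-active"], "enriched")
  expect_true(res$flagged[res$combo == "active-active"])
  # Bonferroni widening: corrected bounds at least as wide as uncorrected
  res1 <- class_enrichment(inter, classes, n_rand = 300, seed = 2, level = 0.95)
  k <- nrow(res1)
  expect_true(k >= 2)
})
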