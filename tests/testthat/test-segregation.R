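test_that("segregation tables round-trip through TSV losslessly", {
  row <- tibble::tibble(chrom = "chr1", start = 0L, end = 40000L, a = 1L, b = 0L)
  st <- seg_table(row[1:3], as.matrix(row[c("a", "b")]))
  expect_equal(unname(seg_matrix(st)[1, ]), c(1L, 0L))

  st2 <- random_seg_table(100, 50, p = 0.3, seed = 7, nps = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_segregation(st2, path)
  back <- read_segregation(path)
  expect_identical(seg_matrix(back), seg_matrix(st2))
  expect_equal(seg_windows(back), seg_windows(st2))
  expect_equal(seg_nps(back), seg_nps(st2))
})

test_that("invalid tables are rejected", {
  win <- make_windows(2)
  expect_error(seg_table(win, matrix(c(0, 2, 1, 1), 2)), "0/1")
  bad_win <- win
  bad_win$start <- rev(bad_win$start)
  bad_win$end <- rev(bad_win$end)
  expect_error(seg_table(bad_win, matrix(0L, 2, 2)), "unsorted")
})

test_that("window calling applies an inclusive read threshold", {
  counts <- dplyr::bind_cols(make_windows(4),
                             tibble::tibble(s1 = c(0L, 3L, 4L, 10L)))
  st <- call_positive_windows(counts, threshold = 4)
  expect_equal(unname(seg_matrix(st)[, 1]), c(0L, 0L, 1L, 1L))
  expect_true(all(seg_matrix(call_positive_windows(counts, threshold = 0)) == 1L))
  expect_true(all(seg_matrix(call_positive_windows(counts, threshold = 11)) == 0L))
  counts$s1[1] <- -1L
  expect_error(call_positive_windows(counts), "non-negative")
})

test_that("in-silico multiplexing partitions columns and ORs groups", {
  st <- random_seg_table(10, 480, p = 0.05, seed = 2)
  expect_length(seg_sample_ids(insilico_multiplex(st, 2, seed = 1)), 240)
  m3 <- insilico_multiplex(st, 3, seed = 1)
  expect_length(seg_sample_ids(m3), 160)
  expect_equal(unname(seg_nps(m3)), rep(3, 160))

  tiny <- seg_table(make_windows(2), cbind(a = c(1L, 0L), b = c(0L, 0L), c = c(0L, 1L)))
  out <- insilico_multiplex(tiny, 3, seed = 5)
  expect_equal(unname(seg_matrix(out)[, 1]), c(1L, 1L))

  zeros <- seg_table(make_windows(3), matrix(0L, 3, 4))
  expect_true(all(seg_matrix(insilico_multiplex(zeros, 2, seed = 1)) == 0L))
  expect_error(insilico_multiplex(tiny, 1), "at least 2")
  expect_error(insilico_multiplex(tiny, 4), "exceeds")
})

test_that("multiplexed coverage follows 1 - (1 - c)^k for independent columns", {
  for (p in c(0.05, 0.07, 0.2)) {
    for (k in c(2, 3)) {
      st <- random_seg_table(60, 480, p = p, seed = round(1000 * p) + k)
      out <- insilico_multiplex(st, k, seed = 3)
      cov <- mean(seg_matrix(out))
      expect_lt(abs(cov - (1 - (1 - p)^k)), 0.012)
    }
  }
})

test_that("detection frequency matches a brute-force column scan", {
  st <- seg_from_sets(list(1:5, integer(0)), n_samp = 20)
  wdf <- window_detection_frequency(st)
  expect_equal(wdf$detection_frequency, c(0.25, 0))

  st2 <- random_seg_table(30, 40, p = 0.2, seed = 9)
  m <- seg_matrix(st2)
  brute <- vapply(seq_len(nrow(m)), function(i) sum(m[i, ]) / ncol(m), 1)
  expect_equal(window_detection_frequency(st2)$detection_frequency, brute)
})

test_that("co-segregation counts partition the samples", {
  st <- seg_from_sets(list(c(1, 2, 3), c(2, 3, 4)), n_samp = 6)
  cnt <- pair_cosegregation_counts(st, 1, 2)
  expect_equal(unlist(cnt), c(m = 6, k_both = 2, k_only_a = 1, k_only_b = 1,
                              k_neither = 2))

  same <- seg_from_sets(list(c(1, 3), c(1, 3)), n_samp = 5)
  cs <- pair_cosegregation_counts(same, 1, 2)
  expect_equal(cs$k_only_a + cs$k_only_b, 0)

  disj <- seg_from_sets(list(c(1, 2), c(3, 4)), n_samp = 5)
  expect_equal(pair_cosegregation_counts(disj, 1, 2)$k_both, 0)

  st3 <- random_seg_table(15, 30, p = 0.3, seed = 4)
  for (pair in list(c(1, 2), c(3, 10), c(5, 15))) {
    cnt <- pair_cosegregation_counts(st3, pair[1], pair[2])
    expect_equal(cnt$k_both + cnt$k_only_a + cnt$k_only_b + cnt$k_neither, cnt$m)
  }
  expect_error(pair_cosegregation_counts(st3, "chrX:0", 2), "unknown")
})

test_that("D' matches its definition and stays within [-1, 1]", {
  # p_A = p_B = 0.5, p_AB = 1/3: D = 1/12, Dmax = 1/4, D' = 1/3
  st <- seg_from_sets(list(c(1, 2, 3), c(2, 3, 4)), n_samp = 6)
  lm <- linkage_matrix(st, max_distance = 40000)
  expect_equal(lm$value, 1 / 3)

  ident <- seg_from_sets(list(c(1, 2), c(1, 2)), n_samp = 5)
  expect_equal(linkage_matrix(ident, 40000)$value, 1)

  st2 <- random_seg_table(25, 60, p = 0.3, seed = 12)
  lm2 <- linkage_matrix(st2, max_distance = 10 * 40000)
  expect_true(all(abs(lm2$value) <= 1 + 1e-12))
  expect_true(all(lm2$bin_b > lm2$bin_a))

  # independent columns: mean D' near zero over replicates (at p = 0.5,
  # where the positive- and negative-D normalizers coincide; away from 0.5
  # the finite-sample D' estimator is skewed by its asymmetric denominator)
  means <- vapply(1:8, function(s) {
    mean(linkage_matrix(random_seg_table(20, 200, p = 0.5, seed = 100 + s),
                        max_distance = 19 * 40000)$value)
  }, 1)
  expect_lt(abs(mean(means)), 0.02)
})

test_that("degenerate windows yield missing (absent) D' entries", {
  m <- cbind(a = c(1L, 1L, 0L), b = c(1L, 0L, 0L), c = c(1L, 1L, 0L))
  st <- seg_table(make_windows(3), m)  # window 1 always detected, 3 never
  lm <- linkage_matrix(st, max_distance = 2 * 40000)
  # pairs touching the always-detected window 1 or never-window 3 are absent
  expect_false(any(lm$bin_a == 0))
  expect_false(any(lm$bin_b == 2 * 40000))
})
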