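make_paired <- function(n_bins = 60, res = 40000, seed = 1, chrom = "chr1") {
  withr::with_seed(seed, {
    idx <- which(upper.tri(diag(n_bins)), arr.ind = TRUE)
    d <- (idx[, 2] - idx[, 1]) * res
    keep <- d <= 4e6
    idx <- idx[keep, , drop = FALSE]
    base <- rnorm(nrow(idx))
    tibble::tibble(
      chrom = chrom,
      bin_a = (idx[, 1] - 1) * res, bin_b = (idx[, 2] - 1) * res,
      distance = (idx[, 2] - idx[, 1]) * res,
      gam_value = base + 0.1 * rnorm(nrow(idx)),
      hic_value = base + 0.1 * rnorm(nrow(idx))
    )
  })
}

test_that("the contact mask applies every exclusion rule from both datasets", {
  res <- 40000
  win <- make_windows(6, res = res)
  gam <- contact_tbl(tibble::tibble(
    chrom = "chr1",
    bin_a = c(0, 0, res, res, 0) ,
    bin_b = c(res, 2 * res, 2 * res, 3 * res, 5 * res),
    value = c(-0.2, 0.3, 0.3, 0.4, 0.5)), res, "dprime")
  hic <- contact_tbl(tibble::tibble(
    chrom = "chr1",
    bin_a = c(0, 0, res, res, 0),
    bin_b = c(res, 2 * res, 2 * res, 3 * res, 5 * res),
    value = c(12, 0, 5, 3, 2)), res, "ligation_count")
  wdf <- win
  wdf$detection_frequency <- c(0.07, 0.07, 0.07, 0.2, 0.07, 0.07)
  out <- build_contact_mask(gam, hic, wdf)
  # row1: negative D'; row2: zero ligation; row4: anchor WDF 0.2 out of range
  expect_equal(nrow(out), 2)
  expect_true(all(out$gam_value >= 0 & out$hic_value > 0))
  expect_true(all(paste(out$bin_a, out$bin_b) %in%
                    c(paste(res, 2 * res), paste(0, 5 * res))))
})

test_that("distance z-scores standardize bands and ignore degenerate bands", {
  df <- tibble::tibble(chrom = "chr1", bin_a = c(0, 1, 2, 0, 1, 2) * 4e4,
                       bin_b = c(1, 2, 3, 2, 3, 4) * 4e4,
                       distance = c(4e4, 4e4, 4e4, 8e4, 8e4, 8e4),
                       value = c(1, 2, 3, 5, 5, 5))
  z <- zscore_by_distance(df)
  expect_equal(z$z[z$distance == 4e4], c(-1, 0, 1))
  expect_true(all(is.na(z$z[z$distance == 8e4])))  # zero variance
  # affine invariance per band
  df2 <- dplyr::mutate(df, value = 7 * .data$value - 3)
  expect_equal(zscore_by_distance(df2)$z, z$z)
  # standardization on random matrices
  pc <- make_paired(seed = 5)
  zz <- zscore_by_distance(pc, "gam_value")
  stats <- zz |>
    dplyr::group_by(.data$distance) |>
    dplyr::summarise(mu = mean(.data$z_gam), s = sd(.data$z_gam)) |>
    dplyr::filter(!is.na(.data$s))
  expect_true(all(abs(stats$mu) < 1e-10))
  expect_true(all(abs(stats$s - 1) < 1e-10))
})

test_that("observed/expected and rank transforms behave as defined", {
  df <- tibble::tibble(chrom = "chr1", bin_a = c(0, 1, 2) * 4e4,
                       bin_b = c(1, 2, 3) * 4e4, distance = 4e4,
                       value = c(2, 4, 6))
  oe <- alternative_transforms(df, mode = "obs_exp")
  expect_equal(oe$oe, c(0.5, 1.0, 1.5))
  rk <- alternative_transforms(df, mode = "rank")
  rk2 <- alternative_transforms(dplyr::mutate(df, value = exp(.data$value)),
                                mode = "rank")
  expect_equal(rk$rank, rk2$rank)  # monotone invariance
  zero <- dplyr::mutate(df, value = c(-1, 0, 1))
  expect_true(all(is.na(alternative_transforms(zero, mode = "obs_exp")$oe)))
})

test_that("delta tails recover the quantiles of a known normal", {
  withr::with_seed(3, {
    n <- 1e5
    df <- tibble::tibble(chrom = "chr1",
                         bin_a = seq_len(n), bin_b = seq_len(n) + 1,
                         z_gam = rnorm(n), z_hic = 0)
  })
  out <- delta_and_tails(df, tail = 0.05)
  thr <- attr(out, "thresholds")
  expect_lt(abs(thr$q_hi - 1.6449), 0.02)
  expect_lt(abs(thr$q_lo + 1.6449), 0.02)
  sel <- mean(out$label == "gam_specific")
  expect_gt(sel, 0.04); expect_lt(sel, 0.06)
  expect_error(delta_and_tails(dplyr::mutate(df, z_gam = .data$z_hic)),
               "zero-variance")
})

test_that("swapping GAM and Hi-C negates deltas and swaps the labels", {
  pc <- make_paired(seed = 9)
  z <- zscore_by_distance(pc, "gam_value") |> zscore_by_distance("hic_value")
  a <- delta_and_tails(z, tail = 0.05)
  swapped <- dplyr::rename(pc, gam_value = "hic_value", hic_value = "gam_value")
  zs <- zscore_by_distance(swapped, "gam_value") |> zscore_by_distance("hic_value")
  b <- delta_and_tails(zs, tail = 0.05)
  expect_equal(b$delta, -a$delta, tolerance = 1e-10)
  expect_equal(b$label == "gam_specific", a$label == "hic_specific")
})

test_that("strong-and-common selection takes the weaker z-score top fraction", {
  pc <- make_paired(seed = 13)
  z <- zscore_by_distance(pc, "gam_value") |> zscore_by_distance("hic_value") |>
    dplyr::mutate(delta = .data$z_gam - .data$z_hic)
  sel <- strong_and_common(z, delta_max = 1.0, top_fraction = 0.10)
  expect_equal(sum(sel$strong_common), round(0.10 * nrow(sel)))
  expect_true(all(abs(sel$delta) < 1.0))
  expect_equal(sel$min_z, pmin(sel$z_gam, sel$z_hic))
  picked_min <- min(sel$min_z[sel$strong_common])
  expect_gte(picked_min, max(sel$min_z[!sel$strong_common]))
  big_delta <- dplyr::mutate(z, delta = 1.5)
  expect_error(strong_and_common(big_delta), "no candidates")
})

test_that("Fit-Hi-C import bins fragments by midpoint and filters", {
  rec <- tibble::tibble(
    chrom1 = c("chr1", "chr1", "chr1", "chr2"),
    start1 = c(35000, 35000, 100000, 0), end1 = c(45000, 45000, 110000, 10000),
    chrom2 = c("chr1", "chr1", "chr1", "chr1"),
    start2 = c(995000, 995000, 6e6, 500000), end2 = c(1005000, 1005000, 6.01e6, 510000),
    q_value = c(0.01, 0.06, 0.01, 0.01))
  out <- import_fithic_contacts(rec)
  # row2 fails q, row3 beyond 4 Mb, row4 trans
  expect_equal(nrow(out), 1)
  expect_equal(out$bin_a, 40000)
  expect_equal(out$bin_b, 1000000)
  expect_error(import_fithic_contacts(rec[, -7]), "malformed")
})

test_that("region preference follows the per-chromosome percentile rule", {
  win <- make_windows(10)
  gam <- tibble::tibble(chrom = "chr1", bin_a = 0,
                        bin_b = c(1, 2, 3, 4, 5) * 40000)
  hic <- tibble::tibble(chrom = "chr1", bin_a = 6 * 40000, bin_b = 7 * 40000)
  common <- tibble::tibble(chrom = "chr1", bin_a = 8 * 40000, bin_b = 9 * 40000)
  out <- preferred_regions(gam, hic, common, win)
  # counts: w0 = 5 gam anchors; w1..w5 = 1; w6 = w7 = 1 hic; diff profile
  # (5,1,1,1,1,1,1,1,0,0): 90th percentile (type 7) = 1.4, only w0 above
  expect_equal(out$preference[out$start == 0], "gam_preferred")
  expect_equal(sum(out$preference != "none"), 1)
  # common: top 10% of 10 windows = 1 window, highest count wins
  expect_equal(sum(out$common == "common"), 1)
  expect_equal(out$start[out$common == "common"], 8 * 40000)
  empty <- preferred_regions(gam[0, ], hic[0, ], common[0, ], win)
  expect_true(all(empty$preference == "none") & all(empty$common == "none"))
})

test_that("planted differential contacts are recovered by the 5% tail", {
  withr::with_seed(27, {
    pc <- make_paired(n_bins = 120, seed = 27)
    n <- nrow(pc)
    planted <- sample(n, round(0.02 * n))
    band_sd <- pc |>
      dplyr::group_by(.data$distance) |>
      dplyr::mutate(s = sd(.data$gam_value)) |>
      dplyr::pull(.data$s)
    pc$gam_value[planted] <- pc$gam_value[planted] + 3 * band_sd[planted]
  })
  z <- zscore_by_distance(pc, "gam_value") |> zscore_by_distance("hic_value")
  out <- delta_and_tails(z, tail = 0.05)
  hit <- out$label[planted] == "gam_specific"
  expect_gte(mean(hit), 0.9)
})
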