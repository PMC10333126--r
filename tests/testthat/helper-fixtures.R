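# Fixture builders shared across the suite. Everything is generated in code
# with explicit seeds; no data files.

make_windows <- function(n, chrom = "chr1", res = 40000) {
  tibble::tibble(chrom = chrom, start = (seq_len(n) - 1) * res,
                 end = seq_len(n) * res)
}

# random independent-column segregation table with per-sample coverage p
random_seg_table <- function(n_win = 20, n_samp = 50, p = 0.1, seed = 1,
                             chrom = "chr1", res = 40000, nps = 1) {
  withr::with_seed(seed, {
    m <- matrix(rbinom(n_win * n_samp, 1, p), n_win, n_samp)
    colnames(m) <- sprintf("s%03d", seq_len(n_samp))
    seg_table(make_windows(n_win, chrom, res), m, nps = nps)
  })
}

# seg table from explicit per-window sample index sets
seg_from_sets <- function(sets, n_samp, res = 40000) {
  m <- vapply(seq_len(n_samp), function(s) {
    vapply(sets, function(set) as.integer(s %in% set), integer(1))
  }, integer(length(sets)))
  colnames(m) <- paste0("s", seq_len(n_samp))
  seg_table(make_windows(length(sets), res = res), m)
}

# dense symmetric fixture as a contact_tbl (all upper-triangle pairs in band)
dense_contacts <- function(values_fun, n_bins, res = 40000, chrom = "chr1",
                           value_kind = "dprime", max_distance = NULL) {
  idx <- which(upper.tri(diag(n_bins)), arr.ind = TRUE)
  df <- tibble::tibble(
    chrom = chrom,
    bin_a = (idx[, 1] - 1) * res,
    bin_b = (idx[, 2] - 1) * res,
    value = values_fun(idx[, 1], idx[, 2])
  )
  if (!is.null(max_distance)) df <- df[df$bin_b - df$bin_a <= max_distance, ]
  contact_tbl(df, res, value_kind, max_distance)
}

# two-block matrix: high linkage within blocks, low/negative between
two_block_contacts <- function(n_bins = 30, split_at = 15, within = 0.8,
                               between = -0.2, res = 40000) {
  dense_contacts(function(i, j) {
    same <- (i <= split_at) == (j <= split_at)
    ifelse(same, within, between)
  }, n_bins, res = res, value_kind = "dprime")
}

# manual cell configurations for the ligation simulator: a star hub plus an
# isolated pair, replicated with jitter over cells
star_cells <- function(n_cells = 200, hub_degree = 5, radius = 0.4, seed = 1) {
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1),
                c(0, 0, -1))[seq_len(hub_degree), , drop = FALSE]
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_cells), function(cell) {
      jit <- function() rnorm(3, 0, 0.01)
      hub <- c(0, 0, 0) + jit()
      partners <- lapply(seq_len(hub_degree), function(k) {
        hub + dirs[k, ] * radius * 0.8 + jit()
      })
      iso <- list(c(3, 3, 3) + jit(), c(3.1, 3, 3) + jit())
      pos <- do.call(rbind, c(list(hub), partners, iso))
      tibble::tibble(cell = cell, chrom = "chr1",
                     window = seq_len(nrow(pos)),
                     x = pos[, 1], y = pos[, 2], z = pos[, 3])
    })
  })
}
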