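#' Contact complexity from significant triplets
#'
#' Complexity quantifies how many simultaneous partners a locus engages:
#' at window level, the number of significant triplets containing the
#' window; at pair level, the number of third windows completing a
#' significant triplet with the pair; at region level, the mean of the
#' window-level counts over the member windows.
#'
#' @param triplets A tibble of significant triplets: `chrom`, `bin_a`,
#'   `bin_b`, `bin_c` (canonically ordered; duplicates removed).
#' @param windows A tibble of windows (`chrom`, `start`) defining the
#'   universe (zero counts included).
#' @param level `"window"`, `"pair"` or `"region"`.
#' @param regions For `level = "region"`: a tibble `chrom`, `start`,
#'   `region` assigning member windows to regions.
#' @return A tibble of counts: per window (`chrom`, `start`, `n_triplets`),
#'   per pair (`chrom`, `bin_a`, `bin_b`, `n_triplets`), or per region
#'   (`region`, `mean_triplets`).
#' @export
complexity_profile <- function(triplets, windows, level = c("window", "pair", "region"),
                               regions = NULL) {
  level <- match.arg(level)
  triplets <- dplyr::distinct(tibble::as_tibble(triplets),
                              .data$chrom, .data$bin_a, .data$bin_b, .data$bin_c)
  window_counts <- function() {
    long <- dplyr::bind_rows(
      dplyr::transmute(triplets, chrom = .data$chrom, start = .data$bin_a),
      dplyr::transmute(triplets, chrom = .data$chrom, start = .data$bin_b),
      dplyr::transmute(triplets, chrom = .data$chrom, start = .data$bin_c)
    ) |>
      dplyr::count(.data$chrom, .data$start, name = "n_triplets")
    tibble::as_tibble(windows)[c("chrom", "start")] |>
      dplyr::left_join(long, by = c("chrom", "start")) |>
      dplyr::mutate(n_triplets = dplyr::coalesce(.data$n_triplets, 0L))
  }
  if (level == "window") return(window_counts())
  if (level == "pair") {
    pairs <- dplyr::bind_rows(
      dplyr::transmute(triplets, chrom = .data$chrom, bin_a = .data$bin_a, bin_b = .data$bin_b),
      dplyr::transmute(triplets, chrom = .data$chrom, bin_a = .data$bin_a, bin_b = .data$bin_c),
      dplyr::transmute(triplets, chrom = .data$chrom, bin_a = .data$bin_b, bin_b = .data$bin_c)
    )
    return(dplyr::count(pairs, .data$chrom, .data$bin_a, .data$bin_b,
                        name = "n_triplets"))
  }
  if (is.null(regions)) abort("regions required at region level")
  window_counts() |>
    dplyr::inner_join(tibble::as_tibble(regions), by = c("chrom", "start")) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(mean_triplets = mean(.data$n_triplets), n_windows = dplyr::n())
}

# enumerate intra-chromosomal triples of bins with spans, as a tibble
enumerate_triples <- function(bins, max_span = Inf) {
  n <- length(bins)
  if (n < 3) return(tibble::tibble(a = numeric(), b = numeric(), c = numeric()))
  combos <- utils::combn(sort(bins), 3)
  out <- tibble::tibble(a = combos[1, ], b = combos[2, ], c = combos[3, ])
  dplyr::filter(out, .data$c - .data$a <= max_span)
}

#' Triplets inferred from Hi-C pairwise transitivity
#'
#' If a triplet (A, B, C) is formed, all three pairwise contacts should be
#' seen by Hi-C, so the triplet intensity is scored as the minimum of the
#' three pairwise ligation values. Candidates are stratified by span
#' (C - A); within every stratum holding at least `min_candidates`
#' candidates the strongest `top_fraction` are kept (ties broken by
#' (A, B, C) order).
#'
#' @param hic A [contact_tbl] of ligation counts (1 Mb bins typically).
#' @param top_fraction Fraction kept per stratum (default 0.02).
#' @param min_candidates Minimum candidates per stratum (default 500).
#' @param max_span Optional span cap in bp.
#' @return A tibble of triplet records: `chrom`, `bin_a`, `bin_b`, `bin_c`,
#'   `span`, `score`, `source = "hic_transitivity"`.
#' @export
hic_transitivity_triplets <- function(hic, top_fraction = 0.02,
                                      min_candidates = 500, max_span = Inf) {
  df <- tibble::as_tibble(hic)
  score_triples(df, top_fraction, min_candidates, max_span,
                best = "high", source = "hic_transitivity")
}

score_triples <- function(df, top_fraction, min_candidates, max_span, best, source) {
  rows <- lapply(split(df, df$chrom), function(sub) {
    val <- setNames(sub$value, paste(sub$bin_a, sub$bin_b))
    bins <- sort(unique(c(sub$bin_a, sub$bin_b)))
    tri <- enumerate_triples(bins, max_span)
    if (nrow(tri) == 0) return(NULL)
    s_ab <- val[paste(tri$a, tri$b)]
    s_ac <- val[paste(tri$a, tri$c)]
    s_bc <- val[paste(tri$b, tri$c)]
    tibble::tibble(
      chrom = sub$chrom[1],
      bin_a = tri$a, bin_b = tri$b, bin_c = tri$c,
      span = tri$c - tri$a,
      score = unname(pmin(s_ab, s_ac, s_bc))
    ) |>
      dplyr::filter(!is.na(.data$score))
  })
  cand <- dplyr::bind_rows(rows)
  if (nrow(cand) == 0) {
    return(tibble::tibble(chrom = character(), bin_a = numeric(),
                          bin_b = numeric(), bin_c = numeric(),
                          span = numeric(), score = numeric(),
                          source = character()))
  }
  cand |>
    dplyr::group_by(.data$span) |>
    dplyr::filter(dplyr::n() >= min_candidates) |>
    dplyr::arrange(if (best == "high") dplyr::desc(.data$score) else .data$score,
                   .data$chrom, .data$bin_a, .data$bin_b, .data$bin_c,
                   .by_group = TRUE) |>
    dplyr::mutate(.keep_n = ceiling(top_fraction * dplyr::n())) |>
    dplyr::filter(dplyr::row_number() <= .data$.keep_n) |>
    dplyr::ungroup() |>
    dplyr::select(-".keep_n") |>
    dplyr::mutate(source = source) |>
    dplyr::arrange(.data$chrom, .data$bin_a, .data$bin_b, .data$bin_c)
}

#' Triplets from single-cell 3D models
#'
#' Scores every bin triple by the maximum of its three pairwise Euclidean
#' distances within each 3D model (cell x haplotype), then takes the
#' minimum over models with complete data; tight triplets (lowest
#' `bottom_fraction` per span stratum with at least `min_candidates`
#' candidates) are kept. Triples with no complete model are skipped.
#'
#' @param coords A tibble: `model`, `chrom`, `bin`, `x`, `y`, `z` (bin 3D
#'   centroids per model; missing bins simply absent).
#' @param bottom_fraction Fraction kept per stratum (default 0.02).
#' @param min_candidates Minimum candidates per stratum (default 500).
#' @param max_span Optional span cap in bp.
#' @return A triplet tibble as in [hic_transitivity_triplets()], with
#'   `source = "model3d"`.
#' @export
model3d_triplets <- function(coords, bottom_fraction = 0.02,
                             min_candidates = 500, max_span = Inf) {
  rows <- lapply(split(coords, coords$chrom), function(sub) {
    bins <- sort(unique(sub$bin))
    tri <- enumerate_triples(bins, max_span)
    if (nrow(tri) == 0) return(NULL)
    models <- split(sub, sub$model)
    score_mat <- vapply(models, function(mod) {
      pos <- as.matrix(mod[c("x", "y", "z")])
      # match() gives NA rows for bins absent from this model
      pa <- pos[match(tri$a, mod$bin), , drop = FALSE]
      pb <- pos[match(tri$b, mod$bin), , drop = FALSE]
      pc <- pos[match(tri$c, mod$bin), , drop = FALSE]
      d_ab <- sqrt(rowSums((pa - pb)^2))
      d_ac <- sqrt(rowSums((pa - pc)^2))
      d_bc <- sqrt(rowSums((pb - pc)^2))
      pmax(d_ab, d_ac, d_bc)
    }, numeric(nrow(tri)))
    score <- apply(matrix(score_mat, nrow = nrow(tri)), 1, function(s) {
      s <- s[is.finite(s)]
      if (length(s) == 0) NA_real_ else min(s)
    })
    tibble::tibble(chrom = sub$chrom[1], bin_a = tri$a, bin_b = tri$b,
                   bin_c = tri$c, span = tri$c - tri$a, score = score) |>
      dplyr::filter(!is.na(.data$score))
  })
  cand <- dplyr::bind_rows(rows)
  if (nrow(cand) == 0) {
    return(tibble::tibble(chrom = character(), bin_a = numeric(),
                          bin_b = numeric(), bin_c = numeric(),
                          span = numeric(), score = numeric(),
                          source = character()))
  }
  cand |>
    dplyr::group_by(.data$span) |>
    dplyr::filter(dplyr::n() >= min_candidates) |>
    dplyr::arrange(.data$score, .data$chrom, .data$bin_a, .data$bin_b,
                   .data$bin_c, .by_group = TRUE) |>
    dplyr::mutate(.keep_n = ceiling(bottom_fraction * dplyr::n())) |>
    dplyr::filter(dplyr::row_number() <= .data$.keep_n) |>
    dplyr::ungroup() |>
    dplyr::select(-".keep_n") |>
    dplyr::mutate(source = "model3d") |>
    dplyr::arrange(.data$chrom, .data$bin_a, .data$bin_b, .data$bin_c)
}

#' Centroid bin positions from particle-level 3D models
#'
#' Collapses fine-grained model particles (for example 10-kb beads) into
#' coarse-bin 3D positions by averaging the coordinates of all particles
#' falling in each bin.
#'
#' @param particles A tibble: `model`, `chrom`, `pos` (bp), `x`, `y`, `z`.
#' @param resolution Coarse bin size in bp (default 1 Mb).
#' @return A tibble `model`, `chrom`, `bin`, `x`, `y`, `z`.
#' @export
bin_model_coordinates <- function(particles, resolution = 1e6) {
  particles |>
    dplyr::mutate(bin = (.data$pos %/% resolution) * resolution) |>
    dplyr::group_by(.data$model, .data$chrom, .data$bin) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
                     .groups = "drop")
}

#' Overlap fraction between two triplet sets
#'
#' `|A intersect B| / |A|` with exact (chrom, A, B, C) identity.
#'
#' @param set_a,set_b Triplet tibbles (`chrom`, `bin_a`, `bin_b`, `bin_c`).
#' @return A fraction in `[0, 1]`.
#' @export
triplet_overlap <- function(set_a, set_b) {
  if (nrow(set_a) == 0) abort("set_a is empty")
  key <- function(d) paste(d$chrom, d$bin_a, d$bin_b, d$bin_c)
  mean(key(set_a) %in% key(set_b))
}

#' Hi-C intensity within GAM-linkage bins, stratified by complexity
#'
#' Bins pairwise contacts by their GAM linkage value, then summarises the
#' Hi-C value distribution within each bin across complexity strata
#' (triplet counts per pair). On ligation-limited data this exposes the
#' dilution of pairwise Hi-C counts at high-complexity pairs that share a
#' GAM linkage level.
#'
#' @param gam A [contact_tbl] (D' or similar linkage values).
#' @param hic A [contact_tbl] of ligation counts on the same bins.
#' @param pair_complexity A pair-level [complexity_profile()] result.
#' @param n_bins Number of GAM-linkage bins (default 5).
#' @param complexity_breaks Breaks for complexity strata (default
#'   `c(-Inf, 0, 2, Inf)` giving 0, 1-2, 3+).
#' @return A tibble per (linkage bin, complexity stratum): `n`,
#'   `hic_median`.
#' @export
complexity_vs_hic_summary <- function(gam, hic, pair_complexity, n_bins = 5,
                                      complexity_breaks = c(-Inf, 0, 2, Inf)) {
  g <- tibble::as_tibble(gam) |> dplyr::rename(gam_value = "value")
  h <- tibble::as_tibble(hic) |> dplyr::rename(hic_value = "value")
  joined <- dplyr::inner_join(g, h, by = c("chrom", "bin_a", "bin_b")) |>
    dplyr::left_join(pair_complexity, by = c("chrom", "bin_a", "bin_b")) |>
    dplyr::mutate(n_triplets = dplyr::coalesce(.data$n_triplets, 0L))
  joined |>
    dplyr::mutate(
      linkage_bin = cut(.data$gam_value, breaks = n_bins, include.lowest = TRUE),
      complexity = cut(.data$n_triplets, breaks = complexity_breaks)
    ) |>
    dplyr::group_by(.data$linkage_bin, .data$complexity) |>
    dplyr::summarise(n = dplyr::n(), hic_median = median(.data$hic_value),
                     .groups = "drop")
}
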