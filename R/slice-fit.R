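#' Fit the SLICE pair model across a segregation table
#'
#' End-to-end pairwise inference: for every intra-chromosomal window pair
#' within `max_distance`, counts tubes detecting one or both windows,
#' estimates the interaction probability `Pi` by inverting the
#' co-segregation ratio, tests it against the non-interacting null, and
#' controls the FDR by Benjamini-Hochberg at `fdr_threshold`.
#'
#' The single-locus capture probability `v` comes from the nuclear
#' geometry; the detection efficiency is calibrated so that the model's
#' per-profile detection rate matches the table's mean window detection
#' frequency (given the effective profiles per tube, taken from the
#' table's `nps` metadata unless supplied). The background `u(d)` is
#' estimated per genomic distance from the table
#' ([background_coseg_from_table()]); pairs whose background reaches the
#' interacting co-capture `t` are unidentifiable and return `NA`.
#'
#' @param x A [seg_table].
#' @param geometry A [nuclear_geometry].
#' @param x_np Effective nuclear profiles per tube; default the mean of the
#'   table's per-sample NP counts.
#' @param detection_efficiency Observation thinning; default calibrated
#'   from the table's mean detection frequency.
#' @param max_distance Band limit in bp.
#' @param delta Physical separation of interacting loci (um), default `h/2`.
#' @param alpha Per-test significance level.
#' @param fdr_threshold BH threshold for the `significant` flag.
#' @param min_pairs Minimum pairs per distance for the background estimate.
#' @return A `slice_pairs` tibble: `chrom`, `bin_a`, `bin_b`, `distance`,
#'   `k1`, `k2`, `m`, `u`, `pi_hat`, `coseg_ratio_obs`, `p_value`,
#'   `q_value`, `significant`.
#' @export
slice_pairs <- function(x, geometry = nuclear_geometry(), x_np = NULL,
                        detection_efficiency = NULL, max_distance = 4e6,
                        delta = geometry$h / 2, alpha = 0.05,
                        fdr_threshold = 0.1, min_pairs = 10) {
  X <- x_np %||% mean(seg_nps(x))
  v <- single_capture_prob(geometry)
  t <- interacting_coseg_prob(geometry, delta)
  eff <- detection_efficiency %||% calibrate_efficiency(x, v, X)
  bg <- background_coseg_from_table(x, v, X, eff, max_distance, min_pairs)
  win <- seg_windows(x)
  m <- seg_matrix(x)
  n_samp <- ncol(m)
  pairs <- dplyr::bind_rows(lapply(split(seq_len(nrow(win)), win$chrom), function(idx) {
    sub <- m[idx, , drop = FALSE]
    both <- tcrossprod(sub)
    npos <- rowSums(sub)
    starts <- win$start[idx]
    ij <- which(upper.tri(both), arr.ind = TRUE)
    d <- starts[ij[, 2]] - starts[ij[, 1]]
    keep <- d > 0 & d <= max_distance
    ij <- ij[keep, , drop = FALSE]
    tibble::tibble(
      chrom = win$chrom[idx[1]],
      bin_a = starts[ij[, 1]], bin_b = starts[ij[, 2]],
      distance = starts[ij[, 2]] - starts[ij[, 1]],
      k2 = both[ij],
      k1 = npos[ij[, 1]] + npos[ij[, 2]] - 2 * both[ij]
    )
  }))
  pairs$m <- n_samp
  pairs <- dplyr::left_join(pairs, bg[c("distance", "u")], by = "distance")
  fit_one <- memoise_pair_fit(v, t, X, eff, n_samp, alpha)
  fits <- purrr::pmap_dfr(pairs[c("k1", "k2", "u")], fit_one)
  out <- dplyr::bind_cols(pairs, fits)
  adj <- bh_adjust(out$p_value, fdr_threshold)
  out$q_value <- adj$q_value
  out$significant <- adj$significant
  attr(out, "params") <- list(geometry = geometry, x_np = X, v = v, t = t,
                              detection_efficiency = eff, alpha = alpha,
                              fdr_threshold = fdr_threshold,
                              max_distance = max_distance)
  class(out) <- unique(c("slice_pairs", class(out)))
  out
}

# Calibrate detection efficiency so the model per-profile detection rate
# matches the observed mean window detection frequency.
calibrate_efficiency <- function(x, v, x_np) {
  wdf <- mean(window_detection_frequency(x)$detection_frequency)
  v_obs <- 1 - (1 - min(wdf, 0.999))^(1 / x_np)
  min(1, v_obs / v)
}

memoise_pair_fit <- function(v, t, x_np, eff, m, alpha) {
  cache <- new.env(parent = emptyenv())
  function(k1, k2, u) {
    key <- paste(k1, k2, signif(u, 10), sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    res <- if (is.na(u) || u >= t) {
      tibble::tibble(pi_hat = NA_real_, coseg_ratio_obs = if (k1 + k2 > 0) k2 / (k1 + k2) else NA_real_,
                     boundary = "unidentifiable", p_value = NA_real_)
    } else {
      est <- estimate_pi(k1, k2, m, v, u, t, x_np, eff)
      tst <- pair_null_test(k1, k2, m, v, u, t, x_np, eff, alpha)
      dplyr::bind_cols(est, tst["p_value"])
    }
    cache[[key]] <- res
    res
  }
}

#' Fit the SLICE triplet model across a segregation table
#'
#' For every intra-chromosomal window triple within `max_span`, counts
#' tubes detecting all three windows and tubes detecting any, and fits the
#' triplet interaction probability `Pi_ABC` by inverting the triple
#' co-segregation ratio (see [estimate_pi_abc()]). Pairwise co-capture
#' probabilities enter through the pairwise fits; the triple background is
#' estimated per span stratum from the table itself. Intended for coarse
#' (for example 1 Mb) windows, where all-triples enumeration is tractable.
#'
#' @inheritParams slice_pairs
#' @param max_span Maximum triplet span (C - A) in bp.
#' @param pair_fit Optional precomputed [slice_pairs()] result for the same
#'   table (computed if missing).
#' @param min_triples Minimum triples per span stratum for the triple
#'   background estimate.
#' @return A `slice_triplets` tibble: `chrom`, `bin_a`, `bin_b`, `bin_c`,
#'   `span`, `k_all`, `k_any`, `pi_abc_hat`, `p_value`, `significant`.
#' @export
slice_triplets <- function(x, geometry = nuclear_geometry(), x_np = NULL,
                           detection_efficiency = NULL, max_span = 20e6,
                           delta = geometry$h / 2, alpha = 0.05,
                           pair_fit = NULL, min_triples = 10, min_pairs = 10) {
  X <- x_np %||% mean(seg_nps(x))
  v <- single_capture_prob(geometry)
  t <- interacting_coseg_prob(geometry, delta)
  eff <- detection_efficiency %||% calibrate_efficiency(x, v, X)
  if (is.null(pair_fit)) {
    pair_fit <- slice_pairs(x, geometry, X, eff, max_distance = max_span,
                            delta = delta, alpha = alpha, min_pairs = min_pairs)
  }
  bg3 <- background_triple_coseg(x, v, X, eff, max_span, min_triples)
  t3 <- t  # three mutually co-located loci share the pairwise slab overlap
  win <- seg_windows(x)
  m <- seg_matrix(x)
  n_samp <- ncol(m)
  pair_key <- paste(pair_fit$chrom, pair_fit$bin_a, pair_fit$bin_b)
  n2_pair <- ifelse(is.na(pair_fit$pi_hat), pair_fit$u,
                    pair_fit$pi_hat * t + (1 - pair_fit$pi_hat) * pair_fit$u)
  names(n2_pair) <- pair_key
  rows <- lapply(split(seq_len(nrow(win)), win$chrom), function(idx) {
    n <- length(idx)
    if (n < 3) return(NULL)
    starts <- win$start[idx]
    combos <- utils::combn(n, 3)
    span <- starts[combos[3, ]] - starts[combos[1, ]]
    keep <- span <= max_span
    combos <- combos[, keep, drop = FALSE]
    if (ncol(combos) == 0) return(NULL)
    sub <- m[idx, , drop = FALSE] > 0
    tibble::tibble(
      chrom = win$chrom[idx[1]],
      bin_a = starts[combos[1, ]], bin_b = starts[combos[2, ]],
      bin_c = starts[combos[3, ]],
      span = span[keep],
      k_all = vapply(seq_len(ncol(combos)), function(j) {
        sum(sub[combos[1, j], ] & sub[combos[2, j], ] & sub[combos[3, j], ])
      }, numeric(1)),
      k_any = vapply(seq_len(ncol(combos)), function(j) {
        sum(sub[combos[1, j], ] | sub[combos[2, j], ] | sub[combos[3, j], ])
      }, numeric(1))
    )
  })
  trips <- dplyr::bind_rows(rows)
  if (nrow(trips) == 0) abort("no triples within max_span")
  trips <- dplyr::left_join(trips, bg3[c("span", "u3")], by = "span")
  fits <- purrr::pmap_dfr(
    trips[c("chrom", "bin_a", "bin_b", "bin_c", "k_all", "k_any", "u3")],
    function(chrom, bin_a, bin_b, bin_c, k_all, k_any, u3) {
      n2 <- c(n2_pair[paste(chrom, bin_a, bin_b)],
              n2_pair[paste(chrom, bin_a, bin_c)],
              n2_pair[paste(chrom, bin_b, bin_c)])
      n2[is.na(n2)] <- v^2
      if (is.na(u3) || u3 >= t3) {
        return(tibble::tibble(pi_abc_hat = NA_real_, ratio_obs = NA_real_,
                              p_value = NA_real_, significant = FALSE,
                              boundary = "unidentifiable"))
      }
      estimate_pi_abc(k_all, k_any, n_samp, v, n2, t3, u3, X, eff, alpha)
    })
  out <- dplyr::bind_cols(trips, fits)
  attr(out, "params") <- list(geometry = geometry, x_np = X, v = v, t3 = t3,
                              detection_efficiency = eff, alpha = alpha)
  class(out) <- unique(c("slice_triplets", class(out)))
  out
}
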