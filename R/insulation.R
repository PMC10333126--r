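#' Insulation-square profile of a contact matrix
#'
#' For each bin `i`, averages the matrix entries in the square spanning the
#' `s` bins to its left against the `s` bins to its right (`s` = square
#' size / resolution). Profiles are normalized per chromosome:
#' `log2(score / chromosomal mean)` when every score is positive, or
#' `score - chromosomal mean` as soon as negative values occur — the
#' adjustment that lets insulation run on D' matrices, whose entries can
#' be negative. Bins within `s` of a chromosome end are invalid.
#'
#' @param x A [contact_tbl].
#' @param square Square size in bp (default 400 kb); must be a multiple of
#'   the resolution.
#' @param normalization `"auto"` (default: log-ratio for strictly positive
#'   matrices, subtractive otherwise), `"log2"`, or `"subtract"`.
#' @return An `insulation_profile` tibble: `chrom`, `start`, `raw`,
#'   `score`, `valid`.
#' @export
insulation_profile <- function(x, square = 400e3,
                               normalization = c("auto", "log2", "subtract")) {
  normalization <- match.arg(normalization)
  res <- contact_resolution(x)
  if (square %% res != 0) abort("square must be a multiple of the resolution")
  s <- square %/% res
  df <- tibble::as_tibble(x)
  out <- purrr::map_dfr(split(df, df$chrom), function(sub) {
    n <- max(sub$bin_b) / res + 1
    if (n <= 2 * s) abort("square too large for chromosome")
    mat <- contact_dense(x, sub$chrom[1], n_bins = n)
    raw <- rep(NA_real_, n)
    for (i in (s + 1):(n - s)) {
      block <- mat[(i - s):(i - 1), (i + 1):(i + s)]
      raw[i] <- mean(block, na.rm = TRUE)
    }
    raw[is.nan(raw)] <- NA_real_
    valid <- !is.na(raw)
    mode <- normalization
    if (mode == "auto") {
      mode <- if (any(raw[valid] <= 0)) "subtract" else "log2"
    }
    score <- rep(NA_real_, n)
    mu <- mean(raw[valid])
    score[valid] <- if (mode == "log2") log2(raw[valid] / mu) else raw[valid] - mu
    tibble::tibble(chrom = sub$chrom[1], start = (seq_len(n) - 1) * res,
                   raw = raw, score = score, valid = valid,
                   normalization = mode)
  })
  attr(out, "square") <- square
  attr(out, "resolution") <- res
  class(out) <- unique(c("insulation_profile", class(out)))
  out
}

#' Call TAD boundaries from an insulation profile
#'
#' Computes the insulation delta at each bin — the mean profile over
#' `delta_span` to the left minus the mean over `delta_span` to the right —
#' and places candidate boundaries at its positive-to-negative zero
#' crossings (insulation minima). Candidates whose local delta amplitude
#' (left maximum minus right minimum of the delta around the crossing)
#' falls below `noise_threshold` are suppressed. Each boundary is reported
#' as a range of `bmoe` bins either side of the candidate (the boundary
#' margin of error), with the delta amplitude as its strength.
#'
#' @param profile An [insulation_profile()] result.
#' @param delta_span Span in bp for the one-sided means (default 200 kb).
#' @param noise_threshold Minimum delta amplitude (default 0.1).
#' @param bmoe Boundary margin of error in bins (default 3).
#' @return A `tad_boundaries` tibble: `chrom`, `start`, `end`, `midpoint`,
#'   `strength`.
#' @export
call_boundaries <- function(profile, delta_span = 200e3, noise_threshold = 0.1,
                            bmoe = 3) {
  res <- attr(profile, "resolution")
  w <- max(1, delta_span %/% res)
  out <- purrr::map_dfr(split(profile, profile$chrom), function(sub) {
    sub <- dplyr::arrange(sub, .data$start)
    sc <- sub$score
    n <- length(sc)
    delta <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      left <- sc[max(1, i - w):max(1, i - 1)]
      right <- sc[min(n, i + 1):min(n, i + w)]
      if (i == 1 || i == n) next
      if (all(is.na(left)) || all(is.na(right))) next
      delta[i] <- mean(left, na.rm = TRUE) - mean(right, na.rm = TRUE)
    }
    cross <- which(!is.na(delta[-n]) & !is.na(delta[-1]) &
                     delta[-n] > 0 & delta[-1] <= 0)
    if (length(cross) == 0) return(NULL)
    purrr::map_dfr(cross, function(i) {
      lo <- max(1, i - w); hi <- min(n, i + 1 + w)
      amp <- max(delta[lo:i], na.rm = TRUE) - min(delta[(i + 1):hi], na.rm = TRUE)
      if (!is.finite(amp) || amp < noise_threshold) return(NULL)
      # boundary bin: the crossing bin whose score is lower
      b <- if (!is.na(sc[i + 1]) && !is.na(sc[i]) && sc[i + 1] < sc[i]) i + 1 else i
      tibble::tibble(
        chrom = sub$chrom[1],
        start = sub$start[max(1, b - bmoe)],
        end = sub$start[min(n, b + bmoe)] + res,
        midpoint = sub$start[b] + res / 2,
        strength = amp
      )
    })
  })
  class(out) <- unique(c("tad_boundaries", class(out)))
  out
}

#' Merge touching boundaries and match boundary sets
#'
#' `merge_boundaries()` coalesces overlapping or touching boundary ranges
#' per chromosome, keeping the maximum strength (idempotent and
#' order-independent). `match_boundaries()` pairs boundaries from two sets
#' bidirectionally: a pair matches when the ranges overlap or lie within
#' `max_gap` (default 1 bp) of one another.
#'
#' @param boundaries,set_a,set_b Boundary tibbles (`chrom`, `start`, `end`,
#'   `strength`).
#' @param max_gap Maximum separation still counted as matched.
#' @return `merge_boundaries()`: a merged boundary tibble.
#'   `match_boundaries()`: a list with `matched` (tibble of index pairs
#'   and gaps), `frac_a_matched`, `frac_b_matched`.
#' @export
merge_boundaries <- function(boundaries) {
  purrr::map_dfr(split(boundaries, boundaries$chrom), function(sub) {
    sub <- dplyr::arrange(sub, .data$start, .data$end)
    grp <- cumsum(c(1, sub$start[-1] > cummax(sub$end[-nrow(sub)])))
    sub |>
      dplyr::mutate(.grp = grp) |>
      dplyr::group_by(.data$.grp) |>
      dplyr::summarise(
        chrom = .data$chrom[1],
        start = min(.data$start), end = max(.data$end),
        midpoint = (min(.data$start) + max(.data$end)) / 2,
        strength = max(.data$strength), .groups = "drop"
      ) |>
      dplyr::select(-".grp")
  })
}

#' @rdname merge_boundaries
#' @export
match_boundaries <- function(set_a, set_b, max_gap = 1) {
  a <- dplyr::mutate(tibble::as_tibble(set_a), .id_a = dplyr::row_number())
  b <- dplyr::mutate(tibble::as_tibble(set_b), .id_b = dplyr::row_number())
  hits <- dplyr::inner_join(a, b, by = "chrom", suffix = c("_a", "_b"),
                            relationship = "many-to-many") |>
    dplyr::mutate(gap = pmax(.data$start_a - .data$end_b,
                             .data$start_b - .data$end_a, 0)) |>
    dplyr::filter(.data$gap <= max_gap)
  list(
    matched = dplyr::select(hits, "chrom", "id_a" = ".id_a", "id_b" = ".id_b", "gap"),
    frac_a_matched = length(unique(hits$.id_a)) / nrow(a),
    frac_b_matched = length(unique(hits$.id_b)) / nrow(b)
  )
}

#' Mean signal profile around boundary midpoints
#'
#' Averages a base-pair signal track in fixed offset bins across a flank
#' around every boundary midpoint, and estimates a background by circularly
#' shifting the boundary positions within each chromosome by random
#' offsets (preserving per-chromosome boundary counts and spacing
#' statistics).
#'
#' @param boundaries A boundary tibble with `chrom` and `midpoint`.
#' @param signal A tibble `chrom`, `start`, `end`, `value` (piecewise
#'   constant track).
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param flank Half-width of the profile in bp (default 500 kb).
#' @param bin Offset bin size in bp (default 10 kb).
#' @param n_shifts Number of circular-shift randomizations (default 10).
#' @param seed Integer seed.
#' @return A tibble per offset bin: `offset`, `mean_signal`, `bg_mean`,
#'   `bg_sd`; boundaries whose flank leaves the chromosome contribute
#'   truncated (flagged in the `n_truncated` attribute).
#' @export
boundary_feature_profile <- function(boundaries, signal, chrom_sizes,
                                     flank = 500e3, bin = 10e3, n_shifts = 10,
                                     seed = 1L) {
  offsets <- seq(-flank, flank - bin, by = bin)
  profile_for <- function(mids_by_chrom) {
    acc <- matrix(NA_real_, 0, length(offsets))
    n_trunc <- 0L
    for (chrom in names(mids_by_chrom)) {
      sig <- signal[signal$chrom == chrom, , drop = FALSE]
      size <- chrom_sizes[[chrom]]
      for (mid in mids_by_chrom[[chrom]]) {
        lo <- mid + offsets
        hi <- lo + bin
        if (any(lo < 0) || any(hi > size)) n_trunc <- n_trunc + 1L
        vals <- vapply(seq_along(lo), function(j) {
          if (lo[j] < 0 || hi[j] > size) return(NA_real_)
          ov <- pmin(sig$end, hi[j]) - pmax(sig$start, lo[j])
          keep <- ov > 0
          if (!any(keep)) return(0)
          sum(sig$value[keep] * ov[keep]) / bin
        }, numeric(1))
        acc <- rbind(acc, vals)
      }
    }
    list(mean = colMeans(acc, na.rm = TRUE), n_trunc = n_trunc)
  }
  mids <- split(boundaries$midpoint, boundaries$chrom)
  obs <- profile_for(mids)
  bg <- with_seed(seed, {
    vapply(seq_len(n_shifts), function(i) {
      shifted <- purrr::imap(mids, function(m, chrom) {
        (m + runif(1) * chrom_sizes[[chrom]]) %% chrom_sizes[[chrom]]
      })
      profile_for(shifted)$mean
    }, numeric(length(offsets)))
  })
  out <- tibble::tibble(
    offset = offsets + bin / 2,
    mean_signal = obs$mean,
    bg_mean = rowMeans(bg),
    bg_sd = apply(bg, 1, sd)
  )
  attr(out, "n_truncated") <- obs$n_trunc
  out
}

#' @export
autoplot.insulation_profile <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$valid),
                  ggplot2::aes(.data$start, .data$score)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "insulation score")
}
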