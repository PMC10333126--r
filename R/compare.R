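#' Shared validity mask for paired GAM and Hi-C matrices
#'
#' Joins a GAM D' matrix with a Hi-C count matrix on (chrom, bin pair) and
#' applies the comparison filters: contacts beyond `max_distance` are
#' dropped, negative D' contacts are removed, contacts with zero Hi-C
#' ligation events are removed, and contacts touching windows whose
#' detection frequency lies outside `wdf_range` (over- or under-sampled
#' windows) are removed. An exclusion from either dataset removes the
#' contact from both.
#'
#' @param gam A [contact_tbl] with `value_kind = "dprime"`.
#' @param hic A [contact_tbl] with `value_kind = "ligation_count"`.
#' @param wdf A tibble from [window_detection_frequency()].
#' @param max_distance Band limit in bp (default 4 Mb).
#' @param wdf_range Admissible detection-frequency interval (default
#'   `c(0.05, 0.10)`).
#' @return A tibble of retained contacts: `chrom`, `bin_a`, `bin_b`,
#'   `distance`, `gam_value`, `hic_value`.
#' @export
build_contact_mask <- function(gam, hic, wdf, max_distance = 4e6,
                               wdf_range = c(0.05, 0.10)) {
  if (contact_resolution(gam) != contact_resolution(hic)) {
    abort("GAM and Hi-C matrices must share a resolution")
  }
  g <- tibble::as_tibble(gam) |> dplyr::rename(gam_value = "value")
  h <- tibble::as_tibble(hic) |> dplyr::rename(hic_value = "value")
  joined <- dplyr::inner_join(g, h, by = c("chrom", "bin_a", "bin_b")) |>
    dplyr::mutate(distance = .data$bin_b - .data$bin_a)
  wdf_key <- setNames(wdf$detection_frequency, paste(wdf$chrom, wdf$start))
  wa <- wdf_key[paste(joined$chrom, joined$bin_a)]
  wb <- wdf_key[paste(joined$chrom, joined$bin_b)]
  joined |>
    dplyr::filter(
      .data$distance <= max_distance,
      .data$gam_value >= 0,
      .data$hic_value > 0,
      !is.na(wa) & !is.na(wb),
      wa >= wdf_range[1] & wa <= wdf_range[2],
      wb >= wdf_range[1] & wb <= wdf_range[2]
    ) |>
    dplyr::select("chrom", "bin_a", "bin_b", "distance",
                  "gam_value", "hic_value")
}

#' Distance-stratified z-score transformation
#'
#' Standardizes contact values within each (chromosome, genomic distance)
#' band: `z = (x - band mean) / band sample sd` (n-1 denominator). Bands
#' with fewer than two contacts or zero variance yield missing values.
#' This removes the distance decay so GAM and Hi-C intensities become
#' comparable.
#'
#' @param contacts A tibble with `chrom`, `bin_a`, `bin_b`, `distance` and
#'   the value column named by `value_col`.
#' @param value_col Column to transform.
#' @param pool_chromosomes If `TRUE`, bands pool all chromosomes.
#' @return The input with an added `z_<value_col>` column.
#' @export
zscore_by_distance <- function(contacts, value_col = "value",
                               pool_chromosomes = FALSE) {
  grp <- if (pool_chromosomes) "distance" else c("chrom", "distance")
  z_col <- transform_col_name("z", value_col)
  contacts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(
      !!z_col := {
        x <- .data[[value_col]]
        s <- sd(x)
        if (dplyr::n() < 2 || is.na(s) || s == 0) rep(NA_real_, dplyr::n())
        else (x - mean(x)) / s
      }
    ) |>
    dplyr::ungroup()
}

# "gam_value" -> "z_gam"; plain "value" -> "z"
transform_col_name <- function(prefix, value_col) {
  stub <- sub("_?value$", "", value_col)
  if (stub == "") prefix else paste(prefix, stub, sep = "_")
}

#' Observed-over-expected and rank transforms
#'
#' Alternatives to the z-score for distance normalization:
#' `mode = "obs_exp"` divides by the band mean (missing where the band mean
#' is zero); `mode = "rank"` replaces values with dense ranks within the
#' band, invariant under any monotone rescaling.
#'
#' @inheritParams zscore_by_distance
#' @param mode `"obs_exp"` or `"rank"`.
#' @return The input with an added `oe_<col>` or `rank_<col>` column.
#' @export
alternative_transforms <- function(contacts, value_col = "value",
                                   mode = c("obs_exp", "rank"),
                                   pool_chromosomes = FALSE) {
  mode <- match.arg(mode)
  grp <- if (pool_chromosomes) "distance" else c("chrom", "distance")
  new_col <- transform_col_name(if (mode == "obs_exp") "oe" else "rank", value_col)
  contacts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(
      !!new_col := {
        x <- .data[[value_col]]
        if (mode == "obs_exp") {
          mu <- mean(x)
          if (is.na(mu) || mu == 0) rep(NA_real_, length(x)) else x / mu
        } else {
          dplyr::dense_rank(x)
        }
      }
    ) |>
    dplyr::ungroup()
}

#' Classify differential contacts from fitted delta tails
#'
#' Subtracting Hi-C z-scores from GAM z-scores yields a delta matrix whose
#' per-chromosome distribution is fitted by maximum likelihood (normal for
#' z-score deltas; logistic is appropriate for observed-over-expected
#' deltas). Contacts in the upper tail (delta above the fitted
#' `1 - tail` quantile) are GAM-specific, lower-tail contacts Hi-C-specific.
#'
#' @param contacts A tibble with `z_gam` and `z_hic` columns (see
#'   [zscore_by_distance()]).
#' @param tail Tail fraction (0.05 default; 0.10 supported).
#' @param family `"normal"` or `"logistic"`.
#' @param pool_chromosomes Fit genome-wide instead of per chromosome.
#' @return The input with `delta`, `label` (`"gam_specific"`,
#'   `"hic_specific"` or `"background"`), and per-chromosome attributes
#'   `thresholds` (tibble of fitted cutoffs).
#' @export
delta_and_tails <- function(contacts, tail = 0.05,
                            family = c("normal", "logistic"),
                            pool_chromosomes = FALSE) {
  family <- match.arg(family)
  out <- contacts |>
    dplyr::mutate(delta = .data$z_gam - .data$z_hic)
  grp <- if (pool_chromosomes) character() else "chrom"
  fit_thresholds <- function(d) {
    d <- d[is.finite(d)]
    if (length(d) < 100) abort("need at least 100 finite deltas per fitting unit")
    if (sd(d) == 0) abort("zero-variance deltas cannot be fitted")
    if (family == "normal") {
      # normal MLE in closed form (n-denominator sd)
      mu <- mean(d)
      sig <- sqrt(mean((d - mu)^2))
      q <- qnorm(c(tail, 1 - tail), mu, sig)
    } else {
      fit <- suppressWarnings(fitdistrplus::fitdist(d, "logis"))
      q <- qlogis(c(tail, 1 - tail), fit$estimate[["location"]],
                  fit$estimate[["scale"]])
    }
    tibble::tibble(q_lo = q[1], q_hi = q[2])
  }
  thresholds <- out |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(fit_thresholds(.data$delta), .groups = "drop")
  out <- if (pool_chromosomes) {
    dplyr::cross_join(out, thresholds)
  } else {
    dplyr::left_join(out, thresholds, by = "chrom")
  }
  out <- out |>
    dplyr::mutate(
      label = dplyr::case_when(
        !is.finite(.data$delta) ~ "excluded",
        .data$delta > .data$q_hi ~ "gam_specific",
        .data$delta < .data$q_lo ~ "hic_specific",
        TRUE ~ "background"
      )
    ) |>
    dplyr::select(-"q_lo", -"q_hi")
  attr(out, "thresholds") <- thresholds
  attr(out, "tail") <- tail
  attr(out, "family") <- family
  out
}

#' Strong-and-common contacts
#'
#' Among contacts whose GAM and Hi-C z-scores barely differ
#' (`|delta| < delta_max`), ranks each contact by the weaker of its two
#' z-scores and keeps the strongest `top_fraction` per chromosome — the
#' contacts both methods detect strongly. Ties at the cutoff are broken by
#' (bin_a, bin_b) order for determinism.
#'
#' @param contacts A tibble with `z_gam`, `z_hic`, `delta`.
#' @param delta_max Candidate threshold on `|delta|` (default 1.0).
#' @param top_fraction Fraction kept per chromosome (0.05 or 0.10).
#' @return The candidate subset with `min_z` and logical `strong_common`.
#' @export
strong_and_common <- function(contacts, delta_max = 1.0, top_fraction = 0.10) {
  cand <- contacts |>
    dplyr::filter(is.finite(.data$z_gam), is.finite(.data$z_hic),
                  abs(.data$delta) < delta_max) |>
    dplyr::mutate(min_z = pmin(.data$z_gam, .data$z_hic))
  if (nrow(cand) == 0) abort("no candidates below delta_max")
  cand |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(dplyr::desc(.data$min_z), .data$bin_a, .data$bin_b,
                   .by_group = TRUE) |>
    dplyr::mutate(strong_common = dplyr::row_number() <= round(top_fraction * dplyr::n())) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$bin_a, .data$bin_b)
}

#' Import significant Fit-Hi-C contacts into fixed windows
#'
#' Filters fragment-level records to cis contacts below `max_distance`
#' with `q < q_max`, then assigns each fragment to the window containing
#' its midpoint.
#'
#' @param records A data frame with columns `chrom1`, `start1`, `end1`,
#'   `chrom2`, `start2`, `end2`, `q_value`.
#' @param q_max Significance threshold (default 0.05).
#' @param max_distance Maximum genomic separation (default 4 Mb).
#' @param resolution Window size in bp (default 40000).
#' @return A tibble of binned contacts `chrom`, `bin_a`, `bin_b`, `q_value`.
#' @export
import_fithic_contacts <- function(records, q_max = 0.05, max_distance = 4e6,
                                   resolution = 40000) {
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "q_value")
  if (!all(need %in% names(records))) abort("malformed Fit-Hi-C records")
  records |>
    dplyr::filter(.data$chrom1 == .data$chrom2, .data$q_value < q_max) |>
    dplyr::mutate(
      mid1 = (.data$start1 + .data$end1) / 2,
      mid2 = (.data$start2 + .data$end2) / 2,
      bin_a = (.data$mid1 %/% resolution) * resolution,
      bin_b = (.data$mid2 %/% resolution) * resolution
    ) |>
    dplyr::filter(abs(.data$mid2 - .data$mid1) <= max_distance,
                  .data$bin_a != .data$bin_b) |>
    dplyr::transmute(
      chrom = .data$chrom1,
      bin_a = pmin(.data$bin_a, .data$bin_b),
      bin_b = pmax(.data$bin_a, .data$bin_b),
      q_value = .data$q_value
    )
}

#' GAM-preferred, Hi-C-preferred and common regions
#'
#' Counts, per window, how often it anchors a GAM-specific or
#' Hi-C-specific contact; windows whose absolute count difference exceeds
#' the per-chromosome 90th percentile (linear-interpolation percentile)
#' are labeled by the dominant method. Independently, windows in the top
#' 10% per chromosome by strong-and-common anchor count are labeled
#' common. A window can hold both a preference and a common label; they
#' are reported in separate columns.
#'
#' @param gam_set,hic_set,common_set Contact tibbles (`chrom`, `bin_a`,
#'   `bin_b`) for the three classes.
#' @param windows A tibble of all windows (`chrom`, `start`, `end`).
#' @param pref_quantile Percentile cutoff for preference (default 0.9).
#' @param common_fraction Top fraction for the common label (default 0.10).
#' @return A tibble per window: counts `n_gam_specific`, `n_hic_specific`,
#'   `n_common`, labels `preference` and `common`.
#' @export
preferred_regions <- function(gam_set, hic_set, common_set, windows,
                              pref_quantile = 0.9, common_fraction = 0.10) {
  anchor_counts <- function(set) {
    if (is.null(set) || nrow(set) == 0) {
      return(tibble::tibble(chrom = character(), start = numeric(), n = numeric()))
    }
    dplyr::bind_rows(
      dplyr::transmute(set, chrom = .data$chrom, start = .data$bin_a),
      dplyr::transmute(set, chrom = .data$chrom, start = .data$bin_b)
    ) |>
      dplyr::count(.data$chrom, .data$start)
  }
  add_count <- function(win, set, col) {
    cnt <- anchor_counts(set)
    win <- dplyr::left_join(win, cnt, by = c("chrom", "start"))
    win[[col]] <- dplyr::coalesce(win$n, 0L)
    dplyr::select(win, -"n")
  }
  out <- tibble::as_tibble(windows)[c("chrom", "start", "end")]
  out <- add_count(out, gam_set, "n_gam_specific")
  out <- add_count(out, hic_set, "n_hic_specific")
  out <- add_count(out, common_set, "n_common")
  out |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      abs_diff = abs(.data$n_gam_specific - .data$n_hic_specific),
      pref_cut = quantile(.data$abs_diff, pref_quantile, type = 7),
      preference = dplyr::case_when(
        .data$abs_diff > .data$pref_cut & .data$n_gam_specific > .data$n_hic_specific ~ "gam_preferred",
        .data$abs_diff > .data$pref_cut ~ "hic_preferred",
        TRUE ~ "none"
      ),
      # rank selection: the top fraction of windows by common-anchor count
      common_rank = rank(-.data$n_common, ties.method = "first"),
      common = ifelse(.data$common_rank <= round(common_fraction * dplyr::n()) &
                        .data$n_common > 0, "common", "none")
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"abs_diff", -"pref_cut", -"common_rank")
}
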