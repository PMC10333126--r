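#' @export
tidy.slice_pairs <- function(x, ...) {
  tibble::as_tibble(x)[c("chrom", "bin_a", "bin_b", "distance", "pi_hat",
                         "coseg_ratio_obs", "p_value", "q_value", "significant")]
}

#' @export
glance.slice_pairs <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(
    n_pairs = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    x_np = p$x_np,
    v = p$v,
    t = p$t,
    detection_efficiency = p$detection_efficiency,
    fdr_threshold = p$fdr_threshold
  )
}

#' @export
tidy.slice_triplets <- function(x, ...) {
  tibble::as_tibble(x)[c("chrom", "bin_a", "bin_b", "bin_c", "span",
                         "pi_abc_hat", "ratio_obs", "p_value", "significant")]
}

#' @export
glance.slice_triplets <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(
    n_triplets = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    x_np = p$x_np,
    v = p$v,
    detection_efficiency = p$detection_efficiency
  )
}

#' @export
tidy.rank_pairs_rf <- function(x, ...) x$importance

#' @export
glance.rank_pairs_rf <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$importance), cv_accuracy = x$cv_accuracy)
}

#' @export
print.rank_pairs_rf <- function(x, ...) {
  cat(sprintf("<rank_pairs_rf> %d feature pairs, CV accuracy %.3f\n",
              nrow(x$importance), x$cv_accuracy))
  cat("Top pairs by Gini importance:\n")
  print(utils::head(x$importance, 5))
  invisible(x)
}

#' @export
autoplot.slice_pairs <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_a, .data$bin_b)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$pi_hat)) +
    ggplot2::geom_point(data = dplyr::filter(df, .data$significant),
                        shape = 4, size = 0.8) +
    ggplot2::facet_wrap(~chrom, scales = "free") +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "bin A (bp)", y = "bin B (bp)", fill = "Pi")
}

#' Delta z-score distribution with fitted tails
#'
#' Histogram of delta z-scores with the fitted tail cutoffs used to call
#' GAM-specific and Hi-C-specific contacts.
#'
#' @param classified A [delta_and_tails()] result.
#' @return A ggplot object.
#' @export
plot_delta_tails <- function(classified) {
  thr <- attr(classified, "thresholds")
  ggplot2::ggplot(classified, ggplot2::aes(.data$delta, fill = .data$label)) +
    ggplot2::geom_histogram(bins = 60) +
    ggplot2::geom_vline(data = thr, ggplot2::aes(xintercept = .data$q_lo),
                        linetype = 2) +
    ggplot2::geom_vline(data = thr, ggplot2::aes(xintercept = .data$q_hi),
                        linetype = 2) +
    (if ("chrom" %in% names(thr)) ggplot2::facet_wrap(~chrom) else NULL) +
    ggplot2::labs(x = "delta z-score (GAM - Hi-C)", y = "contacts")
}

#' Boundary-centred signal profile plot
#'
#' @param profile A [boundary_feature_profile()] result.
#' @return A ggplot object.
#' @export
plot_boundary_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$offset / 1e3)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$bg_mean - 2 * .data$bg_sd,
                                      ymax = .data$bg_mean + 2 * .data$bg_sd),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$bg_mean), color = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_signal), color = "firebrick") +
    ggplot2::labs(x = "offset from boundary midpoint (kb)", y = "mean signal")
}
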