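#' Tube-level detection-state probabilities for a locus pair
#'
#' The SLICE pair model. Per nuclear profile, each locus is captured with
#' probability `v` and both together with probability
#' `N2 = Pi * t + (1 - Pi) * u` — the mixture of the interacting (`t`) and
#' non-interacting (`u`) co-capture probabilities under interaction
#' probability `Pi`. A tube pools `x_np` profiles (real-valued under the
#' mean-field approximation for merged datasets), and a detection efficiency
#' thins each captured locus independently, so with `ve = v * eff` and
#' `n2e = N2 * eff^2` the probabilities of a tube detecting neither, exactly
#' one, or both loci are
#' `M0 = (1 - 2 ve + n2e)^X`,
#' `M1 = 2 ((1 - ve)^X - (1 - 2 ve + n2e)^X)`,
#' `M2 = 1 - 2 (1 - ve)^X + (1 - 2 ve + n2e)^X`.
#' They sum to one; at `x_np = 1`, `eff = 1` they reduce to the per-profile
#' probabilities exactly.
#'
#' @param v Single-locus capture probability per nuclear profile.
#' @param u Non-interacting co-capture probability per profile.
#' @param t Interacting co-capture probability per profile.
#' @param pi Interaction probability in `[0, 1]`.
#' @param x_np Nuclear profiles per tube (positive real).
#' @param detection_efficiency Probability a captured locus is observed.
#' @return A one-row tibble with `m0`, `m1`, `m2` and the per-profile `n2`.
#' @export
pair_tube_state_probs <- function(v, u, t, pi, x_np = 1, detection_efficiency = 1) {
  check_prob_chain(v, u, t)
  if (pi < 0 || pi > 1) abort("pi must lie in [0, 1]")
  if (x_np <= 0) abort("x_np must be positive")
  eff <- detection_efficiency
  if (eff <= 0 || eff > 1) abort("detection_efficiency must lie in (0, 1]")
  n2 <- pi * t + (1 - pi) * u
  ve <- v * eff
  n2e <- n2 * eff^2
  miss_both <- 1 - 2 * ve + n2e
  if (miss_both < 0) abort("invalid parameters: 1 - 2 v + N2 < 0")
  m0 <- miss_both^x_np
  miss_one <- (1 - ve)^x_np
  m1 <- 2 * (miss_one - m0)
  m2 <- 1 - 2 * miss_one + m0
  tibble::tibble(m0 = m0, m1 = m1, m2 = m2, n2 = n2)
}

check_prob_chain <- function(v, u, t) {
  if (!(u >= 0 && u <= t + 1e-12 && t <= v + 1e-12 && v <= 1)) {
    abort("need 0 <= u <= t <= v <= 1")
  }
  invisible(TRUE)
}

#' Co-segregation ratio of a tube-state distribution
#'
#' The fraction of non-empty tubes (tubes detecting at least one of the two
#' loci) that detect both: `M2 / (M1 + M2)`. This is the quantity SLICE fits
#' to estimate `Pi`, and it is strictly increasing in `Pi` whenever `t > u`.
#' The literature also prints the complementary form `M1 / (M1 + M2)`;
#' `numerator = "one_locus"` returns it.
#'
#' @param m1,m2 Tube-state probabilities (or counts).
#' @param numerator `"both_loci"` (default) or `"one_locus"`.
#' @return The ratio.
#' @export
cosegregation_ratio <- function(m1, m2, numerator = c("both_loci", "one_locus")) {
  numerator <- match.arg(numerator)
  if (any(m1 + m2 <= 0)) abort("m1 + m2 must be positive")
  if (numerator == "both_loci") m2 / (m1 + m2) else m1 / (m1 + m2)
}

# r(Pi) for fixed nuisance parameters
pair_ratio_at_pi <- function(pi, v, u, t, x_np, eff) {
  st <- pair_tube_state_probs(v, u, t, pi, x_np, eff)
  cosegregation_ratio(st$m1, st$m2)
}

#' Estimate the pairwise interaction probability
#'
#' Inverts the SLICE co-segregation ratio: finds `Pi` in `[0, 1]` whose
#' model ratio `M2 / (M1 + M2)` equals the observed `k2 / (k1 + k2)`
#' (monotone root finding; requires `t > u`). Observed ratios below the
#' `Pi = 0` value clamp to 0 (`boundary = "floor"`); above the `Pi = 1`
#' value clamp to 1 (`boundary = "ceiling"`).
#'
#' @param k1 Number of tubes detecting exactly one locus.
#' @param k2 Number of tubes detecting both loci.
#' @param m Total number of tubes.
#' @inheritParams pair_tube_state_probs
#' @return A one-row tibble: `pi_hat`, `coseg_ratio_obs`, `boundary`
#'   (`"floor"`, `"interior"`, `"ceiling"`, or `"undefined"` when
#'   `k1 + k2 = 0`).
#' @export
estimate_pi <- function(k1, k2, m, v, u, t, x_np = 1, detection_efficiency = 1) {
  if (k1 + k2 == 0) {
    return(tibble::tibble(pi_hat = NA_real_, coseg_ratio_obs = NA_real_,
                          boundary = "undefined"))
  }
  if (t <= u) abort("t must exceed u for Pi to be identifiable")
  r_obs <- k2 / (k1 + k2)
  r0 <- pair_ratio_at_pi(0, v, u, t, x_np, detection_efficiency)
  r1 <- pair_ratio_at_pi(1, v, u, t, x_np, detection_efficiency)
  if (r_obs <= r0) {
    res <- tibble::tibble(pi_hat = 0, coseg_ratio_obs = r_obs,
                          boundary = if (r_obs < r0) "floor" else "interior")
  } else if (r_obs >= r1) {
    res <- tibble::tibble(pi_hat = 1, coseg_ratio_obs = r_obs,
                          boundary = if (r_obs > r1) "ceiling" else "interior")
  } else {
    root <- uniroot(function(p) pair_ratio_at_pi(p, v, u, t, x_np, detection_efficiency) - r_obs,
                    c(0, 1), tol = 1e-10)
    res <- tibble::tibble(pi_hat = root$root, coseg_ratio_obs = r_obs,
                          boundary = "interior")
  }
  res
}

# Exact tail probability of the null co-segregation ratio.
#
# Under the null the m tubes are iid trinomial (m0, m1, m2); conditioning on
# the number of non-empty tubes n = K1 + K2 ~ Binom(m, m1 + m2) makes
# K2 | n ~ Binom(n, m2 / (m1 + m2)), so P(R >= r | non-empty) is an O(m)
# sum of binomial tails — exact enumeration of the full trinomial without
# visiting O(m^2) states.
null_ratio_tail <- function(r_obs, m, m1, m2, mc_cutoff = 50000, seed = 1L) {
  p_ne <- m1 + m2
  if (p_ne <= 0) return(NA_real_)
  rho <- m2 / p_ne
  if (m <= mc_cutoff) {
    n <- seq_len(m)
    w <- dbinom(n, m, p_ne)
    k_min <- ceiling(r_obs * n - 1e-9)
    tail_p <- ifelse(k_min <= 0, 1, pbinom(k_min - 1, n, rho, lower.tail = FALSE))
    denom <- 1 - dbinom(0, m, p_ne)
    if (denom <= 0) return(NA_real_)
    sum(w * tail_p) / denom
  } else {
    with_seed(seed, {
      n <- rbinom(1e5, m, p_ne)
      n <- n[n > 0]
      k <- rbinom(length(n), n, rho)
      mean(k / n >= r_obs - 1e-12)
    })
  }
}

#' Null test for a pairwise contact
#'
#' Tests the observed co-segregation ratio against the SLICE null of
#' non-interacting loci (`Pi = 0`): the null tube states are trinomial with
#' probabilities `pair_tube_state_probs(v, u, t, 0, ...)`, the statistic is
#' `R = K2 / (K1 + K2)` over non-empty tubes, and the p-value is the exact
#' conditional tail `P(R >= r_obs | K1 + K2 > 0)`. A contact is significant
#' when its ratio exceeds the null 95th percentile, which for this discrete
#' distribution is exactly the event `p_value <= alpha`.
#'
#' @inheritParams estimate_pi
#' @param alpha Significance level (default 0.05).
#' @param seed Seed for the Monte-Carlo path used at very large `m`.
#' @return A one-row tibble: `coseg_ratio_obs`, `p_value`, `significant`.
#' @export
pair_null_test <- function(k1, k2, m, v, u, t, x_np = 1, detection_efficiency = 1,
                           alpha = 0.05, seed = 1L) {
  if (m <= 0) abort("m must be positive")
  null_st <- pair_tube_state_probs(v, u, t, 0, x_np, detection_efficiency)
  if (k1 + k2 == 0) {
    return(tibble::tibble(coseg_ratio_obs = NA_real_, p_value = 1, significant = FALSE))
  }
  r_obs <- k2 / (k1 + k2)
  if (r_obs <= 0) {
    return(tibble::tibble(coseg_ratio_obs = r_obs, p_value = 1, significant = FALSE))
  }
  p <- null_ratio_tail(r_obs, m, null_st$m1, null_st$m2, seed = seed)
  tibble::tibble(coseg_ratio_obs = r_obs, p_value = p,
                 significant = !is.na(p) && p <= alpha)
}

#' Benjamini-Hochberg adjustment with a discovery threshold
#'
#' Standard step-up false discovery rate control (via [stats::p.adjust()]),
#' flagging interactions at an FDR threshold of 0.1 by default — the
#' threshold used to call high-confidence pairwise SLICE interactions.
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param q_threshold FDR threshold for the `significant` flag.
#' @return A tibble with `p_value`, `q_value`, `significant`.
#' @export
bh_adjust <- function(p_values, q_threshold = 0.1) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  q <- p.adjust(p_values, method = "BH")
  tibble::tibble(p_value = p_values, q_value = q,
                 significant = !is.na(q) & q <= q_threshold)
}

#' Estimate the per-profile background co-capture probability from data
#'
#' For non-interacting loci the co-capture probability `u(d)` at genomic
#' distance `d` is estimated from the segregation table itself: the
#' tube-level co-detection fraction of every pair at distance `d` is
#' summarised by its median (robust to the interacting minority; `mean`
#' available), then inverted through the mean-field tube model to the
#' per-profile scale when tubes pool several profiles, and clipped to
#' `[0, v]`.
#'
#' @param x A [seg_table].
#' @param v Single-locus capture probability per profile (from geometry, or
#'   calibrated from the table's detection frequency).
#' @param x_np Nuclear profiles per tube.
#' @param detection_efficiency Observation thinning per captured locus.
#' @param max_distance Band limit in bp.
#' @param min_pairs Minimum pairs per distance required (default 30).
#' @param center `"median"` or `"mean"`.
#' @return A tibble with `distance`, `n_pairs`, `coseg_tube` (tube-level
#'   median co-detection) and `u` (per-profile background co-capture).
#' @export
background_coseg_from_table <- function(x, v, x_np = 1, detection_efficiency = 1,
                                        max_distance = 4e6, min_pairs = 30,
                                        center = c("median", "mean")) {
  center <- match.arg(center)
  res <- seg_resolution(x)
  win <- seg_windows(x)
  m <- seg_matrix(x)
  n_samp <- ncol(m)
  per_chrom <- lapply(split(seq_len(nrow(win)), win$chrom), function(idx) {
    sub <- m[idx, , drop = FALSE]
    co <- tcrossprod(sub) / n_samp
    starts <- win$start[idx]
    pairs <- which(upper.tri(co), arr.ind = TRUE)
    d <- starts[pairs[, 2]] - starts[pairs[, 1]]
    keep <- d > 0 & d <= max_distance
    tibble::tibble(distance = d[keep], coseg = co[pairs][keep])
  })
  cent_fun <- if (center == "median") median else mean
  out <- dplyr::bind_rows(per_chrom) |>
    dplyr::group_by(.data$distance) |>
    dplyr::summarise(n_pairs = dplyr::n(), coseg_tube = cent_fun(.data$coseg)) |>
    dplyr::filter(.data$n_pairs >= min_pairs)
  if (nrow(out) == 0) abort("too few pairs at every distance")
  out$u <- vapply(out$coseg_tube, invert_tube_coseg, numeric(1),
                  v = v, x_np = x_np, eff = detection_efficiency)
  out
}

# Solve M2(u) = f for the per-profile background u, clipped to [0, v].
invert_tube_coseg <- function(f, v, x_np, eff) {
  g <- function(u) {
    ve <- v * eff
    m0 <- (1 - 2 * ve + u * eff^2)^x_np
    1 - 2 * (1 - ve)^x_np + m0 - f
  }
  if (g(0) >= 0) return(0)
  if (g(v) <= 0) return(v)
  uniroot(g, c(0, v), tol = 1e-12)$root
}
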