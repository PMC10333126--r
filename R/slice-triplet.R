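#' Tube-level detection-state probabilities for a locus triplet
#'
#' Extends the SLICE pair model to three loci. Per nuclear profile the
#' three single-locus capture probabilities are `v`, the three pairwise
#' co-captures `n2` (each a mixture of `t` and `u` through its pairwise
#' `Pi`), and the all-three co-capture
#' `N3 = Pi_ABC * t3 + (1 - Pi_ABC) * u3`. Inclusion-exclusion gives the
#' per-profile probability of missing any locus subset; raising these to
#' the (real) `x_np` exponent gives the tube-level miss probabilities, and
#' a Moebius inversion over subsets yields the eight tube detection-state
#' probabilities. Detection efficiency thins each captured locus
#' independently (`v -> v eff`, `n2 -> n2 eff^2`, `n3 -> n3 eff^3`).
#'
#' @param v Single-locus capture probability per profile.
#' @param n2 Length-3 vector of pairwise co-capture probabilities
#'   (AB, AC, BC) per profile.
#' @param n3 All-three co-capture probability per profile.
#' @param x_np Nuclear profiles per tube (positive real).
#' @param detection_efficiency Observation thinning per captured locus.
#' @return A tibble with one row per detection state (`state` is e.g.
#'   `"AB"`, `""` for empty, `"ABC"`) and its probability `prob`; the
#'   probabilities sum to one.
#' @export
triplet_tube_state_probs <- function(v, n2, n3, x_np = 1, detection_efficiency = 1) {
  if (length(n2) != 3) abort("n2 must hold the three pairwise probabilities")
  eff <- detection_efficiency
  ve <- v * eff
  n2e <- n2 * eff^2
  n3e <- n3 * eff^3
  loci <- c("A", "B", "C")
  pair_idx <- list(AB = 1, AC = 2, BC = 3)
  # per-profile P(miss all loci in W), by inclusion-exclusion over captures
  miss_np <- function(W) {
    k <- length(W)
    if (k == 0) return(1)
    if (k == 1) return(1 - ve)
    if (k == 2) {
      key <- paste(sort(W), collapse = "")
      return(1 - 2 * ve + n2e[pair_idx[[key]]])
    }
    1 - 3 * ve + sum(n2e) - n3e
  }
  key_of <- function(W) if (length(W) == 0) "(empty)" else paste(sort(W), collapse = "")
  subsets <- lapply(0:7, function(b) loci[bitwAnd(b, c(1, 2, 4)) > 0])
  q <- vapply(subsets, function(W) {
    p <- miss_np(W)
    if (p < 0) abort("invalid parameters: negative miss probability")
    p^x_np
  }, numeric(1))
  names(q) <- vapply(subsets, key_of, character(1))
  # P(exactly D detected) = sum_{U subset D} (-1)^|U| Q(D^c union U)
  state_prob <- vapply(0:7, function(bd) {
    detected <- loci[bitwAnd(bd, c(1, 2, 4)) > 0]
    absent <- setdiff(loci, detected)
    subs <- subsets[vapply(subsets, function(W) all(W %in% detected), logical(1))]
    sum(vapply(subs, function(U) {
      (-1)^length(U) * q[[key_of(union(absent, U))]]
    }, numeric(1)))
  }, numeric(1))
  tibble::tibble(
    state = vapply(0:7, function(bd) paste(loci[bitwAnd(bd, c(1, 2, 4)) > 0],
                                           collapse = ""), character(1)),
    prob = state_prob
  )
}

# triple ratio r3(Pi_ABC): fraction of tubes detecting any of the three
# that detect all three
triplet_ratio_at_pi <- function(pi_abc, v, n2, t3, u3, x_np, eff) {
  n3 <- pi_abc * t3 + (1 - pi_abc) * u3
  st <- triplet_tube_state_probs(v, n2, n3, x_np, eff)
  p_all <- st$prob[st$state == "ABC"]
  p_empty <- st$prob[st$state == ""]
  p_all / (1 - p_empty)
}

#' Estimate the triplet interaction probability
#'
#' Fits `Pi_ABC` by monotone inversion of the triple co-segregation ratio:
#' the fraction of non-empty tubes (tubes detecting at least one of the
#' three loci) that detect all three. The interacting triple co-capture
#' `t3` treats the three loci as mutually co-located within the slab
#' overlap, and the background `u3` is the distance-matched empirical
#' triple co-capture. Significance is the exact conditional binomial tail
#' under the `Pi_ABC = 0` null, as in [pair_null_test()].
#'
#' @param k_all Tubes detecting all three loci.
#' @param k_any Tubes detecting at least one of the three.
#' @param m Total tubes.
#' @param v Single-locus capture probability per profile.
#' @param n2 Length-3 vector of pairwise co-capture probabilities per
#'   profile (from the pairwise fits: `pi_ij * t + (1 - pi_ij) * u`).
#' @param t3 Interacting triple co-capture probability per profile.
#' @param u3 Background triple co-capture probability per profile.
#' @param x_np Nuclear profiles per tube.
#' @param detection_efficiency Observation thinning.
#' @param alpha Significance level.
#' @return A one-row tibble: `pi_abc_hat`, `ratio_obs`, `p_value`,
#'   `significant`, `boundary`.
#' @export
estimate_pi_abc <- function(k_all, k_any, m, v, n2, t3, u3, x_np = 1,
                            detection_efficiency = 1, alpha = 0.05) {
  if (t3 <= u3) abort("t3 must exceed u3 for Pi_ABC to be identifiable")
  if (k_any == 0) {
    return(tibble::tibble(pi_abc_hat = NA_real_, ratio_obs = NA_real_,
                          p_value = 1, significant = FALSE, boundary = "undefined"))
  }
  r_obs <- k_all / k_any
  eff <- detection_efficiency
  # all-three capture implies each pairwise capture, so n3 <= min(n2):
  # Pi_ABC is only identifiable up to the point where n3 reaches that bound
  pi_max <- min(1, (min(n2) - u3) / (t3 - u3))
  if (pi_max <= 0) {
    return(tibble::tibble(pi_abc_hat = NA_real_, ratio_obs = r_obs,
                          p_value = NA_real_, significant = FALSE,
                          boundary = "unidentifiable"))
  }
  r0 <- triplet_ratio_at_pi(0, v, n2, t3, u3, x_np, eff)
  r1 <- triplet_ratio_at_pi(pi_max, v, n2, t3, u3, x_np, eff)
  if (r_obs <= r0) {
    pi_hat <- 0; boundary <- if (r_obs < r0) "floor" else "interior"
  } else if (r_obs >= r1) {
    pi_hat <- pi_max; boundary <- if (r_obs > r1) "ceiling" else "interior"
  } else {
    pi_hat <- uniroot(function(p) triplet_ratio_at_pi(p, v, n2, t3, u3, x_np, eff) - r_obs,
                      c(0, pi_max), tol = 1e-10)$root
    boundary <- "interior"
  }
  # null: Pi_ABC = 0; K_all | K_any = n ~ Binom(n, p_all / p_nonempty)
  st0 <- triplet_tube_state_probs(v, n2, u3, x_np, eff)
  p_all0 <- st0$prob[st0$state == "ABC"]
  p_ne0 <- 1 - st0$prob[st0$state == ""]
  p <- if (r_obs <= 0) 1 else {
    null_ratio_tail(r_obs, m, m1 = p_ne0 - p_all0, m2 = p_all0)
  }
  tibble::tibble(pi_abc_hat = pi_hat, ratio_obs = r_obs, p_value = p,
                 significant = !is.na(p) && p <= alpha, boundary = boundary)
}

#' Empirical triple background co-capture from a segregation table
#'
#' Median tube-level fraction of samples detecting all three windows,
#' across window triples whose pairwise distance geometry matches the
#' query (stratified by the triplet span), inverted to the per-profile
#' scale through the mean-field exponent.
#'
#' @param x A [seg_table].
#' @param v Single-locus capture probability per profile.
#' @param x_np Nuclear profiles per tube.
#' @param detection_efficiency Observation thinning.
#' @param max_span Maximum span (C - A) in bp.
#' @param min_triples Minimum triples per span stratum (default 30).
#' @return A tibble with `span`, `n_triples`, `coseg_tube`, `u3`.
#' @export
background_triple_coseg <- function(x, v, x_np = 1, detection_efficiency = 1,
                                    max_span = 4e6, min_triples = 30) {
  res <- seg_resolution(x)
  win <- seg_windows(x)
  m <- seg_matrix(x)
  n_samp <- ncol(m)
  rows <- lapply(split(seq_len(nrow(win)), win$chrom), function(idx) {
    n <- length(idx)
    if (n < 3) return(NULL)
    starts <- win$start[idx]
    combos <- utils::combn(n, 3)
    span <- starts[combos[3, ]] - starts[combos[1, ]]
    keep <- span <= max_span
    combos <- combos[, keep, drop = FALSE]
    span <- span[keep]
    sub <- m[idx, , drop = FALSE]
    co3 <- vapply(seq_len(ncol(combos)), function(j) {
      trip <- combos[, j]
      sum(sub[trip[1], ] & sub[trip[2], ] & sub[trip[3], ]) / n_samp
    }, numeric(1))
    tibble::tibble(span = span, coseg = co3)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$span) |>
    dplyr::summarise(n_triples = dplyr::n(), coseg_tube = median(.data$coseg)) |>
    dplyr::filter(.data$n_triples >= min_triples)
  if (nrow(out) == 0) abort("too few triples at every span")
  out$u3 <- vapply(out$coseg_tube, invert_tube_triple_coseg, numeric(1),
                   v = v, x_np = x_np, eff = detection_efficiency)
  out
}

# Solve tube-level all-three probability = f for the per-profile n3,
# holding pairwise co-captures at the independence value v^2.
invert_tube_triple_coseg <- function(f, v, x_np, eff) {
  g <- function(n3) {
    st <- triplet_tube_state_probs(v, rep(v^2, 3), n3, x_np, eff)
    st$prob[st$state == "ABC"] - f
  }
  if (g(0) >= 0) return(0)
  if (g(v) <= 0) return(v)
  uniroot(g, c(0, v), tol = 1e-12)$root
}
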