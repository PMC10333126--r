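#' Minimum number of tubes for a target interaction probability
#'
#' Experimental-design calculator for GAM: the smallest number of tubes
#' `m*` such that the SLICE pair null test (at level `alpha`) detects an
#' interaction of probability `pi_target` with at least the requested
#' power. For each candidate `m` the rejection region is derived from the
#' exact conditional null distribution of the co-segregation ratio and the
#' power evaluated under the exact alternative trinomial; `m*` is found by
#' bisection (power is monotone non-decreasing in `m`).
#'
#' The background co-capture probability defaults to the independent-locus
#' floor `u = v^2`, the regime of well-separated loci (genomic distances
#' beyond ~100 kb) in the absence of a segregation table to calibrate from;
#' pass `u` explicitly to design against a data-derived background.
#'
#' @param pi_target Interaction probability to detect (`> 0`).
#' @param geometry A [nuclear_geometry]; `resolution` may be mapped into it
#'   through `locus_size`.
#' @param x_np Nuclear profiles per tube.
#' @param alpha Significance level (default 0.05).
#' @param power Target power (default 0.8).
#' @param u Background co-capture per profile; default `v^2`.
#' @param delta Physical separation of interacting loci (um), default `h/2`.
#' @param detection_efficiency Observation thinning per captured locus.
#' @param m_max Search ceiling (default 20000).
#' @return A one-row tibble: `m_star`, `power_at_m_star`, plus the model
#'   probabilities `v`, `u`, `t` used.
#' @export
design_m_star <- function(pi_target, geometry = nuclear_geometry(), x_np = 1,
                          alpha = 0.05, power = 0.8, u = NULL,
                          delta = geometry$h / 2, detection_efficiency = 1,
                          m_max = 20000) {
  if (pi_target <= 0 || pi_target > 1) abort("pi_target must lie in (0, 1]")
  if (power <= 0 || power >= 1) abort("power must lie in (0, 1)")
  v <- single_capture_prob(geometry)
  t <- interacting_coseg_prob(geometry, delta)
  u <- u %||% v^2
  if (t <= u) abort("power unreachable: t <= u")
  pow_fun <- function(m) design_power(m, pi_target, v, u, t, x_np,
                                      detection_efficiency, alpha)
  if (pow_fun(m_max) < power) {
    abort(sprintf("power %.2f unreachable within m_max = %d tubes", power, m_max))
  }
  lo <- 1; hi <- 1
  while (pow_fun(hi) < power) {
    lo <- hi
    hi <- min(2 * hi, m_max)
  }
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (pow_fun(mid) >= power) hi <- mid else lo <- mid
  }
  tibble::tibble(m_star = as.integer(hi), power_at_m_star = pow_fun(hi),
                 v = v, u = u, t = t)
}

# Exact power of the conditional ratio test at m tubes.
#
# Null and alternative tube states are trinomial; conditioning on the number
# of non-empty tubes n gives K2 | n ~ Binom(n, rho). The test rejects when
# the null tail P(R >= k/n) <= alpha; for each n the critical count k*(n) is
# found by binary search over the (monotone) null tail, and power sums the
# alternative binomial tails over n.
design_power <- function(m, pi_target, v, u, t, x_np, eff, alpha) {
  null_st <- pair_tube_state_probs(v, u, t, 0, x_np, eff)
  alt_st <- pair_tube_state_probs(v, u, t, pi_target, x_np, eff)
  p_ne0 <- null_st$m1 + null_st$m2
  rho0 <- null_st$m2 / p_ne0
  p_ne1 <- alt_st$m1 + alt_st$m2
  rho1 <- alt_st$m2 / p_ne1
  nn <- seq_len(m)
  w0 <- dbinom(nn, m, p_ne0)
  denom <- 1 - dbinom(0, m, p_ne0)
  # null tail of R at threshold r, exact in O(m)
  tail0 <- function(r) {
    k_min <- ceiling(r * nn - 1e-9)
    tp <- ifelse(k_min <= 0, 1, pbinom(k_min - 1, nn, rho0, lower.tail = FALSE))
    sum(w0 * tp) / denom
  }
  # tail0 is non-increasing in r, so the rejection region is a single ratio
  # threshold r*: bisect it once, then the per-n critical counts follow.
  lo <- 0; hi <- 1 + 1 / m
  if (tail0(hi) > alpha) return(0)  # even R = 1 not significant
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (tail0(mid) <= alpha) hi <- mid else lo <- mid
  }
  r_star <- hi
  k_star <- pmax(ceiling(r_star * nn - 1e-9), 1L)
  w1 <- dbinom(nn, m, p_ne1)
  rej <- ifelse(k_star > nn, 0, pbinom(k_star - 1, nn, rho1, lower.tail = FALSE))
  # tubes with no non-empty draw never reject
  sum(w1 * rej)
}

#' Design table over multiplexing levels
#'
#' Convenience sweep of [design_m_star()] over several `x_np` values,
#' returning one row per level — the table behind choosing how many nuclear
#' profiles to pool per tube.
#'
#' @inheritParams design_m_star
#' @param x_np Vector of multiplexing levels.
#' @return A tibble with one row per `x_np`.
#' @export
design_table <- function(pi_target, geometry = nuclear_geometry(),
                         x_np = c(1, 2, 3, 5, 10), alpha = 0.05, power = 0.8,
                         u = NULL, detection_efficiency = 1) {
  purrr::map_dfr(x_np, function(X) {
    dplyr::bind_cols(tibble::tibble(x_np = X),
                     design_m_star(pi_target, geometry, X, alpha, power, u,
                                   detection_efficiency = detection_efficiency))
  })
}
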