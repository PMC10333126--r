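test_that("slab capture probability matches the closed form and its limits", {
  g <- nuclear_geometry(radius = 4.5, h = 0.22)
  expect_equal(single_capture_prob(g), 0.22 / 9.22, tolerance = 1e-12)
  expect_lt(single_capture_prob(nuclear_geometry(4.5, 1e-9)), 1e-9)
  # finite locus size widens the capture window
  gd <- nuclear_geometry(4.5, 0.22, locus_size = 0.1)
  expect_equal(single_capture_prob(gd), 0.32 / 9.22, tolerance = 1e-12)
  # ellipsoid path reduces to the sphere form at epsilon = 1 + tiny
  ge <- nuclear_geometry(4.5, 0.22, epsilon = 1 + 1e-9)
  expect_equal(single_capture_prob(ge), 0.22 / 9.22, tolerance = 1e-6)
  # a flattened nucleus has a larger mean extent penalty on capture
  gf <- nuclear_geometry(4.5, 0.22, epsilon = 0.5)
  expect_true(is.finite(single_capture_prob(gf)))
})

test_that("capture probability agrees with a Monte-Carlo slicing oracle", {
  g <- nuclear_geometry(4.5, 0.22)
  withr::with_seed(31, {
    n <- 4e5
    pts <- matrix(runif(3 * n, -4.5, 4.5), ncol = 3)
    keep <- rowSums((pts / 4.5)^2) <= 1
    z <- pts[keep, 3]
    off <- runif(sum(keep), -4.5 - 0.11, 4.5 + 0.11)
    v_mc <- mean(abs(z - off) <= 0.11)
    se <- sqrt(v_mc * (1 - v_mc) / sum(keep))
    expect_lt(abs(single_capture_prob(g) - v_mc), 3 * se)
  })
})

test_that("interacting co-capture decreases in separation with exact endpoints", {
  g <- nuclear_geometry(4.5, 0.22)
  v <- single_capture_prob(g)
  expect_equal(interacting_coseg_prob(g, 0), v, tolerance = 1e-12)
  expect_equal(interacting_coseg_prob(g, 0.22 - 1e-12), v / 2, tolerance = 1e-6)
  grid <- vapply(c(0, 0.25, 0.5, 0.75) * 0.22, interacting_coseg_prob,
                 numeric(1), geometry = g)
  expect_true(all(diff(grid) < 0))
  expect_error(interacting_coseg_prob(g, 0.22), "delta")
})

test_that("tube-state probabilities follow the closed form and conserve mass", {
  st <- pair_tube_state_probs(v = 0.05, u = 0.003, t = 0.04, pi = 0.3, x_np = 1)
  # N2 = 0.3 * 0.04 + 0.7 * 0.003 = 0.0141;
  # M0 = 1 - 0.1 + 0.0141, M1 = 2 (0.95 - M0), M2 = N2
  expect_equal(st$n2, 0.0141, tolerance = 1e-12)
  expect_equal(st$m0, 0.9141, tolerance = 1e-12)
  expect_equal(st$m1, 0.0718, tolerance = 1e-12)
  expect_equal(st$m2, 0.0141, tolerance = 1e-12)

  st3 <- pair_tube_state_probs(0.05, 0.003, 0.04, 0.3, x_np = 3)
  expect_equal(st3$m0, 0.9141^3, tolerance = 1e-12)
  expect_equal(st3$m1, 2 * (0.95^3 - 0.9141^3), tolerance = 1e-12)
  expect_equal(st3$m2, 1 - 2 * 0.95^3 + 0.9141^3, tolerance = 1e-12)

  withr::with_seed(8, {
    for (i in 1:25) {
      v <- runif(1, 0.01, 0.3)
      u <- runif(1, 0, v^2)
      t <- runif(1, u, v)
      pi <- runif(1)
      X <- runif(1, 0.5, 5)
      eff <- runif(1, 0.3, 1)
      s <- pair_tube_state_probs(v, u, t, pi, X, eff)
      expect_equal(s$m0 + s$m1 + s$m2, 1, tolerance = 1e-12)
      expect_true(all(unlist(s[c("m0", "m1", "m2")]) >= -1e-15))
    }
  })
  expect_error(pair_tube_state_probs(0.05, 0.04, 0.003, 0.3), "u <= t")
})

test_that("tube-state probabilities match the state-level sampler", {
  m <- 1e5
  draws <- simulate_state_level(0.05, 0.003, 0.04, 0.3, m, x_np = 3, seed = 14)
  st <- pair_tube_state_probs(0.05, 0.003, 0.04, 0.3, 3)
  for (s in 1:3) {
    p <- unlist(st[c("m0", "m1", "m2")])[s]
    k <- unlist(draws)[s]
    se <- sqrt(p * (1 - p) / m)
    expect_lt(abs(k / m - p), 4 * se)
  }
})

test_that("co-segregation ratio is the both-loci fraction and monotone in Pi", {
  expect_equal(cosegregation_ratio(0.1, 0), 0)
  st <- pair_tube_state_probs(0.05, 0.003, 0.04, 0.3, 1)
  expect_equal(cosegregation_ratio(st$m1, st$m2), 0.0141 / (0.0718 + 0.0141),
               tolerance = 1e-12)
  expect_equal(cosegregation_ratio(st$m1, st$m2, "one_locus"),
               0.0718 / (0.0718 + 0.0141), tolerance = 1e-12)
  rats <- vapply(seq(0, 1, 0.1), function(p) {
    s <- pair_tube_state_probs(0.05, 0.003, 0.04, p, 3)
    cosegregation_ratio(s$m1, s$m2)
  }, 1)
  expect_true(all(diff(rats) > 0))
  expect_error(cosegregation_ratio(0, 0), "positive")
})

test_that("estimate_pi inverts the forward model exactly on noiseless input", {
  for (pi in c(0.05, 0.3, 0.62, 0.97)) {
    st <- pair_tube_state_probs(0.05, 0.003, 0.04, pi, 2.5, 0.9)
    big <- 1e9
    est <- estimate_pi(round(big * st$m1), round(big * st$m2), big,
                       0.05, 0.003, 0.04, 2.5, 0.9)
    expect_lt(abs(est$pi_hat - pi), 1e-6)
  }
  st0 <- pair_tube_state_probs(0.05, 0.003, 0.04, 0, 3)
  r0 <- st0$m2 / (st0$m1 + st0$m2)
  est0 <- estimate_pi(round(1e6 * (1 - r0)), round(1e6 * r0), 1e6,
                      0.05, 0.003, 0.04, 3)
  expect_equal(est0$pi_hat, 0, tolerance = 1e-4)
  sat <- estimate_pi(2, 18, 100, 0.05, 0.003, 0.04, 1)
  expect_equal(sat$pi_hat, 1)
  expect_equal(sat$boundary, "ceiling")
  expect_equal(estimate_pi(0, 0, 100, 0.05, 0.003, 0.04, 1)$boundary, "undefined")
})

test_that("estimate_pi recovers planted interaction probabilities", {
  ks <- simulate_state_level(0.05, 0.003, 0.04, 0.4, 5000, x_np = 3, seed = 3)
  est <- estimate_pi(ks$k1, ks$k2, 5000, 0.05, 0.003, 0.04, 3)
  expect_lt(abs(est$pi_hat - 0.4), 0.05)

  pis <- rep(c(0, 0.2, 0.4, 0.6, 0.8), each = 10)
  err <- vapply(seq_along(pis), function(i) {
    kk <- simulate_state_level(0.05, 0.003, 0.04, pis[i], 5000, 3, seed = 100 + i)
    abs(estimate_pi(kk$k1, kk$k2, 5000, 0.05, 0.003, 0.04, 3)$pi_hat - pis[i])
  }, 1)
  expect_lte(mean(err), 0.05)
})

test_that("null test p-values match brute-force trinomial enumeration", {
  # m = 10, (M0, M1, M2) = (0.8, 0.15, 0.05): enumerate all (K1, K2)
  m <- 10; m0 <- 0.8; m1 <- 0.15; m2 <- 0.05
  grid <- expand.grid(k1 = 0:m, k2 = 0:m)
  grid <- grid[grid$k1 + grid$k2 <= m, ]
  grid$p <- with(grid, exp(lgamma(m + 1) - lgamma(k1 + 1) - lgamma(k2 + 1) -
                             lgamma(m - k1 - k2 + 1)) *
                   m1^k1 * m2^k2 * m0^(m - k1 - k2))
  ne <- grid$k1 + grid$k2 > 0
  brute_tail <- function(r) {
    sum(grid$p[ne & grid$k2 / (grid$k1 + grid$k2) >= r - 1e-12]) / sum(grid$p[ne])
  }
  # parameters reproducing these tube states at x_np = 1: v, u with
  # 1 - 2v + u = 0.8, u = 0.05 -> v = 0.125
  cases <- list(c(k1 = 4, k2 = 1), c(k1 = 2, k2 = 2), c(k1 = 0, k2 = 3))
  for (kc in cases) {
    r <- kc["k2"] / sum(kc)
    res <- pair_null_test(kc["k1"], kc["k2"], m, v = 0.125, u = 0.05, t = 0.1,
                          x_np = 1)
    expect_equal(res$p_value, brute_tail(r), tolerance = 1e-10)
  }
  expect_equal(pair_null_test(5, 0, 10, 0.125, 0.05, 0.1, 1)$p_value, 1)
})

test_that("null test maintains its type-I error at alpha = 0.05", {
  st <- pair_tube_state_probs(0.05, 0.003, 0.04, 0, 3)
  withr::with_seed(11, {
    m <- 1000
    k <- rmultinom(2000, m, c(st$m0, st$m1, st$m2))
    rej <- vapply(1:2000, function(i) {
      pair_null_test(k[2, i], k[3, i], m, 0.05, 0.003, 0.04, 3)$significant
    }, logical(1))
    expect_gte(mean(rej), 0.035)
    expect_lte(mean(rej), 0.065)
  })
})

test_that("BH adjustment matches the step-up definition", {
  res <- bh_adjust(c(0.01, 0.02, 0.30, 0.65), q_threshold = 0.1)
  expect_equal(res$q_value, c(0.04, 0.04, 0.40, 0.65))
  expect_equal(res$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(bh_adjust(0.37)$q_value, 0.37)
  expect_false(any(bh_adjust(rep(1, 5))$significant))
  # brute-force BH: q_i = min over j with p_j >= p_i of p_j * n / rank_j
  withr::with_seed(21, {
    p <- runif(40)
    n <- length(p)
    o <- order(p)
    brute <- numeric(n)
    qs <- p[o] * n / seq_len(n)
    brute[o] <- rev(cummin(rev(qs)))
    expect_equal(bh_adjust(p)$q_value, pmin(brute, 1))
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("effective NP count is the tube-weighted batch mean", {
  expect_equal(effective_nps(tubes = c(481, 249), nps = c(1, 3)), 1228 / 730)
  expect_equal(effective_nps(tubes = 57, nps = 4), 4)
  expect_equal(effective_nps(tubes = c(10, 10), nps = c(2, 2)), 2)
  expect_error(effective_nps(tubes = numeric(0), nps = numeric(0)), "no batches")
})

test_that("background co-capture is recovered from independent columns", {
  # independent Bernoulli(v) columns: true per-profile u = v^2
  st <- random_seg_table(50, 5000, p = 0.05, seed = 17)
  bg <- background_coseg_from_table(st, v = 0.05, x_np = 1, max_distance = 49 * 40000)
  expect_lt(abs(bg$u[bg$distance == 40000] - 0.0025), 5e-4)
  # never exceeds the marginal co-detection bound
  expect_true(all(bg$u <= 0.05 + 1e-12))
  expect_error(background_coseg_from_table(st, 0.05, min_pairs = 1e6), "too few")
})

test_that("X_NP = 1 reduces tube formulas to per-profile formulas", {
  s <- pair_tube_state_probs(0.07, 0.004, 0.05, 0.4, x_np = 1)
  n2 <- 0.4 * 0.05 + 0.6 * 0.004
  expect_equal(s$m2, n2, tolerance = 1e-14)
  expect_equal(s$m1, 2 * (0.07 + 0.07) / 2 - 2 * n2, tolerance = 1e-12)
  expect_equal(s$m0, 1 - 2 * 0.07 + n2, tolerance = 1e-14)
})
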