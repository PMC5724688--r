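kk <- kinetic_params()

test_that("daily carbon integrates the diurnal course correctly", {
  # linear-regime closed form: A = phi * Q for 10 h
  resp <- light_response(1000, 0.05, 0.999, 0)
  hours <- seq(0.25, 9.75, by = 0.5)
  const <- data.frame(hour = hours, ppfd = 100)
  expect_equal(daily_carbon(resp, const), 0.05 * 100 * 36000 * 1e-6,
               tolerance = 1e-3)
  # all-dark day: respiration only
  dark <- data.frame(hour = seq(0.25, 23.75, 0.5), ppfd = 0)
  resp2 <- light_response(25, 0.055, 0.8, 1.2)
  expect_equal(daily_carbon(resp2, dark), -1.2 * 86400 * 1e-6)
  # half-sine course vs fine-step quadrature
  resp3 <- light_response(25, 0.055, 0.8, 1.0)
  coarse <- daily_carbon(resp3, half_sine_course(step = 0.5))
  fine <- daily_carbon(resp3, half_sine_course(step = 0.005))
  expect_equal(coarse, fine, tolerance = 3e-3)  # midpoint rule at 0.5 h
  expect_error(daily_carbon(resp3, data.frame(hour = numeric(),
                                              ppfd = numeric())), "empty")
})

test_that("the P_max/phi frontier trades off monotonically at fixed N", {
  rel <- cached_relations()
  fr <- pmax_phi_frontier(0.85, rel, n_points = 40)
  expect_true(all(diff(fr$p_max) > 0))
  expect_true(all(diff(fr$phi) < 0))
  expect_true(all(abs(fr$n_total - 0.85) < 1e-6))
  # boundary: the most capacity-heavy point has max p_max, min phi
  expect_equal(which.max(fr$p_max), nrow(fr))
  expect_equal(which.min(fr$phi), nrow(fr))
  # doubling the budget raises p_max at matched allocation split
  fr2 <- pmax_phi_frontier(1.7, rel, n_points = 40)
  shared <- seq_len(min(nrow(fr), nrow(fr2)))
  expect_true(all(fr2$p_max[shared] >= fr$p_max[shared]))
})

test_that("the acclimation optimum matches brute force and acclimation theory", {
  rel <- cached_relations()
  lo <- half_sine_course(peak = 200)
  hi <- half_sine_course(peak = 2000)
  a_lo <- optimize_acclimation(0.85, lo, rel, grid_size = 60)
  a_hi <- optimize_acclimation(0.85, hi, rel, grid_size = 60)
  # low growth light shifts nitrogen toward light capture
  expect_gt(a_lo$phi_opt, a_hi$phi_opt)
  expect_lt(a_lo$p_max_opt, a_hi$p_max_opt)
  # constant saturating light drives the optimum to the capacity boundary
  sat <- data.frame(hour = seq(0.25, 23.75, 0.5), ppfd = 2500)
  a_sat <- optimize_acclimation(0.85, sat, rel, grid_size = 60)
  fr <- pmax_phi_frontier(0.85, rel, n_points = 60)
  expect_equal(a_sat$p_max_opt, max(fr$p_max), tolerance = 1e-9)
  # coarse grid lands within one coarse cell of a fine brute-force search
  coarse <- optimize_acclimation(0.85, hi, rel, grid_size = 50)
  fine <- optimize_acclimation(0.85, hi, rel, grid_size = 2000)
  cell <- diff(range(0.05, 0.95)) / 49
  expect_lt(abs(coarse$x_opt - fine$x_opt), cell + 1e-9)
  # the chosen point is never beaten on its own frontier
  expect_gte(coarse$daily_carbon + 1e-12,
             max(coarse$frontier$daily_carbon))
})

test_that("nitrogen reallocation honours both strategies", {
  ref <- reference_pools(kk)
  target <- 0.4 * chl_of_pools(ref, kk)
  lhc <- reallocate_nitrogen(ref, target, "lhc_only", kk)
  expect_equal(lhc$rubisco, ref$rubisco)
  expect_equal(lhc$ce, ref$ce)
  expect_equal(lhc$etcf, ref$etcf)
  expect_equal(lhc$psii, ref$psii)
  expect_lt(nitrogen_of_pools(lhc, kk)$total,
            nitrogen_of_pools(ref, kk)$total)

  con <- reallocate_nitrogen(ref, target, "constant_total_n", kk)
  expect_equal(nitrogen_of_pools(con, kk)$total,
               nitrogen_of_pools(ref, kk)$total, tolerance = 1e-9)
  # all non-LHC pools grow by one common factor
  factors <- c(con$rubisco / ref$rubisco, con$ce / ref$ce,
               con$etcf / ref$etcf, con$psii / ref$psii, con$psi / ref$psi)
  expect_lt(diff(range(factors)), 1e-12)
  expect_gt(factors[1], 1)
})
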