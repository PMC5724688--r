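kk <- kinetic_params()
ref <- reference_pools(kk)
q_grid <- seq(0, 2000, by = 100)

test_that("vmax is the kcat * concentration product", {
  expect_equal(vmax(3.5, 20), 70)
  expect_equal(vmax(3.5, 0), 0)
  set.seed(6)
  k <- runif(20, 0, 10); c_ <- runif(20, 0, 50)
  expect_equal(vmax(k, c_), k * c_)
})

test_that("excitation partition is a proper partition with Fig-3 shape", {
  op <- optics_from_chl(494.7)
  q <- c(0, 10, 50, 200, 500, 1000, 1500, 2000)
  pa <- psii_partition(q, op, ref, kk)
  expect_equal(pa$f_photochemistry + pa$f_heat + pa$f_fluorescence,
               rep(1, length(q)), tolerance = 1e-12)
  expect_true(all(pa$f_photochemistry >= 0 & pa$f_photochemistry <= 1))
  expect_true(all(pa$f_heat >= 0 & pa$f_fluorescence >= 0))
  # dark-adapted maximum photochemical yield ~ 0.83
  expect_equal(pa$f_photochemistry[1],
               kk$k_p / (kk$k_p + kk$k_f + kk$k_h0), tolerance = 1e-9)
  # non-increasing with light
  expect_true(all(diff(pa$f_photochemistry) <= 1e-12))
})

test_that("smaller antenna raises the photochemical fraction, not the flux", {
  flux <- vapply(c(227.7, 419.5, 741.5), function(chl) {
    p <- modify_chlorophyll(ref, chl, "antenna_size", kk)
    pa <- psii_partition(1500, optics_from_chl(chl), p, kk)
    c(pa$f_photochemistry, pa$f_photochemistry * pa$absorbed_psii)
  }, numeric(2))
  expect_true(all(diff(flux[1, ]) < 0))      # fraction falls as chl rises
  # absolute photochemistry flux near-invariant at saturation
  expect_lt(diff(range(flux[2, ])) / mean(flux[2, ]), 0.10)
})

test_that("leaf assimilation has the right limits and scaling", {
  op <- optics_from_chl(chl_of_pools(ref, kk))
  a <- leaf_assimilation(q_grid, op, ref, kk)
  # darkness: pure dark respiration
  expect_equal(a[1], -kk$rd_frac * min(kk$kcat_rubisco * kk$rubisco_sites *
                                         ref$rubisco / kk$mw_rubisco * 1e6,
                                       kk$k_ce * ref$ce))
  expect_true(all(diff(a) >= -1e-9))   # non-decreasing in light
  # doubling all pools doubles gross assimilation at saturating light
  dbl <- ref
  for (g in names(dbl)) dbl[[g]] <- dbl[[g]] * 2
  op2 <- optics_from_chl(chl_of_pools(dbl, kk))
  a1 <- leaf_assimilation(6000, op, ref, kk)
  a2 <- leaf_assimilation(6000, op2, dbl, kk)
  rd1 <- -leaf_assimilation(0, op, ref, kk)
  rd2 <- -leaf_assimilation(0, op2, dbl, kk)
  expect_equal((a2 + rd2) / (a1 + rd1), 2, tolerance = 0.01)
})

test_that("chlorophyll modification modes move the intended pools", {
  target <- 0.4 * chl_of_pools(ref, kk)
  ant <- modify_chlorophyll(ref, target, "antenna_size", kk)
  expect_equal(ant$psii, ref$psii)
  expect_equal(ant$psi, ref$psi)
  expect_equal(chl_of_pools(ant, kk), target, tolerance = 1e-9)
  expect_equal(ant$lhcii / ant$psii,
               antenna_size_for_chl(target, ref$psii), tolerance = 1e-9)

  ps <- modify_chlorophyll(ref, target, "ps_number", kk)
  expect_equal(ps$psii, 0.4 * ref$psii)
  expect_equal(ps$lhcii / ps$psii, ref$lhcii / ref$psii)  # n1 preserved
  expect_equal(chl_of_pools(ps, kk), target, tolerance = 1e-9)

  expect_error(modify_chlorophyll(ref, 50, "antenna_size", kk),
               "core-only")
})

test_that("antenna vs photosystem-number routes separate as in the model", {
  target <- 0.4 * chl_of_pools(ref, kk)
  ant <- modify_chlorophyll(ref, target, "antenna_size", kk)
  ps <- modify_chlorophyll(ref, target, "ps_number", kk)
  o_ref <- optics_from_chl(chl_of_pools(ref, kk))
  o_low <- optics_from_chl(target)
  f_ref <- fit_nrh(q_grid, leaf_assimilation(q_grid, o_ref, ref, kk))
  f_ant <- fit_nrh(q_grid, leaf_assimilation(q_grid, o_low, ant, kk))
  f_ps <- fit_nrh(q_grid, leaf_assimilation(q_grid, o_low, ps, kk))
  # antenna route: saturated rate and absorbed-light slope preserved
  expect_equal(f_ant$p_max, f_ref$p_max, tolerance = 0.01)
  expect_equal(f_ant$phi / o_low$absorbance, f_ref$phi / o_ref$absorbance,
               tolerance = 0.02)
  # photosystem-number route: capacity and sub-saturating uptake both fall
  expect_lt(f_ps$p_max, 0.95 * f_ant$p_max)
  a_ant <- leaf_assimilation(600, o_low, ant, kk)
  a_ps <- leaf_assimilation(600, o_low, ps, kk)
  expect_lt(a_ps, a_ant - 1e-6)
})

test_that("nonrectangular hyperbola fitting recovers known parameters", {
  truth <- light_response(25, 0.055, 0.8, 1.0)
  q <- c(0, 50, 100, 200, 300, 500, 800, 1200, 1600, 2000, 2400)
  fit <- fit_nrh(q, nrh_predict(truth, q))
  expect_equal(fit$p_max, 25, tolerance = 0.005)
  expect_equal(fit$phi, 0.055, tolerance = 0.005)
  expect_equal(fit$theta, 0.8, tolerance = 0.01)
  expect_equal(fit$r_d, 1.0, tolerance = 0.01)
  # theta -> 1 approaches the Blackman limit min(phi Q, P_max) - R_d
  bl <- light_response(25, 0.055, 0.999, 1.0)
  expect_equal(nrh_predict(bl, q),
               pmin(0.055 * q, 25) - 1.0, tolerance = 0.25)
})

test_that("NRH fitting is robust to observation noise", {
  truth <- light_response(25, 0.055, 0.8, 1.0)
  q <- c(25, 50, 100, 150, 250, 400, 600, 900, 1200, 1600, 2000, 2400)
  a0 <- nrh_predict(truth, q)
  set.seed(99)
  pm <- replicate(100, {
    fit_nrh(q, a0 * (1 + rnorm(length(q), 0, 0.05)))$p_max
  })
  expect_lt(abs(median(pm) - 25) / 25, 0.05)
  expect_lt(stats::IQR(pm) / 25, 0.12)
})

test_that("pool-parameter relations are linear within the documented range", {
  rel <- cached_relations()
  co <- rel$coef
  expect_gt(min(co$r_squared[co$pool %in% c("rubisco", "ce", "etcf")]), 0.99)
  expect_gt(co$r_squared[co$pool == "psii"], 0.95)
  # reconstruction on a held-out capacity scaling
  p <- reference_pools(kk)
  s <- 0.93
  p$rubisco <- p$rubisco * s; p$ce <- p$ce * s; p$etcf <- p$etcf * s
  sim <- fit_nrh(q_grid, leaf_assimilation(
    q_grid, optics_from_chl(chl_of_pools(p, kk)), p, kk))
  a1 <- co$a[co$pool == "rubisco"]; b1 <- co$b[co$pool == "rubisco"]
  expect_equal(a1 * p$rubisco + b1, sim$p_max, tolerance = 0.02)
  # phi is orthogonal to the capacity pools
  phi_at <- function(scale) {
    p2 <- reference_pools(kk)
    p2$rubisco <- p2$rubisco * scale; p2$ce <- p2$ce * scale
    p2$etcf <- p2$etcf * scale
    fit_nrh(q_grid, leaf_assimilation(
      q_grid, optics_from_chl(chl_of_pools(p2, kk)), p2, kk))$phi
  }
  expect_equal(phi_at(0.85), phi_at(1.15), tolerance = 0.03)
})

test_that("nitrogen accounting is complete and additive", {
  n <- nitrogen_of_pools(ref, kk)
  expect_equal(n$total, Reduce(`+`, n$per_group))
  expect_true(all(unlist(n$per_group) > 0))
  # doubling every pool doubles nitrogen
  dbl <- ref
  for (g in names(dbl)) dbl[[g]] <- dbl[[g]] * 2
  expect_equal(nitrogen_of_pools(dbl, kk)$total, 2 * n$total)
})
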