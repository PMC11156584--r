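test_that("concentration profile reduces to its initial Gaussian and known values", {
  expect_equal(concentration_profile(0, 0, d = 32, sigma = 150), 1)
  # half-variance time: value is 2^(-3/2) of the peak
  sigma <- 150; d <- 32
  expect_equal(concentration_profile(0, sigma^2 / (2 * d), d, sigma),
               2^(-1.5), tolerance = 1e-12)
  # t = 0 equals the initial Gaussian at any radius
  r <- c(0, 50, 200, 600)
  expect_equal(concentration_profile(r, 0, d, sigma, c_peak = 3),
               3 * exp(-r^2 / (2 * sigma^2)))
  expect_error(concentration_profile(-1, 0, d, sigma), "r")
  expect_error(concentration_profile(0, -1, d, sigma), "t")
  expect_error(concentration_profile(0, Inf, d, sigma), "t")
})

test_that("total moles of the spreading source are conserved in time", {
  for (t in c(0, 1e3, 1e5)) {
    m <- 2 * pi * integrate(
      function(r) r^2 * concentration_profile(r, t, d = 32, sigma = 150),
      0, Inf, rel.tol = 1e-10)$value
    m0 <- 2 * pi * sqrt(pi / 2) * 150^3
    expect_equal(m, m0, tolerance = 1e-6)
  }
})

test_that("hemisphere moles matches shell quadrature of the profile", {
  # worked value at t = 0, sigma = R = 1
  expect_equal(hemisphere_moles(0, d = 1, sigma = 1, radius = 1),
               2 * pi * 0.249093, tolerance = 1e-5)
  expect_equal(hemisphere_moles(0, d = 1, sigma = 1, radius = 1),
               oracle_hemisphere_moles(0, 1, 1, 1), tolerance = 1e-10)
  # 20 random parameter draws
  set.seed(11)
  for (i in 1:20) {
    d <- 10^runif(1, 0, 2.7)
    sigma <- runif(1, 50, 500)
    R <- runif(1, 0.3, 3) * sigma
    t <- 10^runif(1, 0, 4)
    expect_equal(hemisphere_moles(t, d, sigma, R),
                 oracle_hemisphere_moles(t, d, sigma, R),
                 tolerance = 1e-6)
  }
})

test_that("hemisphere moles decays monotonically to zero and saturates in R", {
  tt <- c(0, 10, 100, 1000, 1e4, 1e6)
  m <- hemisphere_moles(tt, d = 136, sigma = 150)
  expect_true(all(diff(m) < 0))
  expect_lt(m[length(m)] / m[1], 1e-3)
  # R -> Inf limit is the (time-independent) total moles
  total <- 2 * pi * sqrt(pi / 2) * 150^3
  for (t in c(0, 1e3)) {
    expect_equal(hemisphere_moles(t, 136, 150, radius = 1e7), total,
                 tolerance = 1e-9)
  }
  expect_error(hemisphere_moles(0, 136, 150, radius = -1), "radius")
})

test_that("flow-advected moles reduce to the closed form at zero velocity", {
  for (t in c(0, 60, 3600)) {
    expect_equal(hemisphere_moles_flow(t, d = 32, sigma = 150, velocity = 0),
                 hemisphere_moles(t, d = 32, sigma = 150),
                 tolerance = 1e-9)
  }
})

test_that("flow strictly depletes the detection hemisphere", {
  m <- vapply(c(0, 0.5, 2),
              function(v) hemisphere_moles_flow(600, 32, 150, v),
              numeric(1))
  expect_true(all(diff(m) < 0))
})

test_that("flow quadrature matches Monte-Carlo integration to 0.1%", {
  q <- hemisphere_moles_flow(600, d = 32, sigma = 150, velocity = 0.5,
                             radius = 150)
  mc <- oracle_mc_flow_moles(600, 32, 150, 150, 0.5, n = 1e7)
  expect_equal(q, mc, tolerance = 1e-3)
})

test_that("slab series matches its initial condition and stays bounded", {
  # truncated alternating series at t = 0 sums to C0 within its tail bound
  expect_equal(slab_concentration(0, d = 1, thickness = 1, x = 0), 1,
               tolerance = 2e-3)
  tt <- 10^seq(-2, 0.3, length.out = 20)
  cc <- slab_concentration(tt, d = 1, thickness = 1, x = 0, c0 = 2)
  expect_true(all(cc >= 0 & cc <= 2))
  expect_error(slab_concentration(-1, 1, 1), "t")
  expect_error(slab_concentration(1, 1, 1, x = 2), "x")
})

test_that("slab series agrees with a Crank-Nicolson finite-difference solution", {
  times <- c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1, 2) # = Dt/L^2
  cn <- oracle_cn_slab(1, 1, 0, times, dt = 1e-3)
  expect_equal(slab_concentration(times, 1, 1, x = 0), cn,
               tolerance = 1e-4)
  cn01 <- oracle_cn_slab(1, 1, 0.1, c(0.1, 0.5, 1), dt = 1e-3)
  expect_equal(slab_concentration(c(0.1, 0.5, 1), 1, 1, x = 0.1), cn01,
               tolerance = 1e-4)
})

test_that("slab time course is insensitive to position near the sealed face", {
  tt <- seq(0.1, 2, by = 0.05) # Dt/L^2
  c0x <- slab_concentration(tt, 1, 1, x = 0)
  c10 <- slab_concentration(tt, 1, 1, x = 0.1)
  # the offset never exceeds the single-mode bound 1 - cos(0.05*pi)
  expect_true(all(abs(c10 - c0x) <= (1 - cos(0.05 * pi)) * 1.05))
  # and at late times the two curves differ only by a constant factor,
  # so the time course (hence the fitted D) is unchanged
  late <- tt >= 0.5
  ratio <- c10[late] / c0x[late]
  expect_lt(diff(range(ratio)), 1e-4)
  expect_equal(mean(ratio), cos(0.05 * pi), tolerance = 1e-4)
})

test_that("clearance factor is the exact survival ratio", {
  set.seed(3)
  for (i in 1:5) {
    r <- runif(1, 0, 4000); t <- 10^runif(1, 1, 4.5); tau <- 10^runif(1, 3, 5)
    expect_equal(
      clearance_concentration(r, t, 231, 250, tau) /
        concentration_profile(r, t, 231, 250),
      tau / (t + tau))
  }
  # no-clearance limit
  tt <- 10^seq(0, 5, length.out = 30)
  expect_equal(clearance_concentration(3335, tt, 231, 250, tau = 1e12),
               concentration_profile(3335, tt, 231, 250),
               tolerance = 1e-6)
  expect_error(clearance_concentration(0, 0, 231, 250, tau = -5), "tau")
})

test_that("clearance shifts the arrival peak earlier", {
  tt <- seq(1, 4e4, length.out = 4e4)
  plain <- concentration_profile(3335, tt, 231, 250)
  cleared <- clearance_concentration(3335, tt, 231, 250, tau = 2600)
  expect_lt(tt[which.max(cleared)], tt[which.max(plain)])
})

test_that("clearance percentage follows the saturating law", {
  expect_equal(clearance_percent(0, 2600), 0)
  expect_equal(clearance_percent(2600, 2600), 50)
  expect_equal(clearance_percent(3 * 2600, 2600), 75)
  p <- clearance_percent(seq(0, 1e6, length.out = 100), 2600)
  expect_true(all(diff(p) > 0) && all(p < 100))
})

test_that("tortuosity follows from the diffusion-coefficient ratio", {
  expect_equal(tortuosity(50, 50), 1)
  d_aq_37 <- stokes_einstein_correct(136, 20, 37)
  expect_equal(tortuosity(32.1, d_aq_37), 2.5, tolerance = 0.02)
  # inversion: free-solution value and tortuosity imply the tissue value
  d_aq_af488 <- stokes_einstein_correct(295, 20, 37)
  expect_equal(d_aq_af488 / 1.4^2, 230.7, tolerance = 1e-3)
  expect_error(tortuosity(-1, 10))
  expect_error(tortuosity(10, 0))
})

test_that("temperature correction scales with T/eta as expected", {
  expect_equal(stokes_einstein_correct(136, 25, 25), 136)
  # frozen from hand computation with the table anchors:
  # 136 * (310.15/293.15) * (1.0016/0.6913)
  expect_equal(stokes_einstein_correct(136, 20, 37), 208.47,
               tolerance = 1e-4)
  expect_equal(stokes_einstein_correct(295, 20, 37), 452.20,
               tolerance = 1e-4)
  expect_equal(water_viscosity(c(20, 37)), c(1.0016, 0.6913))
  expect_error(stokes_einstein_correct(100, 20, 120), "range")
})

test_that("peak arrival time matches dense-grid maximisation", {
  # boundary: wide source relative to distance never peaks
  expect_equal(peak_arrival_time(r = 100, d = 10, sigma = 100), 0)
  tp <- peak_arrival_time(3335, 230.7, 250)
  expect_equal(tp, 7.90e3, tolerance = 1e-2)
  expect_equal(tp, oracle_grid_peak_time(3335, 230.7, 250, 3e4),
               tolerance = 1e-3)
  set.seed(5)
  for (i in 1:3) {
    r <- runif(1, 2000, 5000); d <- runif(1, 50, 400); s <- runif(1, 100, 400)
    expect_equal(peak_arrival_time(r, d, s),
                 oracle_grid_peak_time(r, d, s, 1e5), tolerance = 1e-3)
  }
  # scaling law: doubling D halves the point-source peak time
  expect_equal(peak_arrival_time(1000, 100, 0),
               2 * peak_arrival_time(1000, 200, 0))
})

test_that("recovery intensity interpolates between its limits", {
  expect_equal(recovery_intensity(0, 136, 150, i0 = 0.2, i_inf = 1), 0.2)
  expect_equal(recovery_intensity(1e8, 136, 150, i0 = 0.2, i_inf = 1), 1,
               tolerance = 1e-4)
  # at the half-depletion time the intensity is the midpoint
  t_half <- stats::uniroot(function(t) {
    hemisphere_moles(t, 136, 150) / hemisphere_moles(0, 136, 150) - 0.5
  }, c(1, 1e5))$root
  expect_equal(recovery_intensity(t_half, 136, 150, 0.2, 1), 0.6,
               tolerance = 1e-6)
  y <- recovery_intensity(seq(0, 3600, 10), 136, 150, 0.2, 1)
  expect_true(all(diff(y) >= 0))
  expect_error(recovery_intensity(0, 136, 150, i0 = 1, i_inf = 0.5), "i_inf")
})

test_that("bleach-window spread inflates the source width by at most 8%", {
  expect_equal(bleach_spread_sigma(300, d = 32, bleach_duration = 0), 300)
  eff <- bleach_spread_sigma(300, d = 32, bleach_duration = 30)
  expect_gte(eff, 300)
  expect_lte(eff, sqrt(300^2 + 2 * 32 * 30) * (1 + 1e-6))
  expect_lte(eff / 300 - 1, 0.08)
  # faster diffusion, smaller source: still bounded by the analytic width
  eff2 <- bleach_spread_sigma(150, d = 136, bleach_duration = 30)
  expect_gte(eff2, 150)
  expect_lte(eff2, sqrt(150^2 + 2 * 136 * 30) * (1 + 1e-6))
})
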