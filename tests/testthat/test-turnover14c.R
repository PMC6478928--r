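test_that("constant forcing reproduces the closed-form steady state", {
  flat <- flat_curve(0)
  cfg <- tau14c_config()
  # k = lambda: F* = k/(k+lambda) = 1/2, i.e. -500 permil
  expect_equal(forward_simulate(lambda_14c, flat, cfg), -500,
               tolerance = 0.1 / 500)
  # tau = 100 yr: Delta* = -1000*lambda/(k+lambda)
  k <- 1 / 100
  expect_equal(forward_simulate(k, flat, cfg),
               -1000 * lambda_14c / (k + lambda_14c), tolerance = 1e-6)
  # the steady state is a fixed point: no drift just after run_start
  expect_equal(forward_simulate(k, flat, cfg, end_year = 1951),
               forward_simulate(k, flat, cfg, end_year = 2010),
               tolerance = 1e-9)
})

test_that("closed-form endpoint equals the literal step-by-step recursion", {
  crv <- synth_bomb_curve()
  for (cfg in list(tau14c_config(),
                   tau14c_config(space = "delta_literal"),
                   tau14c_config(forcing = "endpoint"))) {
    for (tau in c(3, 40, 300)) {
      expect_equal(forward_simulate(1 / tau, crv, cfg),
                   soctau:::.forward_simulate_loop(1 / tau, crv, cfg),
                   tolerance = 1e-10)
    }
  }
})

test_that("the delta-literal recursion omits the radioactive-decay offset", {
  flat <- flat_curve(0)
  lit <- tau14c_config(space = "delta_literal")
  # in literal Delta space a zero atmosphere pins the pool at exactly 0
  # permil; the fraction-modern form retains the decay depletion
  expect_equal(forward_simulate(1 / 100, flat, lit), 0, tolerance = 1e-9)
  expect_lt(forward_simulate(1 / 100, flat, tau14c_config()), -10)
})

test_that("turnover limits: fast pools track the atmosphere, slow pools age out", {
  crv <- synth_bomb_curve()
  atm_2014 <- atm_value_at(crv, 2014.5)
  expect_lt(abs(forward_simulate(1 / 0.2, crv, tau14c_config(),
                                 end_year = 2014.5) - atm_2014), 5)
  slow <- forward_simulate(1 / 5e5, flat_curve(0), tau14c_config())
  expect_lt(slow, -900)
  expect_gt(slow, -1000)
  # Euler stability guard: sub-monthly turnover is rejected at h = 1/12
  expect_error(forward_simulate(13, crv, tau14c_config()), "instability")
})

test_that("inversion round-trips the forward model on the post-peak branch", {
  crv <- synth_bomb_curve()
  cfg <- tau14c_config()
  d <- forward_simulate(1 / 100, crv, cfg, end_year = 2014.5)
  sol <- invert_tau(rc_measurement(d, 0, 2014.5), crv, cfg)
  expect_equal(sol$tau, 100, tolerance = 1e-3)
  expect_equal(sol$k * sol$tau, 1)
  expect_lt(abs(sol$residual), 1e-3)
})

test_that("an aged sample under constant zero forcing inverts to the mean life", {
  # closed form: Delta = -1000*lambda/(k+lambda) = -500  =>  k = lambda
  sol <- invert_tau(rc_measurement(-500, 0, 2014.5), flat_curve(0),
                    tau14c_config())
  expect_equal(sol$tau, 8267, tolerance = 1e-4)
})

test_that("bomb-enriched samples yield two roots and the larger is returned", {
  crv <- synth_bomb_curve()
  cfg <- tau14c_config()
  d <- forward_simulate(1 / 100, crv, cfg, end_year = 2014.5)
  expect_gt(d, 50)  # bomb-enriched
  sol <- invert_tau(rc_measurement(d, 0, 2014.5), crv, cfg)
  expect_equal(sol$n_roots_found, 2L)
  expect_equal(sol$branch, "post_peak")
  expect_equal(sol$tau, max(sol$roots))
  # brute-force enumeration: sign changes of the mismatch on a fine grid
  taus <- exp(seq(log(1), log(50000), length.out = 4000))
  g <- forward_simulate(1 / taus, crv, cfg, end_year = 2014.5) - d
  flips <- which(sign(g[-1]) * sign(g[-length(g)]) < 0)
  expect_equal(length(flips), 2L)
  expect_equal(sol$roots, sqrt(taus[flips] * taus[flips + 1]),
               tolerance = 0.01)
})

test_that("observations outside the attainable range report a no-solution error", {
  crv <- synth_bomb_curve()
  expect_error(invert_tau(rc_measurement(2000, 0, 2014.5), crv,
                          tau14c_config()),
               "attainable")
})

test_that("analytical uncertainty brackets the point estimate", {
  crv <- synth_bomb_curve()
  cfg <- tau14c_config()
  # zero sigma collapses to a degenerate interval
  d <- forward_simulate(1 / 150, crv, cfg, end_year = 2014.5)
  ui <- tau_uncertainty(rc_measurement(d, 0, 2014.5), crv, cfg)
  expect_equal(unname(ui[1]), unname(ui[2]))
  set.seed(5)
  widths <- numeric(0)
  for (i in 1:15) {
    tau <- exp(runif(1, log(60), log(1500)))
    d <- forward_simulate(1 / tau, crv, cfg, end_year = 2014.5)
    m <- rc_measurement(d, 4, 2014.5)
    sol <- invert_tau(m, crv, cfg)
    ui <- tau_uncertainty(m, crv, cfg)
    expect_lte(ui[1], sol$tau * (1 + 1e-9))
    expect_gte(ui[2], sol$tau * (1 - 1e-9))
    # wider sigma gives a wider (or equal) interval
    ui2 <- tau_uncertainty(rc_measurement(d, 8, 2014.5), crv, cfg)
    expect_gte(diff(ui2), diff(ui) - 1e-9)
  }
})

test_that("forward model tolerates curves ending before the sampling year", {
  crv <- synth_bomb_curve(end_year = 2010)
  expect_warning(d <- forward_simulate(1 / 100, crv, tau14c_config(),
                                       end_year = 2014.5),
                 "extrapolat")
  full <- forward_simulate(1 / 100, synth_bomb_curve(end_year = 2015),
                           tau14c_config(), end_year = 2014.5)
  expect_lt(abs(d - full), 5)  # linear tail vs exponential tail, small gap
})
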