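test_that("trap capacity follows CO2 + 2 NaOH stoichiometry", {
  tr <- trap_spec(volume_ml = 20, molarity = 1)
  expect_equal(tr$capacity_gC, 0.020 * 1 / 2 * 12.011)
  expect_equal(tr$capacity_gC, 0.12011, tolerance = 1e-9)
  expect_error(trap_spec(volume_ml = 0), "positive")
  expect_error(trap_spec(saturation_frac = 1.2), "saturation_frac")
})

test_that("conductivity change maps linearly to trapped carbon", {
  expect_equal(conductivity_to_c(50, 50, slope = -0.5), 0)
  # slope -0.5 mS/cm per mg C, change -10 mS/cm -> 20 mg C
  expect_equal(conductivity_to_c(50, 40, slope = -0.5), 0.020)
  # noise: slight negative clamps to zero with a warning
  expect_warning(v <- conductivity_to_c(50, 50.1, slope = -0.5), "clamped")
  expect_equal(v, 0)
  # a large deficit is a hard error
  expect_error(suppressWarnings(conductivity_to_c(50, 51.2, slope = -0.5)),
               "deficit")
  expect_error(conductivity_to_c(50, 40, slope = -0.5,
                                 cond_range = c(45, 60)), "range")
  expect_error(conductivity_to_c(50, 40, slope = 0), "non-zero")
})

test_that("saturation flag is inclusive at 80% of capacity and monotone", {
  tr <- trap_spec()
  mk <- function(scale) incubation_series("s", rep(scale * tr$capacity_gC, 8),
                                          toc_initial = 100)
  expect_false(flag_saturation(mk(0.5), tr))
  expect_true(flag_saturation(mk(0.8), tr))   # >= is inclusive
  expect_true(flag_saturation(mk(0.95), tr))
  # monotone: scaling emissions up can only flip false -> true
  s <- mk(0.5)
  s$co2c_g <- s$co2c_g * 2
  expect_true(flag_saturation(s, tr))
})

test_that("normalisation to initial OC and its inverse round-trip", {
  # total CO2-C equal to 1% of initial OC -> 10 g per kg OC
  s <- incubation_series("s", rep(0.04 / 8, 8), toc_initial = 100,
                         dry_mass = 40)  # OC mass 4 g, emissions 0.04 g
  norm <- normalize_to_toc(s)
  expect_equal(norm$oc_mass_g, 4)
  expect_equal(norm$co2c_cum_gkg[8], 10)
  # zero emissions stay zero
  z <- incubation_series("s", rep(0, 8), toc_initial = 50)
  expect_equal(normalize_to_toc(z)$co2c_cum_gkg, rep(0, 8))
  # de-normalisation recovers the absolute masses
  set.seed(3)
  co2 <- runif(8, 0, 0.01)
  s <- incubation_series("s", co2, toc_initial = 73, dry_mass = 37)
  norm <- normalize_to_toc(s)
  expect_equal(diff(c(0, norm$co2c_cum_gkg)) * norm$oc_mass_g / 1000, co2,
               tolerance = 1e-12)
})

test_that("turnover time is stock over annualised output flux", {
  # cumulative 181-day respiration of 49.56 g per kg OC -> flux 100, tau 10
  oc <- 4  # g, from toc 100 g/kg x 40 g
  s <- incubation_series("s", rep(49.56 * oc / 1000 / 8, 8),
                         toc_initial = 100, dry_mass = 40)
  ti <- tau_incubation(s)
  expect_equal(ti$annual_flux, 100.0, tolerance = 1e-3)
  expect_equal(ti$tau_i, 10.0, tolerance = 1e-3)
  expect_false(ti$saturated)
  expect_error(tau_incubation(
    incubation_series("s", rep(0, 8), toc_initial = 100)), "zero")
})

test_that("a known first-order decay is recovered on the trap schedule", {
  ti <- tau_incubation(decay_series(k_lab = 0.1))
  expect_equal(ti$tau_i, 10, tolerance = 0.03)
  # invariant to the soil dry mass used (normalisation cancels it)
  ti2 <- tau_incubation(decay_series(k_lab = 0.1, dry_mass = 13))
  expect_equal(ti$tau_i, ti2$tau_i, tolerance = 1e-10)
  # including the (small) DOC flux shortens tau slightly
  s <- decay_series(k_lab = 0.1)
  s$leach_days <- leach_schedule_days
  s$doc_g <- rep(sum(s$co2c_g) * 0.01 / 6, 6)
  expect_lt(tau_incubation(s, include_doc = TRUE)$tau_i,
            tau_incubation(s, include_doc = FALSE)$tau_i)
})

test_that("saturated series withhold the turnover time", {
  tr <- trap_spec()
  s <- incubation_series("6", rep(0.9 * tr$capacity_gC, 8), toc_initial = 100)
  expect_error(tau_incubation(s, tr), class = "soctau_saturation_error")
})

test_that("cumulative DOC is additive and normalised to initial OC", {
  s <- incubation_series("s", rep(0.001, 8), doc_g = rep(0, 6),
                         toc_initial = 100, dry_mass = 40)
  expect_equal(cumulative_doc(s), 0)
  s$doc_g <- rep(2e-4, 6)
  expect_equal(cumulative_doc(s), 6 * 2e-4 / 4 * 1000)
  expect_error(incubation_series("s", rep(0.001, 8), doc_g = rep(-1e-4, 6),
                                 toc_initial = 100), "negative DOC")
})

test_that("generated studies leach about 1% of losses as DOC and lose 1-9% OC", {
  st <- quiet_study(synth_config(seed = 21, inject_pathologies = FALSE))
  ratios <- vapply(st$series, function(s) {
    norm <- normalize_to_toc(s)
    doc <- cumulative_doc(s)
    doc / (norm$co2c_cum_gkg[length(norm$co2c_cum_gkg)] + doc)
  }, numeric(1))
  expect_gt(median(ratios), 0.003)
  expect_lt(median(ratios), 0.03)
  loss <- vapply(st$series, function(s)
    tau_incubation(s)$cum_loss_frac, numeric(1))
  expect_gt(min(loss), 0.005)
  expect_lt(max(loss), 0.15)
})
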