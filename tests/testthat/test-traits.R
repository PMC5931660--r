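test_that("construction cost reproduces reference-mean values", {
  # evaluated at typical native group means
  expect_equal(construction_cost(0.4843, 0.0264, 0.067), 1.49473,
               tolerance = 1e-5)
  expect_true(abs(construction_cost(0.4843, 0.0264, 0.067) - 1.50) <= 0.03)
  # invasive group means
  expect_equal(construction_cost(0.4758, 0.0341, 0.073), 1.48899,
               tolerance = 1e-5)
  expect_true(abs(construction_cost(0.4758, 0.0341, 0.073) - 1.49) <= 0.01)
  # formula collapses without N and ash
  cs <- c(0.35, 0.45, 0.55)
  expect_equal(construction_cost(cs, 0, 0), -1.041 + 5.077 * cs)
})

test_that("construction cost is monotone in its inputs", {
  base <- construction_cost(0.48, 0.026, 0.067)
  expect_gt(construction_cost(0.50, 0.026, 0.067), base)
  expect_gt(construction_cost(0.48, 0.030, 0.067), base)
  expect_lt(construction_cost(0.48, 0.026, 0.080), base)
})

test_that("mg g-1 inputs are auto-rescaled and invalid inputs rejected", {
  w <- capture_warnings(cc <- construction_cost(484.3, 26.4, 67))
  expect_length(w, 3)  # one per rescaled input
  expect_match(w, "mg g-1", all = TRUE)
  expect_equal(cc, construction_cost(0.4843, 0.0264, 0.067))
  expect_error(construction_cost(-0.1, 0.02, 0.06), "c_mass")
  expect_error(suppressWarnings(construction_cost(2000, 0.02, 0.06)))
})

test_that("area/mass conversions are exact inverses with correct units", {
  expect_equal(amax_area_to_mass(10, sla = 200), 200)  # nmol g-1 s-1
  expect_equal(mass_to_area(0.0264, sla = 184), 1.43478, tolerance = 1e-5)
  set.seed(7)
  v <- runif(50, 0.1, 100)
  sla <- runif(50, 50, 400)
  expect_equal(amax_mass_to_area(amax_area_to_mass(v, sla), sla), v,
               tolerance = 1e-12)
  expect_equal(area_to_mass(mass_to_area(v, sla), sla), v, tolerance = 1e-12)
  expect_error(mass_to_area(1, sla = 0), "sla")
})

test_that("efficiencies have correct units, linearity, and NA denominators", {
  e <- efficiencies(7.62, r_d_area = 0.77, n_area = 1.61, cc_area = 113.1,
                    e_trans_sat = 1.2)
  expect_equal(e$pnue, 7.62 / 1.61)
  expect_equal(e$pnue, 4.733, tolerance = 1e-3)
  expect_equal(e$peue, 7.62 / 113.1 * 1000)
  expect_equal(e$wue, 7.62 / 1.2)
  expect_equal(e$amax_over_rd, 7.62 / 0.77)
  expect_equal(efficiencies(10, cc_area = 100)$peue, 100)
  # doubling the numerator doubles every efficiency
  e2 <- efficiencies(2 * 7.62, 0.77, 1.61, 113.1, 1.2)
  expect_equal(unlist(e2), 2 * unlist(e))
  # undefined ratios are NA, not errors
  e3 <- efficiencies(10, r_d_area = 0, n_area = NA, cc_area = -1,
                     e_trans_sat = 0)
  expect_true(all(is.na(unlist(e3))))
})

test_that("derived trait table round-trips and keeps per-individual semantics", {
  cfg <- panel_config(seed = 41, n_native_evergreen = 2,
                      n_native_deciduous = 1, n_invasive = 1,
                      individuals_range = c(3, 4), noise_sd_a = 0.1)
  study <- simulate_study(cfg)
  fits <- fit_curves(study$curves)
  der <- derive_traits(study$traits, fits)
  expect_equal(nrow(der), nrow(study$traits))
  # derived fields recomputable from primitives
  expect_equal(der$cc_mass,
               construction_cost(der$c_mass, der$n_mass, der$ash),
               tolerance = 1e-9)
  expect_equal(der$n_area, mass_to_area(der$n_mass, der$sla),
               tolerance = 1e-9)
  expect_equal(der$a_max_mass, amax_area_to_mass(der$a_max_area, der$sla),
               tolerance = 1e-9)
  expect_equal(der$pnue, der$a_max_area / der$n_area, tolerance = 1e-12)
  # full area -> mass -> area loop reproduces inputs exactly
  expect_equal(area_to_mass(mass_to_area(der$c_mass, der$sla), der$sla),
               der$c_mass, tolerance = 1e-12)
  # mean of per-individual ratios differs from ratio of means (semantics)
  expect_false(isTRUE(all.equal(mean(der$pnue),
                                mean(der$a_max_area) / mean(der$n_area))))
})
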