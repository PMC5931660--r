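test_that("default panel reproduces the study design shape", {
  panel <- generate_panel(panel_config(seed = 5))
  expect_equal(nrow(panel), 19)
  expect_equal(sum(panel$nativity == "invasive"), 3)
  expect_true(all(panel$leaf_habit[panel$nativity == "invasive"] ==
                    "deciduous"))
  expect_equal(sum(panel$nativity == "native" &
                     panel$leaf_habit == "deciduous"), 3)
  expect_true(all(panel$n_individuals >= 4 & panel$n_individuals <= 14))
  # parameter invariants
  expect_true(all(panel$a_max_area > 0))
  expect_true(all(panel$phi > 0 & panel$phi <= 0.125))
  expect_true(all(panel$theta > 0 & panel$theta <= 1))
  expect_true(all(panel$r_d_area >= 0))
  expect_true(all(panel$ldmc <= 1 & panel$ash < 1))
  expect_true(all(as.matrix(panel[, c("sla", "n_mass", "c_mass", "ash",
                                      "ldmc", "thickness", "leaf_area")]) > 0))
})

test_that("zero group effects and zero random effects collapse the panel", {
  cfg <- zero_random_effects(zero_group_effects(panel_config(seed = 3)))
  panel <- generate_panel(cfg)
  for (col in c("a_max_area", "phi", "theta", "r_d_area", "sla", "n_mass"))
    expect_equal(length(unique(panel[[col]])), 1, info = col)
})

test_that("generators are deterministic in the seed and change with it", {
  cfg42 <- panel_config(seed = 42)
  p1 <- generate_panel(cfg42)
  p2 <- generate_panel(cfg42)
  expect_identical(p1, p2)
  expect_false(identical(generate_panel(panel_config(seed = 43))$a_max_area,
                         p1$a_max_area))
  s1 <- simulate_study(cfg42)
  s2 <- simulate_study(cfg42)
  expect_identical(s1$curves, s2$curves)
  expect_identical(s1$traits, s2$traits)
  # byte-identical on disk
  d1 <- file.path(tempdir(), "synth_a"); d2 <- file.path(tempdir(), "synth_b")
  write_synthetic_data(d1, cfg42); write_synthetic_data(d2, cfg42)
  for (f in c("light_curves.csv", "traits.csv", "species.csv", "truth.json"))
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6), info = f)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("configuration errors are caught", {
  expect_error(panel_config(n_native_evergreen = -1), "counts")
  expect_error(panel_config(ppfd_sequence = numeric(0)), "ppfd_sequence")
  expect_error(panel_config(individuals_range = c(5, 2)), "individuals_range")
  expect_error(panel_config(base_params = list(a_max_area = 7, phi = 0.2,
                                               theta = 0.8, r_d_area = 0.7)),
               "bounds")
})

test_that("noise-free curves follow the forward model exactly", {
  cfg <- panel_config(seed = 9, noise_sd_a = 0)
  cfg <- zero_random_effects(cfg)
  panel <- generate_panel(cfg)
  curves <- simulate_light_curves(panel, cfg)
  # every individual contributes exactly 12 rows
  expect_true(all(table(curves$individual_id) == 12))
  expect_equal(nrow(curves), sum(panel$n_individuals) * 12)
  # values equal the NRH evaluated at the species truth
  one <- curves[curves$individual_id == curves$individual_id[1], ]
  sp <- panel[panel$species_code == one$species_code[1], ]
  p <- nrh_params(sp$a_max_area, sp$phi, sp$theta, sp$r_d_area)
  expect_equal(one$a_net, nrh_predict(p, one$ppfd), tolerance = 1e-12)
  # at q = 0 the reading is -r_d
  expect_equal(unique(curves$a_net[curves$ppfd == 0]),
               -unique(panel$r_d_area), tolerance = 1e-12)
  # oracle check at the saturating step
  expect_equal(one$a_net[one$ppfd == 1300],
               oracle_nrh_gross(1300, sp$a_max_area, sp$phi, sp$theta) -
                 sp$r_d_area, tolerance = 1e-10)
})

test_that("transpiration encodes the configured water-use efficiency", {
  cfg <- zero_random_effects(panel_config(seed = 13, noise_sd_a = 0,
                                          wue_true = 6))
  panel <- generate_panel(cfg)
  curves <- simulate_light_curves(panel, cfg)
  top <- curves[curves$ppfd == max(curves$ppfd), ]
  expect_equal(top$a_net / top$e_trans, rep(6, nrow(top)), tolerance = 1e-10)
})

test_that("trait table respects zero-variance config and recovers scaling slopes", {
  cfg <- zero_random_effects(panel_config(seed = 17))
  panel <- generate_panel(cfg)
  traits <- simulate_trait_table(panel, cfg)
  expect_equal(traits$sla,
               panel$sla[match(traits$species_code, panel$species_code)],
               tolerance = 1e-12)

  # noise-free configured slopes are recovered exactly by OLS on logs
  cfg2 <- panel_config(seed = 17, n_native_evergreen = 1,
                       n_native_deciduous = 0, n_invasive = 1,
                       individuals_range = c(200, 200),
                       nmass_sla_slope = c(evergreen = 1.0, deciduous = 0.5),
                       nmass_noise_sd = 0)
  cfg2$species_sd$traits <- 0
  panel2 <- generate_panel(cfg2)
  traits2 <- simulate_trait_table(panel2, cfg2)
  meta <- tiny_species_meta(panel2)
  for (habit in c("evergreen", "deciduous")) {
    sub <- traits2[traits2$species_code %in%
                     meta$species_code[meta$leaf_habit == habit], ]
    sl <- coef(lm(log(n_mass) ~ log(sla), data = sub))[[2]]
    expect_equal(sl, unname(cfg2$nmass_sla_slope[habit]), tolerance = 1e-6)
  }
})

test_that("default trait magnitudes match the study's scale", {
  study <- simulate_study(panel_config(seed = 23))
  expect_gt(median(study$traits$sla), 100)
  expect_lt(median(study$traits$sla), 300)
  expect_gt(median(study$traits$n_mass), 0.015)
  expect_lt(median(study$traits$n_mass), 0.04)
  expect_gt(median(study$traits$c_mass), 0.4)
  expect_lt(median(study$traits$c_mass), 0.55)
})
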