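make_group_data <- function(habit_effect_log_amax = 0, nativity_effect = 0,
                            n_sp_e = 8, n_sp_d = 3, n_inv = 3,
                            n_ind = 6, sp_sd = 0.1, res_sd = 0.1, seed = 1) {
  set.seed(seed)
  meta <- data.frame(
    species_code = sprintf("S%02d", seq_len(n_sp_e + n_sp_d + n_inv)),
    nativity = c(rep("native", n_sp_e + n_sp_d), rep("invasive", n_inv)),
    leaf_habit = c(rep("evergreen", n_sp_e), rep("deciduous", n_sp_d + n_inv)),
    stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(meta)), function(s) {
    mu <- 5 + habit_effect_log_amax * (meta$leaf_habit[s] == "evergreen") +
      nativity_effect * (meta$nativity[s] == "invasive") + rnorm(1, 0, sp_sd)
    data.frame(individual_id = sprintf("%s_%d", meta$species_code[s],
                                       seq_len(n_ind)),
               species_code = meta$species_code[s],
               value = mu + rnorm(n_ind, 0, res_sd),
               stringsAsFactors = FALSE)
  })
  list(values = do.call(rbind, rows), meta = meta)
}

quick_cfg <- function(seed = 1) hb_config(chains = 2, iter = 1500,
                                          burnin = 500, seed = seed)

test_that("significance flag equals '95% CI excludes zero' with boundary convention", {
  expect_true(significance_from_ci(-6.9, -1.6))
  expect_false(significance_from_ci(-5.4, 1.5))
  expect_false(significance_from_ci(0, 0))
  expect_true(significance_from_ci(0.001, 2))
  expect_false(significance_from_ci(-1, 0))   # touching zero: not significant
  expect_error(significance_from_ci(2, 1), "ci_low")
})

test_that("a strong habit effect is detected and a null nativity effect is not", {
  d <- make_group_data(habit_effect_log_amax = -0.8, nativity_effect = 0,
                       seed = 42)
  fit <- fit_group_model(d$values, d$meta, quick_cfg(42), transform = "identity",
                         trait_name = "log_a_max_mass")
  expect_false(fit$degenerate)
  expect_true(fit$beta_leafhabit$significant)
  expect_lt(fit$beta_leafhabit$ci_high, 0)
  expect_false(fit$beta_nativity$significant)
  # effect size recovered within the CI
  expect_true(fit$beta_leafhabit$ci_low <= -0.8 &
                -0.8 <= fit$beta_leafhabit$ci_high)
  expect_match(fit$confounding_note, "confounded")
})

test_that("degenerate and inestimable inputs are flagged, not fitted", {
  d <- make_group_data(seed = 3)
  d$values$value <- 1
  fit <- fit_group_model(d$values, d$meta, quick_cfg())
  expect_true(fit$degenerate)
  expect_match(fit$message, "zero variance")

  all_ever <- make_group_data(n_sp_d = 0, n_inv = 0, seed = 4)
  fit2 <- fit_group_model(all_ever$values, all_ever$meta, quick_cfg())
  expect_true(fit2$inestimable)

  bad <- make_group_data(seed = 5)
  bad$values$species_code[1] <- "ZZZ"
  expect_error(fit_group_model(bad$values, bad$meta, quick_cfg()), "ZZZ")
})

test_that("posterior means match OLS when species variance is negligible", {
  d <- make_group_data(habit_effect_log_amax = -0.5, nativity_effect = 0.3,
                       sp_sd = 0, res_sd = 0.2, n_ind = 10, seed = 7)
  fit <- fit_group_model(d$values, d$meta,
                         hb_config(chains = 2, iter = 4000, burnin = 1000,
                                   seed = 7))
  meta_i <- d$meta[match(d$values$species_code, d$meta$species_code), ]
  ols <- lm(d$values$value ~ I(meta_i$nativity == "invasive") +
              I(meta_i$leaf_habit == "evergreen"))
  expect_equal(fit$beta_nativity$mean, coef(ols)[[2]], tolerance = 0.1)
  expect_equal(fit$beta_leafhabit$mean, coef(ols)[[3]], tolerance = 0.1)
})

test_that("species relabeling leaves the posterior unchanged", {
  d <- make_group_data(habit_effect_log_amax = -0.6, seed = 11)
  fit1 <- fit_group_model(d$values, d$meta, quick_cfg(11))
  # permute labels consistently in values and meta (same data, new names)
  lut <- setNames(sprintf("X%02d", seq_len(nrow(d$meta))),
                  d$meta$species_code)
  d2 <- d
  d2$values$species_code <- unname(lut[d2$values$species_code])
  d2$meta$species_code <- unname(lut[d2$meta$species_code])
  fit2 <- fit_group_model(d2$values, d2$meta, quick_cfg(11))
  expect_equal(fit1$beta_leafhabit$mean, fit2$beta_leafhabit$mean,
               tolerance = 1e-12)
})

test_that("group summary arithmetic matches hand computation", {
  traits <- data.frame(
    species_code = rep(c("A", "B", "C", "D"), each = 2),
    v = c(1, 3, 5, 7, 10, 14, 20, 22))
  meta <- data.frame(species_code = c("A", "B", "C", "D"),
                     nativity = c("native", "native", "native", "invasive"),
                     leaf_habit = c("evergreen", "evergreen", "deciduous",
                                    "deciduous"))
  gs <- summarize_groups(traits, meta, traits = "v")
  g <- function(grp) gs[gs$group == grp, ]
  # species means: A=2, B=6, C=12, D=21
  expect_equal(g("all_native")$mean, mean(c(2, 6, 12)))
  expect_equal(g("all_native")$se, sd(c(2, 6, 12)) / sqrt(3))
  expect_equal(g("native_evergreen")$mean, 4)
  expect_equal(g("native_deciduous")$mean, 12)
  expect_true(is.na(g("native_deciduous")$se))  # single-species group
  expect_equal(g("invasive")$mean, 21)
  expect_equal(g("all_native")$n, 3)
  expect_error(summarize_groups(
    data.frame(species_code = "E", v = 1), meta, traits = "v"), "E")
})

test_that("study-shaped groups use species counts for the SE", {
  cfg <- panel_config(seed = 19)
  study <- simulate_study(cfg)
  fits <- fit_curves(study$curves)
  der <- derive_traits(study$traits, fits)
  gs <- summarize_groups(der, tiny_species_meta(study$panel),
                         traits = "a_max_mass")
  expect_equal(gs$n[gs$group == "native_evergreen"], 13)
  expect_equal(gs$n[gs$group == "native_deciduous"], 3)
  expect_equal(gs$n[gs$group == "invasive"], 3)
  expect_equal(gs$n[gs$group == "all_native"], 16)
})
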