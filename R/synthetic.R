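#' Configuration for the synthetic study-design generator
#'
#' Builds the configuration object consumed by [generate_panel()],
#' [simulate_light_curves()] and [simulate_trait_table()]. The defaults
#' emulate a temperate-forest native/invasive woody-species comparison:
#' 19 species (13 native evergreen, 3 native deciduous, 3 invasive — all
#' invasives deciduous), 4--14 individuals per species, and a 12-step
#' light-response sequence per individual measured from saturating light
#' down to darkness (two irradiance levels are revisited on the way
#' down, so 1000 and 800 each appear twice; the repeats are kept as
#' distinct observations).
#'
#' Group effects are multiplicative shifts applied to species means
#' (value 1 = no effect). Species- and individual-level random effects
#' act on the log scale for positive parameters and on the logit scale
#' for the convexity \code{theta}, which keeps every draw inside its
#' physiological bounds.
#'
#' @param n_native_evergreen,n_native_deciduous,n_invasive species counts
#'   per group; all invasive species are deciduous.
#' @param individuals_range integer length-2: min/max individuals per
#'   species (drawn uniformly).
#' @param ppfd_sequence irradiance steps (umol photons m-2 s-1) at which
#'   each individual's curve is recorded.
#' @param noise_sd_a additive Gaussian measurement noise SD on net
#'   assimilation (umol CO2 m-2 s-1).
#' @param base_params named list of group-baseline (native evergreen)
#'   light-response parameters: \code{a_max_area}, \code{phi},
#'   \code{theta}, \code{r_d_area}.
#' @param base_traits named list of baseline species trait means:
#'   \code{sla} (cm2 g-1), \code{n_mass}, \code{c_mass}, \code{ash},
#'   \code{ldmc} (g g-1), \code{thickness} (mm), \code{leaf_area} (cm2),
#'   \code{chl_index}.
#' @param group_effects named list of multiplicative shifts:
#'   \code{habit_a_max} (deciduous vs evergreen A_max),
#'   \code{habit_sla}, \code{habit_n_mass}, \code{habit_ldmc},
#'   \code{habit_thickness}, \code{habit_leaf_area},
#'   \code{nativity_leaf_area} (invasive vs native), and optional
#'   \code{nativity_a_max}. Pass \code{zero_group_effects(config)} or set
#'   all to 1 for a no-difference panel.
#' @param species_sd,individual_sd named lists of random-effect SDs (log
#'   scale; logit scale for \code{theta}) for \code{a_max}, \code{phi},
#'   \code{theta}, \code{r_d}, plus \code{traits} (shared log-SD for all
#'   trait means at that level).
#' @param wue_true target water-use efficiency (umol CO2 mmol-1 H2O) used
#'   to generate transpiration; constant per species up to a species-level
#'   log-scale random effect of SD \code{species_sd$traits}.
#' @param nmass_sla_slope named numeric: within-habit individual-level
#'   log-log scaling slope of N_mass on SLA for \code{evergreen} and
#'   \code{deciduous} leaves.
#' @param nmass_noise_sd residual SD of individual log N_mass around the
#'   within-habit scaling line.
#' @param seed integer seed; identical configurations produce
#'   byte-identical tables.
#' @return A list of class \code{"panel_config"}.
#' @export
panel_config <- function(n_native_evergreen = 13,
                         n_native_deciduous = 3,
                         n_invasive = 3,
                         individuals_range = c(4L, 14L),
                         ppfd_sequence = c(800, 1000, 1300, 1000, 800, 500,
                                           300, 200, 100, 50, 20, 0),
                         noise_sd_a = 0.3,
                         base_params = list(a_max_area = 7.6, phi = 0.059,
                                            theta = 0.8, r_d_area = 0.75),
                         base_traits = list(sla = 165, n_mass = 0.025,
                                            c_mass = 0.488, ash = 0.065,
                                            ldmc = 0.28, thickness = 0.25,
                                            leaf_area = 64, chl_index = 47),
                         group_effects = list(habit_a_max = 1.75,
                                              nativity_a_max = 1,
                                              habit_sla = 1.35,
                                              habit_n_mass = 1.3,
                                              habit_ldmc = 0.85,
                                              habit_thickness = 0.78,
                                              habit_leaf_area = 0.67,
                                              nativity_leaf_area = 3.4),
                         species_sd = list(a_max = 0.15, phi = 0.03,
                                           theta = 0.3, r_d = 0.15,
                                           traits = 0.12),
                         individual_sd = list(a_max = 0.10, phi = 0.02,
                                              theta = 0.2, r_d = 0.10,
                                              traits = 0.08),
                         wue_true = 6,
                         nmass_sla_slope = c(evergreen = 0.9, deciduous = 0.45),
                         nmass_noise_sd = 0.05,
                         seed = 1L) {
  cfg <- list(n_native_evergreen = as.integer(n_native_evergreen),
              n_native_deciduous = as.integer(n_native_deciduous),
              n_invasive = as.integer(n_invasive),
              individuals_range = as.integer(individuals_range),
              ppfd_sequence = as.numeric(ppfd_sequence),
              noise_sd_a = noise_sd_a,
              base_params = base_params,
              base_traits = base_traits,
              group_effects = group_effects,
              species_sd = species_sd,
              individual_sd = individual_sd,
              wue_true = wue_true,
              nmass_sla_slope = nmass_sla_slope,
              nmass_noise_sd = nmass_noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "panel_config"
  validate_panel_config(cfg)
}

validate_panel_config <- function(cfg) {
  counts <- c(cfg$n_native_evergreen, cfg$n_native_deciduous, cfg$n_invasive)
  if (any(!is.finite(counts)) || any(counts < 0) || sum(counts) < 1)
    stop("species counts must be non-negative with at least one species",
         call. = FALSE)
  if (length(cfg$ppfd_sequence) == 0 || any(cfg$ppfd_sequence < 0))
    stop("ppfd_sequence must be a non-empty vector of irradiances >= 0",
         call. = FALSE)
  if (length(cfg$individuals_range) != 2 || any(cfg$individuals_range < 1) ||
      cfg$individuals_range[1] > cfg$individuals_range[2])
    stop("individuals_range must be (min, max) with 1 <= min <= max",
         call. = FALSE)
  if (cfg$noise_sd_a < 0) stop("noise_sd_a must be >= 0", call. = FALSE)
  bp <- cfg$base_params
  if (bp$a_max_area <= 0 || bp$phi <= 0 || bp$phi > 0.125 ||
      bp$theta <= 0 || bp$theta > 1 || bp$r_d_area < 0)
    stop("base_params violate NRH parameter bounds", call. = FALSE)
  cfg
}

#' Remove all group effects from a panel configuration
#'
#' Returns a copy of the configuration with every multiplicative group
#' shift set to 1, i.e. a panel in which nativity and leaf habit carry no
#' true signal.
#' @param config a [panel_config()] object.
#' @return The modified configuration.
#' @export
zero_group_effects <- function(config) {
  config$group_effects[] <- lapply(config$group_effects, function(x) 1)
  config$nmass_sla_slope[] <- mean(config$nmass_sla_slope)
  config
}

#' Remove all species- and individual-level random variation
#'
#' Sets every random-effect SD and the N_mass scaling noise to zero, so
#' species means equal their group means and individuals equal their
#' species means exactly.
#' @param config a [panel_config()] object.
#' @return The modified configuration.
#' @export
zero_random_effects <- function(config) {
  config$species_sd[] <- lapply(config$species_sd, function(x) 0)
  config$individual_sd[] <- lapply(config$individual_sd, function(x) 0)
  config$nmass_noise_sd <- 0
  config
}

#' Generate the species panel
#'
#' Draws the species-level design: codes, nativity, leaf habit, number of
#' individuals, true light-response parameters and trait means. Deciduous
#' species receive the configured multiplicative shift on A_max;
#' leaf-area shifts by habit and nativity, SLA/N_mass/LDMC/thickness
#' shifts by habit. Species-level scatter is log-normal (logit-normal for
#' theta) with the configured SDs.
#'
#' @param config a [panel_config()] object.
#' @return A data.frame of class \code{"species_panel"}, one row per
#'   species, with columns \code{species_code}, \code{nativity},
#'   \code{leaf_habit}, \code{n_individuals}, true parameters
#'   (\code{a_max_area}, \code{phi}, \code{theta}, \code{r_d_area},
#'   \code{wue}) and trait means (\code{sla}, \code{n_mass},
#'   \code{c_mass}, \code{ash}, \code{ldmc}, \code{thickness},
#'   \code{leaf_area}, \code{chl_index}).
#' @export
#' @examples
#' panel <- generate_panel(panel_config(seed = 42))
#' table(panel$nativity, panel$leaf_habit)
generate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  validate_panel_config(config)
  n_e <- config$n_native_evergreen
  n_d <- config$n_native_deciduous
  n_i <- config$n_invasive
  code <- c(sprintf("NE%02d", seq_len(n_e)),
            sprintf("ND%02d", seq_len(n_d)),
            sprintf("IN%02d", seq_len(n_i)))
  nativity <- c(rep("native", n_e + n_d), rep("invasive", n_i))
  leaf_habit <- c(rep("evergreen", n_e), rep("deciduous", n_d + n_i))
  n_sp <- length(code)
  ge <- config$group_effects
  bp <- config$base_params
  bt <- config$base_traits
  ssd <- config$species_sd

  with_seed(config$seed + 101L, {
    n_ind <- sample(seq(config$individuals_range[1], config$individuals_range[2]),
                    n_sp, replace = TRUE)
    dec <- leaf_habit == "deciduous"
    inv <- nativity == "invasive"

    mu_amax <- bp$a_max_area *
      ifelse(dec, ge$habit_a_max, 1) * ifelse(inv, ge$nativity_a_max %||% 1, 1)
    a_max <- mu_amax * exp(stats::rnorm(n_sp, 0, ssd$a_max))
    phi <- pmin(bp$phi * exp(stats::rnorm(n_sp, 0, ssd$phi)), 0.124)
    theta <- inv_logit(logit(bp$theta) + stats::rnorm(n_sp, 0, ssd$theta))
    r_d <- bp$r_d_area * exp(stats::rnorm(n_sp, 0, ssd$r_d))
    wue <- config$wue_true * exp(stats::rnorm(n_sp, 0, ssd$traits))

    tr_mult <- function(base, habit_key = NULL, nativity_key = NULL) {
      m <- rep(base, n_sp)
      if (!is.null(habit_key)) m <- m * ifelse(dec, ge[[habit_key]] %||% 1, 1)
      if (!is.null(nativity_key)) m <- m * ifelse(inv, ge[[nativity_key]] %||% 1, 1)
      m * exp(stats::rnorm(n_sp, 0, ssd$traits))
    }
    sla <- tr_mult(bt$sla, "habit_sla")
    # Leaf-economics coordination: species N_mass scales with species SLA
    # along the habit-specific log-log slope, with residual scatter, so
    # the bivariate relationship exists between species as well as
    # within them.
    slope_sp <- unname(config$nmass_sla_slope[leaf_habit])
    mu_sla <- bt$sla * ifelse(dec, ge$habit_sla %||% 1, 1)
    mu_n <- bt$n_mass * ifelse(dec, ge$habit_n_mass %||% 1, 1)
    n_mass <- mu_n * exp(slope_sp * (log(sla) - log(mu_sla)) +
                           stats::rnorm(n_sp, 0, config$nmass_noise_sd))
    c_mass <- pmin(tr_mult(bt$c_mass), 0.95)
    ash <- pmin(tr_mult(bt$ash), 0.5)
    ldmc <- pmin(tr_mult(bt$ldmc, "habit_ldmc"), 1)
    thickness <- tr_mult(bt$thickness, "habit_thickness")
    leaf_area <- tr_mult(bt$leaf_area, "habit_leaf_area", "nativity_leaf_area")
    chl_index <- tr_mult(bt$chl_index)

    panel <- data.frame(species_code = code, nativity = nativity,
                        leaf_habit = leaf_habit, n_individuals = n_ind,
                        a_max_area = a_max, phi = phi, theta = theta,
                        r_d_area = r_d, wue = wue,
                        sla = sla, n_mass = n_mass, c_mass = c_mass,
                        ash = ash, ldmc = ldmc, thickness = thickness,
                        leaf_area = leaf_area, chl_index = chl_index,
                        stringsAsFactors = FALSE)
    class(panel) <- c("species_panel", "data.frame")
    panel
  })
}

panel_individual_ids <- function(panel) {
  unlist(lapply(seq_len(nrow(panel)), function(s)
    sprintf("%s_%02d", panel$species_code[s], seq_len(panel$n_individuals[s]))),
    use.names = FALSE)
}

# Individual-level true parameters: species values perturbed on log/logit scale.
draw_individual_params <- function(panel, config) {
  isd <- config$individual_sd
  rows <- lapply(seq_len(nrow(panel)), function(s) {
    n <- panel$n_individuals[s]
    data.frame(
      individual_id = sprintf("%s_%02d", panel$species_code[s], seq_len(n)),
      species_code = panel$species_code[s],
      a_max = panel$a_max_area[s] * exp(stats::rnorm(n, 0, isd$a_max)),
      phi = pmin(panel$phi[s] * exp(stats::rnorm(n, 0, isd$phi)), 0.1249),
      theta = inv_logit(logit(panel$theta[s]) + stats::rnorm(n, 0, isd$theta)),
      r_d = panel$r_d_area[s] * exp(stats::rnorm(n, 0, isd$r_d)),
      wue = panel$wue[s],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate light-response curves for a species panel
#'
#' For every individual, draws true NRH parameters around its species'
#' values (log/logit-scale random effects), evaluates the NRH forward
#' model at each irradiance step, and adds Gaussian measurement noise.
#' Transpiration is generated as predicted assimilation divided by the
#' species' true water-use efficiency (floored at a small positive flux),
#' so that at saturating light A_net / E recovers the configured WUE.
#'
#' @param panel a [generate_panel()] result.
#' @param config the same [panel_config()] used to build the panel.
#' @return A data.frame with one row per (individual, PPFD step):
#'   \code{individual_id}, \code{species_code}, \code{ppfd}, \code{a_net},
#'   \code{e_trans}. The individual-level ground-truth parameters are
#'   attached as \code{attr(, "truth")}.
#' @export
simulate_light_curves <- function(panel, config) {
  stopifnot(inherits(config, "panel_config"))
  if (nrow(panel) == 0) stop("panel is empty", call. = FALSE)
  q <- config$ppfd_sequence
  with_seed(config$seed + 202L, {
    truth <- draw_individual_params(panel, config)
    n_ind <- nrow(truth)
    n_q <- length(q)
    pred <- vapply(seq_len(n_ind), function(j)
      nrh_gross(q, truth$a_max[j], truth$phi[j], truth$theta[j]) - truth$r_d[j],
      numeric(n_q))
    a_net <- as.vector(pred) + stats::rnorm(n_ind * n_q, 0, config$noise_sd_a)
    e_trans <- pmax(as.vector(pred) / rep(truth$wue, each = n_q), 0.05)
    out <- data.frame(
      individual_id = rep(truth$individual_id, each = n_q),
      species_code = rep(truth$species_code, each = n_q),
      ppfd = rep(q, times = n_ind),
      a_net = a_net,
      e_trans = e_trans,
      stringsAsFactors = FALSE)
    attr(out, "truth") <- truth
    out
  })
}

#' Simulate the per-individual trait table
#'
#' Draws individual traits log-normally around species means. Individual
#' N_mass follows the configured within-habit log-log scaling with SLA:
#' an individual's deviation of log N_mass from its species mean equals
#' the habit's slope times its deviation in log SLA, plus residual noise.
#' All traits are strictly positive; LDMC is capped at 1.
#'
#' @param panel a [generate_panel()] result.
#' @param config the same [panel_config()] used to build the panel.
#' @return A data.frame with one row per individual: \code{individual_id},
#'   \code{species_code}, \code{sla}, \code{ldmc}, \code{thickness},
#'   \code{leaf_area}, \code{c_mass}, \code{n_mass}, \code{ash},
#'   \code{chl_index}.
#' @export
simulate_trait_table <- function(panel, config) {
  stopifnot(inherits(config, "panel_config"))
  if (nrow(panel) == 0) stop("panel is empty", call. = FALSE)
  isd <- config$individual_sd$traits
  with_seed(config$seed + 303L, {
    rows <- lapply(seq_len(nrow(panel)), function(s) {
      n <- panel$n_individuals[s]
      habit <- panel$leaf_habit[s]
      slope <- unname(config$nmass_sla_slope[habit])
      dlog_sla <- stats::rnorm(n, 0, isd)
      sla <- panel$sla[s] * exp(dlog_sla)
      n_mass <- panel$n_mass[s] *
        exp(slope * dlog_sla + stats::rnorm(n, 0, config$nmass_noise_sd))
      data.frame(
        individual_id = sprintf("%s_%02d", panel$species_code[s], seq_len(n)),
        species_code = panel$species_code[s],
        sla = sla,
        ldmc = pmin(panel$ldmc[s] * exp(stats::rnorm(n, 0, isd)), 1),
        thickness = panel$thickness[s] * exp(stats::rnorm(n, 0, isd)),
        leaf_area = panel$leaf_area[s] * exp(stats::rnorm(n, 0, isd)),
        c_mass = pmin(panel$c_mass[s] * exp(stats::rnorm(n, 0, isd)), 0.95),
        n_mass = pmin(n_mass, 0.5),
        ash = pmin(panel$ash[s] * exp(stats::rnorm(n, 0, isd)), 0.6),
        chl_index = panel$chl_index[s] * exp(stats::rnorm(n, 0, isd)),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: builds the panel and both tables from one
#' configuration.
#' @param config a [panel_config()] object.
#' @return A list with \code{panel}, \code{curves}, \code{traits},
#'   \code{truth} (individual-level true parameters) and \code{config}.
#' @export
simulate_study <- function(config = panel_config()) {
  panel <- generate_panel(config)
  curves <- simulate_light_curves(panel, config)
  list(panel = panel, curves = curves,
       traits = simulate_trait_table(panel, config),
       truth = attr(curves, "truth"),
       config = config)
}

#' Write a synthetic study to disk
#'
#' Writes \code{light_curves.csv}, \code{traits.csv}, \code{species.csv}
#' and \code{truth.json} (ground-truth parameters for recovery checks)
#' into \code{dir}.
#' @param dir output directory (created if absent).
#' @param config a [panel_config()] object.
#' @return Invisibly, the [simulate_study()] bundle.
#' @export
write_synthetic_data <- function(dir, config = panel_config()) {
  study <- simulate_study(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$curves, file.path(dir, "light_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(study$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  species <- study$panel[, c("species_code", "nativity", "leaf_habit")]
  utils::write.csv(species, file.path(dir, "species.csv"), row.names = FALSE)
  truth <- list(species = study$panel, individuals = study$truth,
                seed = config$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA, auto_unbox = TRUE)
  invisible(study)
}
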