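#' Reference group-mean trait values
#'
#' Published-scale group means (native evergreen, native deciduous,
#' invasive, and all natives pooled) for the trait set of a temperate
#' New Zealand native/invasive woody-species comparison: the values this
#' package's synthetic defaults are calibrated to. Concentrations are
#' stored as mass fractions (g g-1), gas exchange per area in
#' umol CO2 m-2 s-1 (mass basis nmol g-1 s-1), SLA in cm2 g-1, leaf area
#' in cm2, construction cost in g glucose g-1 (area basis g m-2).
#'
#' These serve two purposes: defaults for [group_contrast_ratios()]
#' demonstrations, and desk checks of the construction-cost and
#' conversion arithmetic at realistic trait values.
#'
#' @return data.frame with columns \code{trait}, \code{group},
#'   \code{mean}, \code{se}.
#' @export
#' @examples
#' rg <- reference_group_means()
#' subset(rg, trait == "a_max_mass")
reference_group_means <- function() {
  tr <- function(trait, all_native, evergreen, deciduous, invasive,
                 se = c(NA, NA, NA, NA)) {
    data.frame(trait = trait,
               group = c("all_native", "native_evergreen",
                         "native_deciduous", "invasive"),
               mean = c(all_native, evergreen, deciduous, invasive),
               se = se, stringsAsFactors = FALSE)
  }
  rbind(
    tr("a_max_area", 8.4, 7.62, 11.8, 14.8, c(0.6, 0.5, 1.6, 1.5)),
    tr("a_max_mass", 167, 138, 284, 294, c(23, 19, 46, 13)),
    tr("r_d_area", 0.76, 0.77, 0.72, 0.66, c(0.04, 0.05, 0.07, 0.01)),
    tr("r_d_mass", 14.7, 14.1, 17.4, 13.3, c(1.8, 2.1, 3.2, 1.1)),
    tr("amax_over_rd", 12, 11, 18, 23, c(1, 1, 5, 13)),
    tr("phi", 0.059, 0.059, 0.060, 0.061, c(0.001, 0.001, 0.001, 0.002)),
    tr("lcp", 13.1, 13.4, 11.8, 10.8, c(0.9, 1.1, 1.1, 0.1)),
    tr("sla", 184, 165, 251, 205, c(5, 5, 12, 9)),
    tr("ldmc", 0.27, 0.28, 0.22, 0.26, c(0.02, 0.02, 0.02, 0.02)),
    tr("thickness", 0.243, 0.252, 0.201, 0.187,
       c(0.005, 0.005, 0.007, 0.005)),
    tr("leaf_area", 60, 64, 43, 145, c(5, 6, 4, 6)),
    tr("c_mass", 0.4843, 0.4886, 0.4667, 0.4758,
       c(0.0065, 0.0076, 0.0050, 0.0065)),
    tr("c_area", 33.45, 36.35, 21.86, 27.14, c(4.59, 5.43, 2.33, 1.93)),
    tr("n_mass", 0.0264, 0.0251, 0.0316, 0.0341,
       c(0.0021, 0.0025, 0.0008, 0.0029)),
    tr("n_area", 1.58, 1.61, 1.46, 1.89, c(0.13, 0.16, 0.20, 0.15)),
    tr("chl_index", 46, 48, 39, 47, c(2, 3, 4, 5)),
    tr("ash", 0.067, 0.064, 0.079, 0.073, c(0.006, 0.007, 0.011, 0.008)),
    tr("cc_mass", 1.50, 1.51, 1.43, 1.49, c(0.03, 0.04, 0.03, 0.02)),
    tr("cc_area", 103.8, 113.1, 66.8, 85.0, c(14.4, 17.0, 6.5, 6.1)),
    tr("pnue", 5.71, 5.03, 8.46, 7.79, c(0.56, 0.41, 1.62, 0.26)),
    tr("peue", 115, 94, 198, 198, c(17, 14, 29, 11)),
    tr("wue", 6.41, 6.72, 5.16, 6.40, c(0.81, 0.99, 0.29, 0.69)))
}

#' Default contrast specification for the headline group comparisons
#'
#' The standard set of habit and nativity contrasts: percent-lower
#' A_max (mass and area basis) for evergreens versus the pooled
#' deciduous mean, percent-greater PNUE/PEUE for deciduous versus
#' evergreen, and the invasive/native leaf-area fold and percent
#' difference. The pooled deciduous mean is the unweighted average of
#' the native-deciduous and invasive group means.
#'
#' @return data.frame with columns \code{trait}, \code{type}
#'   (\code{percent_lower}, \code{percent_greater} or \code{fold}),
#'   \code{group_a}, \code{group_b}. The contrast compares a to b.
#' @export
default_contrasts <- function() {
  data.frame(
    trait = c("a_max_mass", "a_max_area", "pnue", "peue",
              "leaf_area", "leaf_area"),
    type = c("percent_lower", "percent_lower", "percent_greater",
             "percent_greater", "fold", "percent_greater"),
    group_a = c("native_evergreen", "native_evergreen", "deciduous_pooled",
                "deciduous_pooled", "invasive", "invasive"),
    group_b = c("deciduous_pooled", "deciduous_pooled", "native_evergreen",
                "native_evergreen", "all_native", "all_native"),
    stringsAsFactors = FALSE)
}

#' Headline group-contrast ratios
#'
#' Computes percent differences and fold ratios between named group
#' means, with the reporting conventions: percent-lower = (1 - a/b) x
#' 100 rounded to the nearest integer; percent-greater = (a/b - 1) x 100
#' rounded to the nearest integer; fold = a/b rounded to one decimal.
#' The pseudo-group \code{"deciduous_pooled"} is the unweighted average
#' of the \code{native_deciduous} and \code{invasive} means. Every
#' reported number carries the group means that produced it, so the
#' report is recomputable from the summary table.
#'
#' @param summary a group-summary table (columns \code{trait},
#'   \code{group}, \code{mean}), e.g. [summarize_groups()] output or
#'   [reference_group_means()].
#' @param contrasts contrast specification as in [default_contrasts()].
#' @return data.frame of class \code{"contrast_report"}: \code{trait},
#'   \code{type}, \code{group_a}, \code{group_b}, \code{mean_a},
#'   \code{mean_b}, \code{ratio} (unrounded a/b), \code{value} (rounded
#'   per convention), \code{direction}.
#' @export
#' @examples
#' group_contrast_ratios(reference_group_means())
group_contrast_ratios <- function(summary, contrasts = default_contrasts()) {
  assert_columns(summary, c("trait", "group", "mean"), "group summary")
  assert_columns(contrasts, c("trait", "type", "group_a", "group_b"),
                 "contrast spec")
  get_mean <- function(trait, group) {
    if (group == "deciduous_pooled") {
      return(mean(c(get_mean(trait, "native_deciduous"),
                    get_mean(trait, "invasive"))))
    }
    row <- summary$trait == trait & summary$group == group
    if (!any(row))
      stop(sprintf("summary lacks group '%s' for trait '%s'", group, trait),
           call. = FALSE)
    summary$mean[row][1]
  }
  rows <- lapply(seq_len(nrow(contrasts)), function(i) {
    ct <- contrasts[i, ]
    a <- get_mean(ct$trait, ct$group_a)
    b <- get_mean(ct$trait, ct$group_b)
    ratio <- if (is.finite(b) && b != 0) a / b else NA_real_
    value <- switch(ct$type,
                    percent_lower = round((1 - ratio) * 100),
                    percent_greater = round((ratio - 1) * 100),
                    fold = round(ratio, 1),
                    stop("unknown contrast type: ", ct$type, call. = FALSE))
    data.frame(trait = ct$trait, type = ct$type, group_a = ct$group_a,
               group_b = ct$group_b, mean_a = a, mean_b = b,
               ratio = ratio, value = value,
               direction = if (!is.finite(ratio)) NA_character_ else
                 if (ratio >= 1) "greater" else "lower",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("contrast_report", "data.frame")
  out
}

#' Pipeline configuration
#'
#' Bundles every stage's settings for [run_full_analysis()].
#'
#' @param panel a [panel_config()] for the synthetic study (ignored when
#'   reading data from \code{input_dir}).
#' @param sampler an [hb_config()] for the hierarchical light-response
#'   fit (its \code{group_by} is set from \code{hb_group_by}).
#' @param hb_group_by metadata columns defining top-level groups in the
#'   light-response fit.
#' @param group_model_traits traits passed through the univariate
#'   nativity/leaf-habit group model; named character vector mapping
#'   trait name to transform (\code{"log"} or \code{"identity"}). The
#'   default registry log-transforms traits spanning orders of magnitude
#'   (mass-basis rates, SLA, leaf area, PEUE) and keeps near-symmetric
#'   traits (LCP, phi, LDMC, thickness fractions) on the identity scale.
#' @param sma_pairs data.frame of trait pairs (\code{x}, \code{y}) for
#'   SMA comparison; default covers the A_max scaling set (R_d, N, CC,
#'   SLA on both bases) and the N-SLA pair.
#' @param sma_level \code{"individual"} or \code{"species"}: fit SMA to
#'   individual values or species means.
#' @param input_dir optional directory with \code{light_curves.csv},
#'   \code{traits.csv}, \code{species.csv}; when \code{NULL} the
#'   synthetic generator supplies the data.
#' @param out_dir optional output directory; when set, all result tables
#'   and a JSON run manifest are written there.
#' @param seed master seed, propagated to the generator and samplers.
#' @return list of class \code{"run_config"}.
#' @export
run_config <- function(panel = panel_config(seed = seed),
                       sampler = hb_config(seed = seed),
                       hb_group_by = "leaf_habit",
                       group_model_traits = c(
                         a_max_area = "log", a_max_mass = "log",
                         r_d_area = "log", r_d_mass = "log",
                         phi = "identity", lcp = "identity",
                         sla = "log", ldmc = "identity",
                         thickness = "identity", leaf_area = "log",
                         c_mass = "identity", n_mass = "log",
                         n_area = "log", ash = "log",
                         cc_mass = "identity", cc_area = "log",
                         pnue = "log", peue = "log", wue = "log",
                         amax_over_rd = "log"),
                       sma_pairs = data.frame(
                         x = c("r_d_mass", "n_mass", "cc_mass", "sla",
                               "r_d_area", "n_area", "cc_area", "sla",
                               "sla", "sla"),
                         y = c("a_max_mass", "a_max_mass", "a_max_mass",
                               "a_max_mass", "a_max_area", "a_max_area",
                               "a_max_area", "a_max_area",
                               "n_mass", "n_area"),
                         stringsAsFactors = FALSE),
                       sma_level = c("individual", "species"),
                       input_dir = NULL, out_dir = NULL, seed = 1L) {
  structure(list(panel = panel, sampler = sampler, hb_group_by = hb_group_by,
                 group_model_traits = group_model_traits,
                 sma_pairs = sma_pairs, sma_level = match.arg(sma_level),
                 input_dir = input_dir, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

read_study_inputs <- function(input_dir) {
  need <- c("light_curves.csv", "traits.csv", "species.csv")
  paths <- file.path(input_dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing))
    stop("input_dir lacks: ", paste(missing, collapse = ", "), call. = FALSE)
  curves <- utils::read.csv(paths[1], stringsAsFactors = FALSE)
  assert_columns(curves, c("individual_id", "species_code", "ppfd", "a_net"),
                 "light_curves.csv")
  traits <- utils::read.csv(paths[2], stringsAsFactors = FALSE)
  assert_columns(traits, c("individual_id", "species_code", "sla", "c_mass",
                           "n_mass", "ash"), "traits.csv")
  species <- utils::read.csv(paths[3], stringsAsFactors = FALSE)
  assert_columns(species, c("species_code", "nativity", "leaf_habit"),
                 "species.csv")
  list(curves = curves, traits = traits, species = species)
}

#' Run the complete analysis pipeline
#'
#' Orchestrates simulate (or load) -> per-curve least squares ->
#' hierarchical Bayesian light-response fit -> trait derivation ->
#' univariate group models -> group summary -> SMA comparisons ->
#' contrast report. All stages share one master seed; re-running the
#' same configuration reproduces every output.
#'
#' @param config a [run_config()] object.
#' @return list of class \code{"leafecon_run"} with \code{inputs},
#'   \code{curve_fits}, \code{hb_fit}, \code{derived}, \code{group_models},
#'   \code{group_effects} (tidy table), \code{group_summary},
#'   \code{sma_results}, \code{contrasts}, \code{manifest}. When
#'   \code{config$out_dir} is set the tables are also written as CSV plus
#'   a JSON manifest.
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$input_dir)) {
    study <- simulate_study(config$panel)
    inputs <- list(curves = study$curves, traits = study$traits,
                   species = study$panel[, c("species_code", "nativity",
                                             "leaf_habit")])
  } else {
    inputs <- read_study_inputs(config$input_dir)
  }
  species_meta <- inputs$species
  n_species_in <- length(unique(inputs$curves$species_code))

  curve_fits <- fit_curves(inputs$curves)
  sampler <- config$sampler
  sampler$group_by <- config$hb_group_by
  hb <- fit_hierarchical(inputs$curves, species_meta, sampler)

  derived <- derive_traits(inputs$traits, curve_fits)
  meta_d <- species_meta[match(derived$species_code,
                               species_meta$species_code), ]
  derived$nativity <- meta_d$nativity
  derived$leaf_habit <- meta_d$leaf_habit

  reg <- config$group_model_traits
  reg <- reg[names(reg) %in% names(derived)]
  gm_cfg <- config$sampler
  group_models <- lapply(names(reg), function(tr) {
    vals <- data.frame(individual_id = derived$individual_id,
                       species_code = derived$species_code,
                       value = derived[[tr]])
    fit_group_model(vals, species_meta, gm_cfg, transform = reg[[tr]],
                    trait_name = tr)
  })
  names(group_models) <- names(reg)
  group_effects <- do.call(rbind, lapply(group_models, function(m) {
    if (isTRUE(m$degenerate) || isTRUE(m$inestimable))
      return(data.frame(trait = m$trait_name, transform = m$transform,
                        beta_nativity_low = NA_real_,
                        beta_nativity_high = NA_real_,
                        significant_nativity = NA,
                        beta_habit_low = NA_real_, beta_habit_high = NA_real_,
                        significant_habit = NA, max_rhat = NA_real_,
                        stringsAsFactors = FALSE))
    data.frame(trait = m$trait_name, transform = m$transform,
               beta_nativity_low = m$beta_nativity$ci_low,
               beta_nativity_high = m$beta_nativity$ci_high,
               significant_nativity = m$beta_nativity$significant,
               beta_habit_low = m$beta_leafhabit$ci_low,
               beta_habit_high = m$beta_leafhabit$ci_high,
               significant_habit = m$beta_leafhabit$significant,
               max_rhat = max(m$rhat), stringsAsFactors = FALSE)
  }))
  rownames(group_effects) <- NULL

  group_summary <- summarize_groups(derived, species_meta)
  stopifnot(sum(group_summary$n[group_summary$group %in%
                                  c("all_native", "invasive") &
                                  group_summary$trait ==
                                  group_summary$trait[1]]) == n_species_in)

  sma_data <- if (config$sma_level == "species") {
    sp <- stats::aggregate(derived[, intersect(unique(unlist(config$sma_pairs)),
                                               names(derived))],
                           by = list(species_code = derived$species_code),
                           FUN = mean, na.rm = TRUE)
    sp$leaf_habit <- species_meta$leaf_habit[match(sp$species_code,
                                                   species_meta$species_code)]
    sp
  } else derived
  sma_results <- lapply(seq_len(nrow(config$sma_pairs)), function(i)
    tryCatch(sma_compare_groups(sma_data, config$sma_pairs$x[i],
                                config$sma_pairs$y[i], "leaf_habit"),
             error = function(e) NULL))
  names(sma_results) <- paste(config$sma_pairs$y, config$sma_pairs$x,
                              sep = "~")
  sma_table <- do.call(rbind, lapply(names(sma_results), function(nm) {
    cmp <- sma_results[[nm]]
    if (is.null(cmp)) return(NULL)
    if (!cmp$prefilter_passed)
      return(data.frame(pair = nm, group = NA_character_, n = NA, slope = NA,
                        intercept = NA, r2 = NA, p = NA,
                        common_slope_p = NA, elevation_p = NA, shift_p = NA,
                        prefilter_passed = FALSE, stringsAsFactors = FALSE))
    do.call(rbind, lapply(names(cmp$fits), function(g) {
      f <- cmp$fits[[g]]
      data.frame(pair = nm, group = g, n = f$n, slope = f$slope,
                 intercept = f$intercept, r2 = f$r_squared, p = f$p_value,
                 common_slope_p = cmp$common_slope_p,
                 elevation_p = cmp$elevation_p, shift_p = cmp$shift_p,
                 prefilter_passed = TRUE, stringsAsFactors = FALSE)
    }))
  }))

  ct_spec <- default_contrasts()
  ct_spec <- ct_spec[ct_spec$trait %in% group_summary$trait, ]
  contrasts <- group_contrast_ratios(group_summary, ct_spec)

  manifest <- list(
    seed = config$seed,
    sampler = unclass(config$sampler)[c("chains", "iter", "burnin", "thin",
                                        "seed")],
    hb_group_by = config$hb_group_by,
    hb_converged = hb$converged, hb_max_rhat = hb$max_rhat,
    n_species = n_species_in,
    n_individuals = length(unique(inputs$curves$individual_id)),
    sma_level = config$sma_level,
    config_hash = sum(utils::object.size(config)))

  out <- structure(list(inputs = inputs, curve_fits = curve_fits,
                        hb_fit = hb, derived = derived,
                        group_models = group_models,
                        group_effects = group_effects,
                        group_summary = group_summary,
                        sma_results = sma_results, sma_table = sma_table,
                        contrasts = contrasts, manifest = manifest),
                   class = "leafecon_run")
  if (!is.null(config$out_dir)) write_run_outputs(out, config$out_dir)
  out
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  w(run$curve_fits, "curve_fits.csv")
  w(run$hb_fit$summary, "hb_summary.csv")
  w(species_posteriors(run$hb_fit), "species_curves.csv")
  w(run$derived, "traits_derived.csv")
  w(run$group_effects, "group_effects.csv")
  w(as.data.frame(run$group_summary), "group_summary.csv")
  w(run$sma_table, "sma_results.csv")
  w(as.data.frame(run$contrasts), "contrast_report.csv")
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.leafecon_run <- function(x, ...) {
  cat("leafecon pipeline run\n")
  cat(sprintf("  %d species, %d individuals, %d curve observations\n",
              x$manifest$n_species, x$manifest$n_individuals,
              nrow(x$inputs$curves)))
  cat(sprintf("  hierarchical fit: max rhat %.3f (%s)\n", x$manifest$hb_max_rhat,
              if (x$manifest$hb_converged) "converged" else "NOT CONVERGED"))
  cat("  headline contrasts:\n")
  print(as.data.frame(x$contrasts[, c("trait", "type", "value")]),
        row.names = FALSE)
  invisible(x)
}
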