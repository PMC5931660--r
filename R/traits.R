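#' Leaf construction cost from carbon, nitrogen and ash concentrations
#'
#' Glucose equivalents required to build one gram of leaf from its
#' elemental composition:
#' \deqn{CC_{mass} = (-1.041 + 5.077\, C_{mass})(1 - 0.67\, Ash) + 5.325\, N_{mass}}
#' with all inputs as mass fractions (g g-1). The first term is the
#' carbon-skeleton/reductant cost, the ash factor removes the mineral
#' fraction (which needs no carbon skeletons), and the nitrogen term is
#' the cost of reducing nitrate to organic N (nitrate is assumed to be
#' the dominant N source and leaf NO3- accumulation negligible).
#'
#' Inputs supplied in mg g-1 (values > 1) are auto-rescaled by 1/1000
#' with a warning: the formula only reproduces realistic costs
#' (~1.5 g glucose g-1) with fractional inputs.
#'
#' @param c_mass leaf carbon concentration (g C g-1).
#' @param n_mass leaf nitrogen concentration (g N g-1).
#' @param ash leaf ash (mineral) concentration (g g-1).
#' @return Construction cost (g glucose g-1 leaf). Vectorised.
#' @export
#' @examples
#' construction_cost(0.4843, 0.0264, 0.067)
construction_cost <- function(c_mass, n_mass, ash) {
  rescale <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0))
      stop(nm, " must be finite and >= 0", call. = FALSE)
    if (any(x > 1)) {
      if (any(x > 1000)) stop(nm, " outside [0, 1] even as mg g-1", call. = FALSE)
      warning(nm, " > 1: interpreting as mg g-1 and rescaling by 1/1000",
              call. = FALSE)
      x <- x / 1000
    }
    x
  }
  c_mass <- rescale(c_mass, "c_mass")
  n_mass <- rescale(n_mass, "n_mass")
  ash <- rescale(ash, "ash")
  (-1.041 + 5.077 * c_mass) * (1 - 0.67 * ash) + 5.325 * n_mass
}

#' Area/mass conversions through specific leaf area
#'
#' Gas-exchange rates are measured per unit leaf area while chemistry is
#' per unit dry mass; SLA (cm2 g-1) links the two. Unit bookkeeping:
#' \itemize{
#'   \item \code{amax_area_to_mass()}: umol m-2 s-1 x SLA cm2 g-1 x 0.1
#'     = nmol g-1 s-1 (and back).
#'   \item \code{mass_to_area()}: a per-gram mass fraction (g g-1) over
#'     SLA, x 1e4, gives g m-2 (and back). Used for N_area, C_area and
#'     CC_area.
#' }
#' All conversions are exact inverses of each other.
#'
#' @param a_max_area,a_max_mass photosynthetic rate per area
#'   (umol CO2 m-2 s-1) or per mass (nmol CO2 g-1 s-1). Also applies to
#'   respiration rates.
#' @param value_mass per-mass quantity (g g-1 for N/C fractions, or
#'   g glucose g-1 for construction cost).
#' @param value_area the corresponding per-area quantity (g m-2).
#' @param sla specific leaf area (cm2 g-1), > 0.
#' @return The converted quantity; vectorised.
#' @name mass_area
#' @export
#' @examples
#' amax_area_to_mass(10, sla = 200)          # 200 nmol g-1 s-1
#' mass_to_area(0.0264, sla = 184)           # ~1.43 g N m-2
amax_area_to_mass <- function(a_max_area, sla) {
  check_sla(sla)
  a_max_area * sla * 0.1
}

#' @rdname mass_area
#' @export
amax_mass_to_area <- function(a_max_mass, sla) {
  check_sla(sla)
  a_max_mass / (sla * 0.1)
}

#' @rdname mass_area
#' @export
mass_to_area <- function(value_mass, sla) {
  check_sla(sla)
  value_mass / sla * 1e4
}

#' @rdname mass_area
#' @export
area_to_mass <- function(value_area, sla) {
  check_sla(sla)
  value_area * sla / 1e4
}

check_sla <- function(sla) {
  if (any(!is.finite(sla)) || any(sla <= 0))
    stop("sla must be finite and > 0", call. = FALSE)
  invisible(sla)
}

#' Photosynthetic resource-use efficiencies
#'
#' Carbon return per unit resource invested:
#' \itemize{
#'   \item PNUE = A_max,area / N_area (umol CO2 g-1 N s-1),
#'   \item PEUE = A_max,area / CC_area x 1000 (umol CO2 kg-1 glucose s-1),
#'   \item WUE = A_max,area / E at saturating light
#'     (umol CO2 mmol-1 H2O),
#'   \item A_max/R_d, the dimensionless respiration efficiency.
#' }
#' Non-positive denominators yield \code{NA} for the affected ratio (an
#' explicitly undefined efficiency), never an error, so batch derivation
#' keeps going.
#'
#' @param a_max_area light-saturated photosynthetic rate (umol m-2 s-1).
#' @param r_d_area dark respiration rate (umol m-2 s-1).
#' @param n_area leaf nitrogen per area (g m-2).
#' @param cc_area construction cost per area (g glucose m-2).
#' @param e_trans_sat transpiration at saturating light (mmol H2O m-2 s-1).
#' @return data.frame with columns \code{pnue}, \code{peue}, \code{wue},
#'   \code{amax_over_rd}; vectorised over the inputs.
#' @export
#' @examples
#' efficiencies(7.62, 0.77, n_area = 1.61, cc_area = 113.1, e_trans_sat = 1.2)
efficiencies <- function(a_max_area, r_d_area = NA, n_area = NA,
                         cc_area = NA, e_trans_sat = NA) {
  safe_ratio <- function(num, den, scale = 1) {
    out <- ifelse(is.na(den) | den <= 0, NA_real_, num / den * scale)
    out
  }
  data.frame(
    pnue = safe_ratio(a_max_area, n_area),
    peue = safe_ratio(a_max_area, cc_area, 1000),
    wue = safe_ratio(a_max_area, e_trans_sat),
    amax_over_rd = safe_ratio(a_max_area, r_d_area))
}

#' Derive the full per-individual economics table
#'
#' Joins the measured trait table with per-individual light-response
#' estimates and computes every derived quantity: construction costs
#' (mass and area basis), area-based C and N, mass-based photosynthesis
#' and respiration, and the four efficiencies. Ratios are computed per
#' individual; group averages of these ratios (not ratios of group
#' averages) are what [summarize_groups()] reports.
#'
#' @param traits per-individual trait table (see
#'   [simulate_trait_table()] for the schema).
#' @param curve_fits per-individual parameter table from [fit_curves()]
#'   (or the species/individual summary of a hierarchical fit mapped to
#'   the same columns \code{individual_id}, \code{a_max}, \code{r_d},
#'   \code{e_trans_sat}).
#' @return The trait table augmented with \code{cc_mass}, \code{cc_area},
#'   \code{c_area}, \code{n_area}, \code{a_max_area}, \code{r_d_area},
#'   \code{a_max_mass}, \code{r_d_mass}, \code{lcp}, \code{pnue},
#'   \code{peue}, \code{wue}, \code{amax_over_rd}.
#' @export
derive_traits <- function(traits, curve_fits) {
  assert_columns(traits, c("individual_id", "species_code", "sla", "c_mass",
                           "n_mass", "ash"), "trait table")
  assert_columns(curve_fits, c("individual_id", "a_max", "r_d"), "curve fits")
  keep <- intersect(c("individual_id", "a_max", "phi", "theta", "r_d", "lcp",
                      "e_trans_sat"), names(curve_fits))
  out <- merge(traits, curve_fits[, keep], by = "individual_id",
               all.x = TRUE, sort = FALSE)
  out <- out[order(match(out$individual_id, traits$individual_id)), ]
  out$cc_mass <- construction_cost(out$c_mass, out$n_mass, out$ash)
  out$cc_area <- mass_to_area(out$cc_mass, out$sla)
  out$c_area <- mass_to_area(out$c_mass, out$sla)
  out$n_area <- mass_to_area(out$n_mass, out$sla)
  out$a_max_area <- out$a_max
  out$r_d_area <- out$r_d
  out$a_max_mass <- amax_area_to_mass(out$a_max, out$sla)
  out$r_d_mass <- amax_area_to_mass(out$r_d, out$sla)
  eff <- efficiencies(out$a_max_area, out$r_d_area, out$n_area, out$cc_area,
                      if ("e_trans_sat" %in% names(out)) out$e_trans_sat else NA)
  out$pnue <- eff$pnue
  out$peue <- eff$peue
  out$wue <- eff$wue
  out$amax_over_rd <- eff$amax_over_rd
  rownames(out) <- NULL
  out
}
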