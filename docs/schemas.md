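# CSV schemas

All files are plain UTF-8 CSV with a header row.

## Inputs

### light_curves.csv
| column | type | units | description |
|---|---|---|---|
| individual_id | string | — | unique per measured leaf/individual |
| species_code | string | — | must appear in species.csv |
| ppfd | numeric | umol photons m-2 s-1 | irradiance step (>= 0) |
| a_net | numeric | umol CO2 m-2 s-1 | net assimilation |
| e_trans | numeric | mmol H2O m-2 s-1 | transpiration (optional) |

Repeated irradiance levels within a curve are independent replicate
observations. A minimal instrument export with `PARi`/`Photo` columns can
be renamed to this schema before loading.

### traits.csv (one row per individual)
`individual_id`, `species_code`, `sla` (cm2 g-1), `ldmc` (g g-1),
`thickness` (mm), `leaf_area` (cm2), `c_mass` (g C g-1),
`n_mass` (g N g-1), `ash` (g g-1), `chl_index` (meter units).
Concentrations are mass fractions in [0, 1].

### species.csv
`species_code`, `nativity` (`native`/`invasive`),
`leaf_habit` (`deciduous`/`evergreen`).

## Outputs

- `curve_fits.csv` — per-individual least-squares estimates: `ok`,
  `a_max`, `phi`, `theta`, `r_d`, `lcp`, `sigma`, `n_obs`,
  `e_trans_sat`, `message`.
- `hb_summary.csv` — one row per monitored MCMC parameter: `parameter`,
  `level` (group/species/hyper), `label`, `mean`, `ci_low`, `ci_high`,
  `rhat`, `ess`.
- `species_curves.csv` — species-level posterior means and 95% CIs per
  parameter, plus the derived `lcp`.
- `traits_derived.csv` — traits.csv plus `cc_mass`, `cc_area`, `c_area`,
  `n_area`, `a_max_area`, `r_d_area`, `a_max_mass`, `r_d_mass`, `lcp`,
  `pnue`, `peue`, `wue`, `amax_over_rd`, `nativity`, `leaf_habit`.
- `group_effects.csv` — per trait: `transform`, nativity/habit 95% CI
  bounds, significance flags, `max_rhat`.
- `group_summary.csv` — `trait`, `group` (all_native, native_evergreen,
  native_deciduous, invasive), `mean`, `se` (over species means), `n`.
- `sma_results.csv` — per trait pair and group: `n`, `slope`,
  `intercept`, `r2`, `p`, `common_slope_p`, `elevation_p`, `shift_p`,
  `prefilter_passed`.
- `contrast_report.csv` — `trait`, `type` (percent_lower /
  percent_greater / fold), groups compared, the group means used,
  unrounded `ratio` and the rounded `value`.
- `manifest.json` — seed, sampler settings, convergence flag and
  maximum Gelman-Rubin statistic, species/individual counts.
- `truth.json` (synthetic studies) — species- and individual-level
  ground-truth parameters for recovery checks.
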