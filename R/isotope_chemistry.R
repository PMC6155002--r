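# Isotope conversions and the closed-vial 13C tracer mass balance.
#
# Conventions: delta-13C in per-mil vs VPDB; atom percent on the linear
# scale a = (1 + delta/1000) * 1.124, the working approximation used for
# IRMS data reduction near natural abundance and adopted here throughout;
# amounts in mmol per vessel.

#' Physical and isotopic constants
#'
#' Read-only constants used by the chemistry operations: the VPDB scale
#' factor (atom percent 13C at delta = 0), the equilibrium carbon isotope
#' fractionation between gaseous CO2 and dissolved bicarbonate at 25 C,
#' the gas constant, the molar mass and carbon count of 1,4-dioxane, the
#' molar mass of carbon, and the natural-abundance and tracer atom
#' percentages.
#'
#' @return A named list (a fresh copy on every call, so effectively
#'   immutable).
#' @export
#' @examples
#' sip_constants()$vpdb_scale_factor
sip_constants <- function() {
  list(
    vpdb_scale_factor = 1.124,      # atom % 13C at delta = 0
    epsilon_hco3 = -7.93,           # per mil, gaseous CO2 <-> HCO3-, 25 C
    gas_constant = 0.082057,        # L atm mol-1 K-1
    dioxane_molar_mass = 88.11,     # g mol-1
    carbons_per_dioxane = 4,
    carbon_molar_mass = 12.011,     # g mol-1
    background_atom_percent = 1.1,  # natural-abundance 13C
    tracer_atom_percent = 99        # labeled substrate
  )
}

#' Serum-vial geometry
#'
#' Volumes and temperature of the closed incubation vessel. Defaults are a
#' 123-ml serum vial holding 20 ml of sludge at 25 C.
#'
#' @param total_volume_l Total vessel volume (l).
#' @param liquid_volume_l Liquid (sludge) volume (l).
#' @param headspace_volume_l Headspace volume (l); must equal total minus
#'   liquid.
#' @param temperature_K Incubation temperature (K).
#' @return A list of class `vessel_geometry`.
#' @export
vessel_geometry <- function(total_volume_l = 0.123,
                            liquid_volume_l = 0.020,
                            headspace_volume_l = total_volume_l - liquid_volume_l,
                            temperature_K = 298.15) {
  stopifnot(total_volume_l > 0, liquid_volume_l > 0, headspace_volume_l > 0,
            temperature_K > 0)
  if (abs(liquid_volume_l + headspace_volume_l - total_volume_l) > 1e-12)
    stop("liquid_volume_l + headspace_volume_l must equal total_volume_l")
  structure(list(total_volume_l = total_volume_l,
                 liquid_volume_l = liquid_volume_l,
                 headspace_volume_l = headspace_volume_l,
                 temperature_K = temperature_K),
            class = "vessel_geometry")
}

#' Convert delta-13C (per mil, VPDB) to atom percent 13C
#'
#' Applies the linear conversion a = (1 + delta/1000) * 1.124.
#'
#' @param delta_per_mil Numeric vector of delta values (> -1000).
#' @return Atom percent 13C.
#' @export
#' @examples
#' delta_to_atom_percent(0)      # 1.124
#' delta_to_atom_percent(1000)   # 2.248
delta_to_atom_percent <- function(delta_per_mil) {
  if (any(delta_per_mil <= -1000))
    stop("delta_per_mil must be > -1000")
  (1 + delta_per_mil / 1000) * sip_constants()$vpdb_scale_factor
}

#' Convert atom percent 13C to delta-13C (per mil, VPDB)
#'
#' Exact inverse of [delta_to_atom_percent()].
#'
#' @param atom_percent Numeric vector of atom percentages (> 0).
#' @return delta-13C in per mil.
#' @export
#' @examples
#' atom_percent_to_delta(1.124)  # 0
atom_percent_to_delta <- function(atom_percent) {
  if (any(atom_percent <= 0)) stop("atom_percent must be > 0")
  (atom_percent / sip_constants()$vpdb_scale_factor - 1) * 1000
}

#' delta-13C of dissolved bicarbonate from delta-13C of gaseous CO2
#'
#' Applies the equilibrium relation
#' delta_HCO3 = (delta_CO2 - epsilon) / (1 + epsilon/1000),
#' with epsilon the gaseous-CO2/bicarbonate fractionation (-7.93 per mil
#' at 25 C).
#'
#' @param delta_co2_per_mil delta-13C of gaseous CO2 (per mil).
#' @param epsilon_per_mil Fractionation factor (per mil, > -1000).
#' @return delta-13C of dissolved bicarbonate (per mil).
#' @export
#' @examples
#' bicarbonate_delta(-7.93)  # 0
bicarbonate_delta <- function(delta_co2_per_mil,
                              epsilon_per_mil = sip_constants()$epsilon_hco3) {
  if (epsilon_per_mil <= -1000) stop("epsilon_per_mil must be > -1000")
  (delta_co2_per_mil - epsilon_per_mil) / (1 + epsilon_per_mil / 1000)
}

#' Headspace gas amount from partial pressure (ideal gas law)
#'
#' @param partial_pressure_atm Partial pressure (atm, >= 0).
#' @param geometry A [vessel_geometry()].
#' @return Amount in mmol.
#' @export
#' @examples
#' headspace_mmol(0.030)  # ~0.126 mmol in the default vial
headspace_mmol <- function(partial_pressure_atm, geometry = vessel_geometry()) {
  if (any(partial_pressure_atm < 0)) stop("partial_pressure_atm must be >= 0")
  k <- sip_constants()
  partial_pressure_atm * geometry$headspace_volume_l /
    (k$gas_constant * geometry$temperature_K) * 1000
}

#' Tracer-derived (excess) 13C in a carbon pool
#'
#' Background-corrected 13C content: total carbon times the atom-percent
#' excess over background, clipped at zero.
#'
#' @param total_mmol Total carbon in the pool (mmol).
#' @param atom_percent Measured atom percent 13C of the pool (<= 100).
#' @param background_atom_percent Background atom percent (default natural
#'   abundance, 1.1).
#' @return Excess 13C in mmol.
#' @export
excess_13c_mmol <- function(total_mmol, atom_percent,
                            background_atom_percent =
                              sip_constants()$background_atom_percent) {
  if (any(atom_percent > 100)) stop("atom_percent must be <= 100")
  if (any(atom_percent < 0) || any(background_atom_percent < 0))
    stop("atom percentages must be >= 0")
  pmax(0, total_mmol * (atom_percent - background_atom_percent) / 100)
}

#' 13C in degraded labeled 1,4-dioxane
#'
#' Converts a decrease in 1,4-dioxane concentration to mmol of
#' substrate-derived carbon per vessel (4 carbons per molecule,
#' 88.11 g/mol).
#'
#' @param dioxane_decrease_mg_per_l Concentration decrease (mg/l, >= 0).
#' @param liquid_volume_l Liquid volume of the vessel (l).
#' @return mmol of 13C per vessel.
#' @export
#' @examples
#' dioxane_13c_mmol(51, 0.020)  # ~0.0463
dioxane_13c_mmol <- function(dioxane_decrease_mg_per_l, liquid_volume_l) {
  if (any(dioxane_decrease_mg_per_l < 0) || any(liquid_volume_l < 0))
    stop("inputs must be >= 0")
  k <- sip_constants()
  dioxane_decrease_mg_per_l * liquid_volume_l / k$dioxane_molar_mass *
    k$carbons_per_dioxane
}

#' 13C tracer budget of a closed incubation
#'
#' Carbon recovery of the tracer: the percentage of degraded substrate 13C
#' recovered in the gaseous CO2 and dissolved inorganic carbon pools.
#'
#' @param degraded_13c_mmol 13C in degraded substrate (mmol, > 0).
#' @param gaseous_13c_mmol Excess 13C in headspace CO2 (mmol, >= 0).
#' @param dissolved_13c_mmol Excess 13C in dissolved inorganic carbon
#'   (mmol, >= 0).
#' @return A one-row tibble with the three pools and `recovery_percent`.
#' @export
#' @examples
#' tracer_budget(0.0466, 0.0144, 0.0201)  # recovery ~74%
tracer_budget <- function(degraded_13c_mmol, gaseous_13c_mmol,
                          dissolved_13c_mmol) {
  if (degraded_13c_mmol <= 0) stop("degraded_13c_mmol must be > 0")
  if (gaseous_13c_mmol < 0 || dissolved_13c_mmol < 0)
    stop("13C pools must be >= 0")
  tibble::tibble(
    degraded_13c_mmol = degraded_13c_mmol,
    gaseous_13c_mmol = gaseous_13c_mmol,
    dissolved_13c_mmol = dissolved_13c_mmol,
    recovery_percent = 100 * (gaseous_13c_mmol + dissolved_13c_mmol) /
      degraded_13c_mmol
  )
}

#' Contaminant removal efficiency
#'
#' @param influent_mg_per_l Influent concentration (mg/l, > 0).
#' @param effluent_mg_per_l Effluent concentration (mg/l, >= 0).
#' @return Removal efficiency in percent, floored at 0.
#' @export
#' @examples
#' removal_efficiency(20.0, 0.26)  # 98.7
removal_efficiency <- function(influent_mg_per_l, effluent_mg_per_l) {
  if (any(influent_mg_per_l <= 0)) stop("influent_mg_per_l must be > 0")
  if (any(effluent_mg_per_l < 0)) stop("effluent_mg_per_l must be >= 0")
  pmax(0, 100 * (influent_mg_per_l - effluent_mg_per_l) / influent_mg_per_l)
}

#' Analyze an incubation chemistry time series
#'
#' Runs the tracer mass balance over a chemistry table covering the 13C
#' (and, for paired background correction, the unlabeled) treatment:
#' converts measured delta-13C of headspace CO2 to atom percent, derives
#' the bicarbonate delta via the equilibrium fractionation, converts
#' headspace pressure and inorganic-carbon concentration to mmol pools,
#' background-corrects each pool, and closes the budget against the
#' degraded substrate at the final time point.
#'
#' Background atom percent defaults to the unlabeled-treatment measurement
#' at the same time point (`background = "paired"`); with
#' `background = "natural"` a flat natural-abundance 1.1 atom percent is
#' used for both pools.
#'
#' @param chem Tibble with columns `treatment`, `time_h`,
#'   `dioxane_mg_per_l`, `co2_headspace_atm`, `delta13c_co2_per_mil`,
#'   `ic_mg_per_l` (and optionally others), as written by
#'   [simulate_chemistry()].
#' @param geometry A [vessel_geometry()].
#' @param background `"paired"` or `"natural"`.
#' @return A list with `timepoints` (per-time atom percentages and excess
#'   13C pools, mmol) and `budget` (one-row [tracer_budget()] at the final
#'   time).
#' @export
analyze_chemistry <- function(chem, geometry = vessel_geometry(),
                              background = c("paired", "natural")) {
  background <- match.arg(background)
  k <- sip_constants()
  lab <- chem[chem$treatment == "13C", , drop = FALSE]
  if (!nrow(lab)) stop("chemistry table has no 13C treatment rows")
  lab <- lab[order(lab$time_h), , drop = FALSE]
  if (background == "paired") {
    unl <- chem[chem$treatment == "unlabeled", , drop = FALSE]
    if (!nrow(unl)) stop("paired background correction needs unlabeled rows")
    unl <- unl[order(unl$time_h), , drop = FALSE]
    if (!isTRUE(all.equal(lab$time_h, unl$time_h)))
      stop("13C and unlabeled treatments must share time points")
    bg_gas <- delta_to_atom_percent(unl$delta13c_co2_per_mil)
    bg_dis <- delta_to_atom_percent(bicarbonate_delta(unl$delta13c_co2_per_mil))
  } else {
    bg_gas <- bg_dis <- rep(k$background_atom_percent, nrow(lab))
  }
  a_gas <- delta_to_atom_percent(lab$delta13c_co2_per_mil)
  n_gas <- headspace_mmol(lab$co2_headspace_atm, geometry)
  gaseous <- excess_13c_mmol(n_gas, a_gas, bg_gas)
  a_dis <- delta_to_atom_percent(bicarbonate_delta(lab$delta13c_co2_per_mil))
  n_dis <- lab$ic_mg_per_l * geometry$liquid_volume_l / k$carbon_molar_mass
  dissolved <- excess_13c_mmol(n_dis, a_dis, bg_dis)
  degraded <- dioxane_13c_mmol(
    pmax(0, lab$dioxane_mg_per_l[1] - lab$dioxane_mg_per_l),
    geometry$liquid_volume_l
  )
  timepoints <- tibble::tibble(
    time_h = lab$time_h,
    co2_atom_percent = a_gas,
    hco3_atom_percent = a_dis,
    headspace_co2_mmol = n_gas,
    dissolved_ic_mmol = n_dis,
    gaseous_excess_13c_mmol = gaseous,
    dissolved_excess_13c_mmol = dissolved,
    degraded_13c_mmol = degraded
  )
  n <- nrow(timepoints)
  budget <- tracer_budget(degraded[n], gaseous[n], dissolved[n])
  list(timepoints = timepoints, budget = budget)
}
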