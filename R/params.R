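#' Fire-module parameters
#'
#' All constants of the fire probability chain and the elliptical-spread
#' geometry live in this one record; no fire-path literal is hard-coded
#' elsewhere. Defaults for the probability chain are the published model
#' constants; the lightning thresholds `F_low`/`F_high`, the per-class maximum
#' spread rates `u_max`, and the moisture-probability exponent are implementer
#' defaults (the published description defers their numeric values to the
#' underlying fire model), documented as non-canonical in the methods
#' vignette.
#'
#' @param biomass_lower kg C m-2 below which fire is not sustained (P_b = 0).
#' @param biomass_upper kg C m-2 above which fuel does not limit fire (P_b = 1).
#' @param pd_ref people km-2 reference density of the human-ignition law.
#' @param ignition_exp exponent of the human-ignition law.
#' @param suppression_rate km2 person-1 rate of the extinguishing law.
#' @param base_extinguish extinguishing probability at zero population.
#' @param a_rep km2 representative area the fire-occurrence probability refers to.
#' @param F_low,F_high cloud-to-ground flash-density thresholds
#'   (flashes km-2 month-1) between which the lightning scalar ramps 0 -> 1.
#' @param sigmoid_center,sigmoid_width ignition-sigmoid shape constants.
#' @param moisture_exp exponent of the moisture probability P_m = 1 - w^e.
#' @param u_max named vector of maximum fire spread rates (km h-1) per
#'   vegetation class.
#' @param wind_ref km h-1 e-folding wind speed of the wind spread modifier.
#' @param spread_wind_floor value of the wind modifier at zero wind.
#' @param lb_max maximum length-to-breadth ratio of the fire ellipse.
#' @param lb_wind_coef per (km h-1) rate at which the length-to-breadth ratio
#'   approaches `lb_max` with wind.
#' @param head_back_factor total (head + back) spread as a multiple of the
#'   head spread rate.
#' @return a validated list of class `fc_fire_params`.
#' @export
fire_params <- function(biomass_lower = 0.2, biomass_upper = 1.0,
                        pd_ref = 300, ignition_exp = 0.43,
                        suppression_rate = 0.025, base_extinguish = 0.5,
                        a_rep = 500, F_low = 0.25, F_high = 10,
                        sigmoid_center = 0.8, sigmoid_width = 0.1,
                        moisture_exp = 2,
                        u_max = c(natural = 0.45, tree = 0.35, grass = 0.55),
                        wind_ref = 15, spread_wind_floor = 0.1,
                        lb_max = 10, lb_wind_coef = 0.06,
                        head_back_factor = 1.1) {
  p <- list(biomass_lower = biomass_lower, biomass_upper = biomass_upper,
            pd_ref = pd_ref, ignition_exp = ignition_exp,
            suppression_rate = suppression_rate,
            base_extinguish = base_extinguish, a_rep = a_rep,
            F_low = F_low, F_high = F_high,
            sigmoid_center = sigmoid_center, sigmoid_width = sigmoid_width,
            moisture_exp = moisture_exp, u_max = u_max,
            wind_ref = wind_ref, spread_wind_floor = spread_wind_floor,
            lb_max = lb_max, lb_wind_coef = lb_wind_coef,
            head_back_factor = head_back_factor)
  validate_fire_params(p)
}

validate_fire_params <- function(p) {
  check_number(p$biomass_lower, "biomass_lower", lower = 0, key = "fire.biomass_lower")
  check_number(p$biomass_upper, "biomass_upper", lower = 0, key = "fire.biomass_upper")
  if (p$biomass_lower >= p$biomass_upper) {
    config_error("biomass_lower must be < biomass_upper", "fire.biomass_lower")
  }
  check_number(p$base_extinguish, "base_extinguish", lower = 1e-12, upper = 1,
               key = "fire.base_extinguish")
  if (p$F_low >= p$F_high) config_error("F_low must be < F_high", "fire.F_low")
  for (nm in c("pd_ref", "ignition_exp", "suppression_rate", "a_rep",
               "F_low", "wind_ref", "lb_wind_coef", "head_back_factor")) {
    check_number(p[[nm]], nm, lower = 0, key = paste0("fire.", nm))
  }
  check_number(p$lb_max, "lb_max", lower = 1, key = "fire.lb_max")
  check_number(p$spread_wind_floor, "spread_wind_floor", lower = 0, upper = 1,
               key = "fire.spread_wind_floor")
  if (!is.numeric(p$u_max) || is.null(names(p$u_max)) || any(p$u_max < 0)) {
    config_error("u_max must be a named non-negative numeric vector", "fire.u_max")
  }
  structure(p, class = "fc_fire_params")
}

#' Carbon-cycle parameters
#'
#' Constants of the two-pool (vegetation, litter+soil) carbon bookkeeping.
#'
#' @param cf_veg,cf_litter combustion factors: the fraction of the vegetation
#'   (resp. litter+soil) carbon in the burned area that is emitted.
#' @param fire_mortality fraction of the uncombusted vegetation in the burned
#'   area that is killed and transferred to litter; the remainder survives
#'   (fire in grass-dominated fire regions kills only part of the standing
#'   biomass).
#' @param k_veg yr-1 vegetation turnover rate (biomass transferred to litter).
#' @param k_litter yr-1 base decomposition rate of the litter+soil pool.
#' @param npp_gamma dimensionless CO2 sensitivity of NPP
#'   (xi = 1 + gamma * log(CO2/co2_ref), floored at 0): a logarithmic response
#'   that emulates downregulation of photosynthesis under rising CO2.
#' @param co2_ref ppm reference CO2 at which xi = 1.
#' @param luc_burn_frac fraction of cleared biomass emitted immediately on
#'   conversion to cropland; the remainder decays from the litter pool.
#' @param rh_wet_min moisture modifier of decomposition at zero wetness
#'   (r(w) = rh_wet_min + (1 - rh_wet_min) * w).
#' @param substeps number of substeps per model year (monthly by default).
#' @return a validated list of class `fc_carbon_params`.
#' @export
carbon_params <- function(cf_veg = 0.2, cf_litter = 0.6, fire_mortality = 0.2,
                          k_veg = 0.18, k_litter = 0.05,
                          npp_gamma = 0.35, co2_ref = 285,
                          luc_burn_frac = 0.5, rh_wet_min = 0.2,
                          substeps = 12L) {
  p <- list(cf_veg = cf_veg, cf_litter = cf_litter,
            fire_mortality = fire_mortality, k_veg = k_veg,
            k_litter = k_litter, npp_gamma = npp_gamma, co2_ref = co2_ref,
            luc_burn_frac = luc_burn_frac, rh_wet_min = rh_wet_min,
            substeps = as.integer(substeps))
  validate_carbon_params(p)
}

validate_carbon_params <- function(p) {
  for (nm in c("cf_veg", "cf_litter", "fire_mortality", "luc_burn_frac",
               "rh_wet_min")) {
    check_number(p[[nm]], nm, lower = 0, upper = 1, key = paste0("carbon.", nm))
  }
  for (nm in c("k_veg", "k_litter", "npp_gamma")) {
    check_number(p[[nm]], nm, lower = 0, key = paste0("carbon.", nm))
  }
  check_number(p$co2_ref, "co2_ref", lower = 1e-9, key = "carbon.co2_ref")
  check_number(p$substeps, "substeps", lower = 1, key = "carbon.substeps")
  structure(p, class = "fc_carbon_params")
}

#' Synthetic-forcing generator parameters
#'
#' Defaults define the study conditions of the factorial experiment: population
#' grows ~7x along a logistic curve with midpoint at the 1960-analog year,
#' cropland expands linearly from 5 to 15 million km2 (allocated greedily to
#' productive, populated cells), CO2 rises 285 -> 397 ppm, and climate carries
#' a seasonal cycle with AR(1) interannual wetness anomalies plus monthly
#' weather noise.
#'
#' @param land_frac uniform land fraction per cell (0.29 matches Earth's land
#'   area on the full sphere); set to 1 for an all-land planet.
#' @param growth_factor total population growth over the span.
#' @param pop_mean_density initial area-weighted mean population density
#'   (people km-2 of land).
#' @param pop_logistic_mid,pop_logistic_width years: midpoint and width of the
#'   logistic population growth curve.
#' @param crop_start_area,crop_end_area km2: global crop area at the first and
#'   last simulated year.
#' @param crop_max_frac maximum crop fraction a single cell can reach.
#' @param co2_start,co2_end ppm endpoints of the CO2 trajectory.
#' @param wet_seasonal_amp seasonal wetness amplitude (fraction).
#' @param wet_ar1 AR(1) coefficient of annual wetness anomalies.
#' @param wet_anom_sd standard deviation of annual wetness anomalies.
#' @param wet_month_sd standard deviation of independent monthly wetness noise.
#' @param climate_block years: length of the block recycled in frozen-climate
#'   mode.
#' @param lightning_max flashes km-2 month-1 at the tropical maximum of the
#'   synthetic lightning climatology.
#' @param npp_max kg C m-2 yr-1 scale of potential net primary productivity.
#' @return a validated list of class `fc_forcing_params`.
#' @export
forcing_params <- function(land_frac = 0.29,
                           growth_factor = 7, pop_mean_density = 0.6,
                           pop_logistic_mid = 110, pop_logistic_width = 30,
                           crop_start_area = 5e6, crop_end_area = 15e6,
                           crop_max_frac = 0.95,
                           co2_start = 285, co2_end = 397,
                           wet_seasonal_amp = 0.25, wet_ar1 = 0.3,
                           wet_anom_sd = 0.012, wet_month_sd = 0,
                           climate_block = 25L,
                           lightning_max = 4, npp_max = 1.4) {
  p <- list(land_frac = land_frac, growth_factor = growth_factor,
            pop_mean_density = pop_mean_density,
            pop_logistic_mid = pop_logistic_mid,
            pop_logistic_width = pop_logistic_width,
            crop_start_area = crop_start_area, crop_end_area = crop_end_area,
            crop_max_frac = crop_max_frac,
            co2_start = co2_start, co2_end = co2_end,
            wet_seasonal_amp = wet_seasonal_amp, wet_ar1 = wet_ar1,
            wet_anom_sd = wet_anom_sd, wet_month_sd = wet_month_sd,
            climate_block = as.integer(climate_block),
            lightning_max = lightning_max, npp_max = npp_max)
  validate_forcing_params(p)
}

validate_forcing_params <- function(p) {
  check_number(p$land_frac, "land_frac", lower = 1e-6, upper = 1,
               key = "forcing.land_frac")
  check_number(p$growth_factor, "growth_factor", lower = 1e-12,
               key = "forcing.growth_factor")
  check_number(p$pop_mean_density, "pop_mean_density", lower = 0,
               key = "forcing.pop_mean_density")
  check_number(p$crop_start_area, "crop_start_area", lower = 0,
               key = "forcing.crop_start_area")
  check_number(p$crop_end_area, "crop_end_area", lower = 0,
               key = "forcing.crop_end_area")
  if (p$crop_start_area > p$crop_end_area) {
    config_error("crop_start_area must be <= crop_end_area",
                 "forcing.crop_start_area")
  }
  check_number(p$crop_max_frac, "crop_max_frac", lower = 0, upper = 1,
               key = "forcing.crop_max_frac")
  check_number(p$co2_start, "co2_start", lower = 1e-9, key = "forcing.co2_start")
  check_number(p$co2_end, "co2_end", lower = 1e-9, key = "forcing.co2_end")
  check_number(p$wet_ar1, "wet_ar1", lower = 0, upper = 0.999,
               key = "forcing.wet_ar1")
  for (nm in c("wet_seasonal_amp", "wet_anom_sd", "wet_month_sd",
               "lightning_max", "npp_max", "pop_logistic_width")) {
    check_number(p[[nm]], nm, lower = 0, key = paste0("forcing.", nm))
  }
  check_number(p$climate_block, "climate_block", lower = 1,
               key = "forcing.climate_block")
  structure(p, class = "fc_forcing_params")
}
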