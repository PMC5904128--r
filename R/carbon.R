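#' Net primary productivity
#'
#' NPP = npp_potential * xi(CO2) * m(wetness), with a logarithmic CO2 response
#' xi = max(0, 1 + gamma * log(CO2/co2_ref)) that emulates downregulation of
#' photosynthesis under rising CO2, and a linear moisture modifier m(w) = w
#' (no production on completely dry soil).
#'
#' @param co2 atmospheric CO2, ppm (> 0).
#' @param wetness fraction in [0, 1] (vectorized).
#' @param npp_potential kg C m-2 yr-1 (vectorized).
#' @param params `fc_carbon_params`.
#' @return NPP flux, kg C m-2 yr-1.
#' @export
npp_flux <- function(co2, wetness, npp_potential, params = carbon_params()) {
  stop_if(any(co2 <= 0), "co2 must be > 0")
  xi <- pmax(0, 1 + params$npp_gamma * log(co2 / params$co2_ref))
  npp_potential * xi * wetness
}

#' Fire CO2 emissions and pool transfers
#'
#' Of the vegetation standing in the burned area, a fraction `cf_veg` is
#' combusted (emitted), a further fraction `fire_mortality` of the remainder
#' is killed and transferred to the litter+soil pool, and the rest survives;
#' a fraction `cf_litter` of the litter in the burned area is combusted.
#' Carbon is conserved exactly: pool change + emission = 0.
#'
#' @param A_b burned area, km2.
#' @param A_g cell area, km2 (A_b <= A_g).
#' @param B_veg vegetation carbon density, kg C m-2 (on the natural-land
#'   basis given by `A_nat`).
#' @param C_litter litter+soil carbon density, kg C m-2 (whole-cell basis).
#' @param params `fc_carbon_params`.
#' @param A_nat burnable (natural) area the vegetation density refers to,
#'   km2; defaults to `A_g`.
#' @return list with `E_fire` (kg C emitted), `B_veg`, `C_litter` (updated
#'   densities) and `to_litter` (kg C of killed, uncombusted biomass moved to
#'   litter).
#' @export
fire_emissions <- function(A_b, A_g, B_veg, C_litter,
                           params = carbon_params(), A_nat = A_g) {
  stop_if(any(A_b < 0), "burned area must be >= 0")
  stop_if(any(A_b > A_g + 1e-9), "burned area cannot exceed the cell area")
  fb_nat <- ifelse(A_nat > 0, A_b / A_nat, 0)
  f_cell <- ifelse(A_g > 0, A_b / A_g, 0)
  combust_v <- params$cf_veg * fb_nat * B_veg      # per m2 of natural land
  killed <- params$fire_mortality * (1 - params$cf_veg) * fb_nat * B_veg
  combust_l <- params$cf_litter * f_cell * C_litter # per m2 of cell
  E_fire <- combust_v * A_nat * 1e6 + combust_l * A_g * 1e6
  list(E_fire = E_fire,
       B_veg = B_veg - combust_v - killed,
       C_litter = C_litter - combust_l +
         ifelse(A_g > 0, killed * A_nat / A_g, 0),
       to_litter = killed * A_nat * 1e6)
}

#' Land-use-change clearing flux
#'
#' Converting a fraction of a cell to cropland removes the vegetation standing
#' on it: a fraction `luc_burn_frac` of the cleared biomass is emitted
#' immediately (burned on clearing), the remainder enters the litter pool for
#' delayed decay. Cropland thereafter carries low fixed biomass outside the
#' natural-vegetation pool.
#'
#' @param delta_crop_frac increment of crop fraction (>= 0, per m2 basis).
#' @param B_veg vegetation carbon density on the cleared land, kg C m-2.
#' @param params `fc_carbon_params`.
#' @param natural_frac remaining natural fraction available for conversion.
#' @return list with `E_luc` (kg C m-2 emitted now) and `to_litter`
#'   (kg C m-2 transferred to litter).
#' @export
luc_clearing <- function(delta_crop_frac, B_veg, params = carbon_params(),
                         natural_frac = 1) {
  stop_if(any(delta_crop_frac < 0), "crop-fraction change must be >= 0")
  stop_if(any(delta_crop_frac > natural_frac + 1e-12),
          "crop expansion exceeds the remaining natural fraction")
  cleared <- delta_crop_frac * B_veg
  list(E_luc = params$luc_burn_frac * cleared,
       to_litter = (1 - params$luc_burn_frac) * cleared)
}

#' Heterotrophic respiration
#'
#' First-order decay of the litter+soil pool, faster on wet soil:
#' Rh = k_litter * C_litter * r(w) with r(w) = rh_wet_min + (1 - rh_wet_min) w.
#'
#' @param C_litter litter+soil carbon (kg C m-2 or kg C; vectorized).
#' @param wetness fraction in [0, 1].
#' @param params `fc_carbon_params`.
#' @return respiration flux in the units of `C_litter` per year.
#' @export
heterotrophic_respiration <- function(C_litter, wetness,
                                      params = carbon_params()) {
  stop_if(any(C_litter < 0), "litter pool must be >= 0")
  r <- params$rh_wet_min + (1 - params$rh_wet_min) * wetness
  params$k_litter * C_litter * r
}

#' Initialize the carbon state near its climatological equilibrium
#'
#' Vegetation and litter pools are set from the year-1 climatology with one
#' fixed-point pass over the fire kill rate, so a short spin-up suffices to
#' polish the state to equilibrium.
#'
#' @param forcing an `fc_forcing`.
#' @param fire `fc_fire_params`.
#' @param carbon `fc_carbon_params`.
#' @return an object of class `fc_carbon_state`: per-cell pool masses
#'   `B_veg`, `C_litter` (kg C) and a cumulative flux ledger (kg C).
#' @export
init_carbon_state <- function(forcing, fire = fire_params(),
                              carbon = carbon_params()) {
  n <- length(forcing$grid$lat)
  land_m2 <- forcing$land_area_km2 * 1e6
  A_nat_m2 <- pmax(0, (1 - forcing$crop_frac[, 1L]) * land_m2)
  wbar <- rowMeans(forcing$wetness[, , 1L])
  npp0 <- npp_flux(forcing$co2[1L], wbar, forcing$npp_potential, carbon)
  # climatological annual fire scalar of year 1 (per unit P_b)
  Xm <- year_fire_scalar(forcing$wetness[, , 1L], forcing$wind[, , 1L],
                         forcing$lightning, forcing$population[, 1L], fire)
  Xa <- rowSums(Xm)
  loss_frac <- carbon$cf_veg + carbon$fire_mortality * (1 - carbon$cf_veg)
  B <- npp0 / max(carbon$k_veg, 1e-9)
  for (i in 1:25) {
    fb <- pmin(1, biomass_probability(pmax(0, B), fire) * Xa)
    B <- npp0 / (carbon$k_veg + loss_frac * fb)
  }
  fb <- pmin(1, biomass_probability(pmax(0, B), fire) * Xa)
  natfrac <- ifelse(land_m2 > 0, A_nat_m2 / land_m2, 0)
  litter_in <- (carbon$k_veg +
                  carbon$fire_mortality * (1 - carbon$cf_veg) * fb) * B
  r <- carbon$rh_wet_min + (1 - carbon$rh_wet_min) * wbar
  loss_rate <- carbon$k_litter * r + carbon$cf_litter * fb * natfrac
  L_mass <- ifelse(loss_rate > 0, litter_in * A_nat_m2 / loss_rate, 0)
  structure(
    list(B_veg = B * A_nat_m2, C_litter = L_mass,
         ledger = list(npp = numeric(n), rh = numeric(n),
                       e_fire = numeric(n), e_luc = numeric(n))),
    class = "fc_carbon_state")
}

# Per-year fire scalar per unit P_b: Xm[cell, month] such that monthly burned
# area is P_b * A_nat_km2 * Xm. Drivers are interpolated monthly -> daily and
# the daily chain P_m * P_i * a_1day * Theta(q) / a_rep is summed within
# months. p_d (hence P_i,h, q, Theta) is annual.
year_fire_scalar <- function(wet_m, wind_m, light_m, p_d, fp,
                             veg_class = "natural") {
  W <- day_weights(); S <- month_collapse()
  wet_d <- clamp01(wet_m %*% W)
  wind_d <- wind_m %*% W
  light_d <- light_m %*% W
  P_m <- 1 - wet_d^fp$moisture_exp
  ups <- clamp01((light_d - fp$F_low) / (fp$F_high - fp$F_low))
  y <- 1 / (1 + exp((fp$sigmoid_center - ups) / fp$sigmoid_width))
  y0 <- 1 / (1 + exp(fp$sigmoid_center / fp$sigmoid_width))
  y1 <- 1 / (1 + exp((fp$sigmoid_center - 1) / fp$sigmoid_width))
  P_in <- y - y0 * (1 - ups) + ups * (1 - y1)
  P_ih <- pmin(1, (p_d / fp$pd_ref)^fp$ignition_exp)   # recycles by column
  P_i <- clamp01(P_in + (1 - P_in) * P_ih)
  q <- fp$base_extinguish +
    pmax(0, 1 - exp(-fp$suppression_rate * p_d)) * (1 - fp$base_extinguish)
  theta <- (1 - q) * (2 - q) / q^2
  u <- fp$u_max[[veg_class]] * spread_wind_modifier(wind_d, fp) *
    spread_moisture_modifier(wet_d)
  l <- fp$head_back_factor * u * 24
  a1 <- pi * l^2 / (4 * length_breadth_ratio(wind_d, fp))
  X <- P_m * P_i * a1 * theta / fp$a_rep
  X %*% S
}

#' Extract one year of drivers from a forcing set
#'
#' @param forcing an `fc_forcing` (possibly scenario-frozen).
#' @param y year index within the span.
#' @return list of the per-cell drivers `step_annual()` consumes.
#' @export
year_forcing <- function(forcing, y) {
  y <- as.integer(y)
  stop_if(y < 1 || y > forcing$years, "year index outside the forcing span")
  list(land_km2 = forcing$land_area_km2,
       npp_potential = forcing$npp_potential,
       wetness = forcing$wetness[, , y],
       wind = forcing$wind[, , y],
       lightning = forcing$lightning,
       p_d = forcing$population[, y],
       crop_prev = forcing$crop_frac[, max(1L, y - 1L)],
       crop_now = forcing$crop_frac[, y],
       co2 = forcing$co2[y])
}

#' Advance the carbon state by one model year
#'
#' Runs the monthly substeps in the fixed order NPP (growth + turnover) ->
#' land-use clearing -> fire -> heterotrophic respiration, with the fire
#' chain evaluated daily from linearly interpolated drivers and accumulated to
#' monthly burned area (capped at the year's remaining natural area). The
#' carbon ledger identity
#' dB_veg + dC_litter = NPP - Rh - E_fire - E_luc holds exactly per cell;
#' non-finite or negative pools abort with a diagnostic.
#'
#' @param state an `fc_carbon_state`.
#' @param fy one year of drivers from [year_forcing()].
#' @param fire `fc_fire_params`.
#' @param carbon `fc_carbon_params`.
#' @return list with the updated `state` and per-cell annual diagnostics:
#'   `burned_km2`, `e_fire`, `e_luc`, `npp`, `rh`, `nee` (kg C except burned
#'   area).
#' @export
step_annual <- function(state, fy, fire = fire_params(),
                        carbon = carbon_params()) {
  n <- length(state$B_veg)
  dt <- 1 / carbon$substeps
  land_m2 <- fy$land_km2 * 1e6
  B <- state$B_veg; L <- state$C_litter
  Xm <- year_fire_scalar(fy$wetness, fy$wind, fy$lightning, fy$p_d, fire)
  dcrop_m <- (fy$crop_now - fy$crop_prev) / carbon$substeps
  crop <- fy$crop_prev
  xi <- pmax(0, 1 + carbon$npp_gamma * log(fy$co2 / carbon$co2_ref))
  burned_ytd <- numeric(n)
  acc <- list(npp = numeric(n), rh = numeric(n), e_fire = numeric(n),
              e_luc = numeric(n), burned = numeric(n))
  for (m in seq_len(carbon$substeps)) {
    midx <- 1L + ((m - 1L) %% 12L)
    w_m <- fy$wetness[, midx]
    # 1. production and turnover
    A_nat_m2 <- pmax(0, (1 - crop) * land_m2)
    npp_d <- fy$npp_potential * xi * w_m
    d_npp <- npp_d * A_nat_m2 * dt
    B <- B + d_npp
    turn <- carbon$k_veg * B * dt
    B <- B - turn; L <- L + turn
    # 2. land-use clearing
    natfrac <- 1 - crop
    d <- pmin(dcrop_m, natfrac)
    cleared <- ifelse(natfrac > 0, B * d / natfrac, 0)
    e_luc <- carbon$luc_burn_frac * cleared
    L <- L + (1 - carbon$luc_burn_frac) * cleared
    B <- B - cleared
    crop <- crop + d
    A_nat_m2 <- pmax(0, (1 - crop) * land_m2)
    A_nat_km2 <- A_nat_m2 / 1e6
    # 3. fire
    B_dens <- ifelse(A_nat_m2 > 0, B / A_nat_m2, 0)
    P_b <- clamp01((B_dens - fire$biomass_lower) /
                     (fire$biomass_upper - fire$biomass_lower))
    A_b <- pmin(P_b * A_nat_km2 * Xm[, midx],
                pmax(0, A_nat_km2 - burned_ytd))
    burned_ytd <- burned_ytd + A_b
    fb_nat <- ifelse(A_nat_km2 > 0, A_b / A_nat_km2, 0)
    f_cell <- ifelse(fy$land_km2 > 0, A_b / fy$land_km2, 0)
    combust_v <- carbon$cf_veg * fb_nat * B
    killed <- carbon$fire_mortality * (1 - carbon$cf_veg) * fb_nat * B
    combust_l <- carbon$cf_litter * f_cell * L
    B <- B - combust_v - killed
    L <- L + killed - combust_l
    e_fire <- combust_v + combust_l
    # 4. respiration
    r <- carbon$rh_wet_min + (1 - carbon$rh_wet_min) * w_m
    rh <- pmin(L, carbon$k_litter * L * r * dt)
    L <- L - rh
    acc$npp <- acc$npp + d_npp
    acc$rh <- acc$rh + rh
    acc$e_fire <- acc$e_fire + e_fire
    acc$e_luc <- acc$e_luc + e_luc
    acc$burned <- acc$burned + A_b
    if (any(!is.finite(B)) || any(!is.finite(L)) ||
        any(B < -1e-6) || any(L < -1e-6)) {
      bad <- which(!is.finite(B) | !is.finite(L) | B < -1e-6 | L < -1e-6)[1L]
      stop(sprintf(paste0("carbon state corrupted at substep %d, cell %d ",
                          "(B = %g, L = %g)"), m, bad, B[bad], L[bad]),
           call. = FALSE)
    }
  }
  state$B_veg <- B
  state$C_litter <- L
  state$ledger$npp <- state$ledger$npp + acc$npp
  state$ledger$rh <- state$ledger$rh + acc$rh
  state$ledger$e_fire <- state$ledger$e_fire + acc$e_fire
  state$ledger$e_luc <- state$ledger$e_luc + acc$e_luc
  list(state = state, burned_km2 = acc$burned, e_fire = acc$e_fire,
       e_luc = acc$e_luc, npp = acc$npp, rh = acc$rh,
       nee = acc$npp - acc$rh - acc$e_fire - acc$e_luc)
}

#' Spin the carbon state to pre-industrial equilibrium
#'
#' Runs the model under all-frozen forcing (climate recycling its fixed
#' block) until the cycle-over-cycle change of the global carbon pool drops
#' below `tol` per year, mirroring a pre-industrial spin-up.
#'
#' @param forcing an `fc_forcing` (transient; the all-frozen scenario is
#'   derived internally).
#' @param fire,carbon parameter records.
#' @param state optional starting `fc_carbon_state`; defaults to the
#'   analytic initialization.
#' @param max_years hard cap on spin-up length.
#' @param tol relative global pool change per year below which the state is
#'   considered equilibrated.
#' @return list with `state`, `years` run, and final `drift` (yr-1).
#' @export
spin_up <- function(forcing, fire = fire_params(), carbon = carbon_params(),
                    state = NULL, max_years = 300, tol = 2e-5) {
  block <- min(forcing$params$climate_block, forcing$years)
  spec <- scenario_spec(character(), years = block, seed = forcing$seed,
                        id = "spinup")
  frozen <- scenario_forcing(forcing, spec)
  if (is.null(state)) state <- init_carbon_state(frozen, fire, carbon)
  yfs <- lapply(seq_len(block), function(y) year_forcing(frozen, y))
  total_prev <- sum(state$B_veg) + sum(state$C_litter)
  years <- 0L
  drift <- Inf
  while (years < max_years) {
    for (y in seq_len(block)) {
      state <- step_annual(state, yfs[[y]], fire, carbon)$state
    }
    years <- years + block
    total <- sum(state$B_veg) + sum(state$C_litter)
    drift <- abs(total - total_prev) / (total * block)
    total_prev <- total
    if (drift < tol) break
  }
  list(state = state, years = years, drift = drift)
}
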