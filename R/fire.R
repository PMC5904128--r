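#' Fuel-availability fire probability
#'
#' Probability that fire is sustained given above-ground biomass density:
#' zero at or below `biomass_lower` (fire is not sustained), one at or above
#' `biomass_upper` (fuel does not limit fire), with a continuous linear ramp
#' between the two thresholds.
#'
#' @param B_ag above-ground biomass density, kg C m-2 (vectorized).
#' @param params `fc_fire_params`.
#' @return P_b in [0, 1].
#' @export
biomass_probability <- function(B_ag, params = fire_params()) {
  stop_if(any(B_ag < 0), "biomass density must be >= 0")
  clamp01((B_ag - params$biomass_lower) /
            (params$biomass_upper - params$biomass_lower))
}

#' Fuel-combustibility (moisture) fire probability
#'
#' The wetter the root-zone/litter layer, the lower the likelihood of fire:
#' P_m = 1 - w^e, strictly decreasing with P_m(0) = 1 and P_m(1) = 0.
#'
#' @param wetness fraction in [0, 1] (vectorized).
#' @param params `fc_fire_params` (uses `moisture_exp`).
#' @return P_m in [0, 1].
#' @export
moisture_probability <- function(wetness, params = fire_params()) {
  stop_if(any(wetness < 0 | wetness > 1), "wetness must be in [0,1]")
  1 - wetness^params$moisture_exp
}

#' Lightning scalar
#'
#' Clamped linear map of cloud-to-ground flash density onto [0, 1]: 0 at or
#' below `F_low` (too few strikes to ignite), 1 at or above `F_high` (lightning
#' poses no constraint).
#'
#' @param F_c2g flashes km-2 month-1 (vectorized).
#' @param params `fc_fire_params`.
#' @return upsilon_F in [0, 1].
#' @export
lightning_scalar <- function(F_c2g, params = fire_params()) {
  stop_if(any(F_c2g < 0), "flash density must be >= 0")
  clamp01((F_c2g - params$F_low) / (params$F_high - params$F_low))
}

#' Ignition sigmoid
#'
#' y(u) = 1 / (1 + exp((c - u)/w)) with center c and width w.
#'
#' @param upsilon_F lightning scalar in [0, 1] (vectorized).
#' @param params `fc_fire_params`.
#' @return y in (0, 1).
#' @export
ignition_sigmoid <- function(upsilon_F, params = fire_params()) {
  1 / (1 + exp((params$sigmoid_center - upsilon_F) / params$sigmoid_width))
}

#' Natural (lightning) ignition probability
#'
#' P_i,n = y(u) - y(0)(1 - u) + u(1 - y(1)); the correction terms cancel the
#' sigmoid's offsets algebraically so the endpoints are exactly
#' P_i,n(0) = 0 and P_i,n(1) = 1.
#'
#' @param upsilon_F lightning scalar in [0, 1] (vectorized).
#' @param params `fc_fire_params`.
#' @return P_i,n in [0, 1].
#' @export
natural_ignition_probability <- function(upsilon_F, params = fire_params()) {
  stop_if(any(upsilon_F < 0 | upsilon_F > 1), "upsilon_F must be in [0,1]")
  y <- ignition_sigmoid(upsilon_F, params)
  y0 <- ignition_sigmoid(0, params)
  y1 <- ignition_sigmoid(1, params)
  y - y0 * (1 - upsilon_F) + upsilon_F * (1 - y1)
}

#' Human ignition probability
#'
#' P_i,h = min[1, (p_d / pd_ref)^ignition_exp]: monotone non-decreasing in
#' population density, saturating at one at the reference density.
#'
#' @param p_d population density, people km-2 (vectorized).
#' @param params `fc_fire_params`.
#' @return P_i,h in [0, 1].
#' @export
human_ignition_probability <- function(p_d, params = fire_params()) {
  stop_if(any(p_d < 0), "population density must be >= 0")
  pmin(1, (p_d / params$pd_ref)^params$ignition_exp)
}

#' Total ignition probability
#'
#' Union of the natural and human ignition sources:
#' P_i = clamp[0,1](P_i,n + (1 - P_i,n) P_i,h), which reduces to P_i,h when
#' there is no natural ignition.
#'
#' @param P_i_n,P_i_h component ignition probabilities in [0, 1] (vectorized).
#' @return P_i in [0, 1].
#' @export
total_ignition_probability <- function(P_i_n, P_i_h) {
  stop_if(any(P_i_n < 0 | P_i_n > 1) || any(P_i_h < 0 | P_i_h > 1),
          "ignition probabilities must be in [0,1]")
  clamp01(P_i_n + (1 - P_i_n) * P_i_h)
}

#' Fire occurrence probability
#'
#' The fire-triangle product for the representative area:
#' P_f = P_b * P_m * P_i.
#'
#' @param P_b,P_m,P_i component probabilities in [0, 1] (vectorized).
#' @return P_f in [0, 1].
#' @export
fire_probability <- function(P_b, P_m, P_i) {
  stop_if(any(c(P_b, P_m, P_i) < 0) || any(c(P_b, P_m, P_i) > 1),
          "probabilities must be in [0,1]")
  P_b * P_m * P_i
}

#' Fire extinguishing probability
#'
#' q = base + max[0, 1 - exp(-rate * p_d)] * (1 - base), with the default
#' constants q = 0.5 + max[0, 1 - exp(-0.025 p_d)]/2: 0.5 with nobody around,
#' approaching 1 as population density (fire fighting, landscape
#' fragmentation) grows without bound.
#'
#' @param p_d population density, people km-2 (vectorized).
#' @param params `fc_fire_params`.
#' @return q in [base_extinguish, 1).
#' @export
extinguish_probability <- function(p_d, params = fire_params()) {
  stop_if(any(p_d < 0), "population density must be >= 0")
  b <- params$base_extinguish
  b + pmax(0, 1 - exp(-params$suppression_rate * p_d)) * (1 - b)
}

#' Expected fire duration
#'
#' With daily extinguishing probability q and independent fire days, fire
#' duration tau follows P(tau) = q (1-q)^tau, so E[tau] = (1 - q)/q days.
#'
#' @param q extinguishing probability in (0, 1] (vectorized).
#' @return expected duration, days.
#' @export
expected_duration <- function(q) {
  stop_if(any(q <= 0 | q > 1), "q must lie in (0, 1]")
  (1 - q) / q
}

#' Duration amplification of burned area
#'
#' Burned area grows like tau^2, so the expected total burned area is the
#' one-day area times Theta(q) = E[tau^2] = (1 - q)(2 - q)/q^2.
#'
#' @param q extinguishing probability in (0, 1] (vectorized).
#' @return Theta(q) >= 0, zero at q = 1.
#' @export
duration_amplification <- function(q) {
  stop_if(any(q <= 0 | q > 1), "q must lie in (0, 1]")
  (1 - q) * (2 - q) / q^2
}

# wind and moisture spread modifiers (shapes documented in the vignette)
spread_wind_modifier <- function(wind, params) {
  params$spread_wind_floor +
    (1 - params$spread_wind_floor) * (1 - exp(-wind / params$wind_ref))
}
spread_moisture_modifier <- function(wetness) (1 - wetness)^2

#' Fire spread rate
#'
#' u = u_max(class) * g(wind) * h(wetness), where g rises from a floor of
#' `spread_wind_floor` at calm toward 1 with wind and h = (1 - w)^2 falls with
#' root-zone wetness; u never exceeds the class maximum.
#'
#' @param veg_class name of a vegetation class in `params$u_max`.
#' @param wind wind speed km h-1 (vectorized).
#' @param wetness fraction in [0, 1] (vectorized).
#' @param params `fc_fire_params`.
#' @return spread rate km h-1.
#' @export
spread_rate <- function(veg_class = "natural", wind, wetness,
                        params = fire_params()) {
  stop_if(!veg_class %in% names(params$u_max),
          "unknown vegetation class '%s'", veg_class)
  stop_if(any(wind < 0), "wind must be >= 0")
  stop_if(any(wetness < 0 | wetness > 1), "wetness must be in [0,1]")
  params$u_max[[veg_class]] * spread_wind_modifier(wind, params) *
    spread_moisture_modifier(wetness)
}

# length-to-breadth ratio of the fire ellipse, 1 at calm
length_breadth_ratio <- function(wind, params) {
  1 + (params$lb_max - 1) * (1 - exp(-params$lb_wind_coef * wind))
}

#' Area burned in one day
#'
#' The burn is elliptical: the fire front advances at `u` (head plus back
#' spread totalling `head_back_factor * u`), so after 24 h the major axis is
#' l = head_back_factor * u * 24, the minor axis is l / LB(wind), and the
#' area is pi (l/2)(b/2). LB(wind) rises from 1 at calm (a circular burn)
#' toward `lb_max`.
#'
#' @param u spread rate km h-1 (vectorized).
#' @param wind wind speed km h-1 (vectorized).
#' @param params `fc_fire_params`.
#' @return one-day burned area, km2.
#' @export
daily_burned_area <- function(u, wind, params = fire_params()) {
  stop_if(any(u < 0), "spread rate must be >= 0")
  l <- params$head_back_factor * u * 24
  pi * l^2 / (4 * length_breadth_ratio(wind, params))
}

#' Grid-cell burned area
#'
#' A_b = P_f * a_1day * Theta(q) * (A_g (1 - crop_frac)) / a_rep, capped at
#' the non-crop area: cropland is assumed not to burn, so the burnable area of
#' a cell is its natural (non-crop) fraction and the occurrence probability
#' defined for the representative area `a_rep` is scaled up by the number of
#' representative areas the natural land holds.
#'
#' @param P_f fire occurrence probability.
#' @param a_1day one-day burned area, km2.
#' @param q extinguishing probability.
#' @param A_g cell (land) area, km2.
#' @param crop_frac crop fraction of the cell in [0, 1].
#' @param params `fc_fire_params`.
#' @return burned area km2, never exceeding (1 - crop_frac) * A_g.
#' @export
cell_burned_area <- function(P_f, a_1day, q, A_g, crop_frac = 0,
                             params = fire_params()) {
  stop_if(any(crop_frac < 0 | crop_frac > 1), "crop_frac must be in [0,1]")
  A_nat <- A_g * (1 - crop_frac)
  pmin(A_nat, P_f * a_1day * duration_amplification(q) * A_nat / params$a_rep)
}

#' Burned-area scalar as a function of population density
#'
#' Holding fuel and moisture fixed, burned area is proportional to
#' A(p_d) = P_i * Theta(q): population density raises ignitions through
#' P_i,h but suppresses fire through q. With no natural ignition the curve
#' rises from zero to an interior optimum before suppression wins; with
#' saturated natural ignition it decreases monotonically.
#'
#' @param p_d population densities to evaluate (people km-2).
#' @param P_i_n natural ignition probability held fixed along the curve.
#' @param params `fc_fire_params`.
#' @return data.frame with columns `p_d` and `A`; the density of the maximum
#'   is attached as attribute `argmax`.
#' @export
burned_area_scalar_curve <- function(p_d, P_i_n = 0, params = fire_params()) {
  stop_if(any(p_d < 0), "population density must be >= 0")
  P_i <- total_ignition_probability(rep(P_i_n, length(p_d)),
                                    human_ignition_probability(p_d, params))
  A <- P_i * duration_amplification(extinguish_probability(p_d, params))
  out <- data.frame(p_d = p_d, A = A)
  attr(out, "argmax") <- p_d[which.max(A)]
  out
}

#' Full per-cell fire diagnostics
#'
#' Evaluates the whole probability chain for one or more cells/steps and
#' returns every intermediate, suitable for export as a diagnostics table.
#'
#' @param B_ag above-ground biomass density kg C m-2.
#' @param wetness fraction in [0, 1].
#' @param F_c2g flashes km-2 month-1.
#' @param p_d people km-2.
#' @param wind km h-1.
#' @param A_g cell land area km2.
#' @param crop_frac crop fraction in [0, 1].
#' @param veg_class vegetation class for the spread rate.
#' @param params `fc_fire_params`.
#' @return data.frame with columns P_b, P_m, upsilon_F, P_i_n, P_i_h, P_i,
#'   P_f, q, tau_bar, theta, u, a_1day, A_b.
#' @export
cell_fire_diagnostics <- function(B_ag, wetness, F_c2g, p_d, wind,
                                  A_g, crop_frac = 0, veg_class = "natural",
                                  params = fire_params()) {
  P_b <- biomass_probability(B_ag, params)
  P_m <- moisture_probability(wetness, params)
  ups <- lightning_scalar(F_c2g, params)
  P_i_n <- natural_ignition_probability(ups, params)
  P_i_h <- human_ignition_probability(p_d, params)
  P_i <- total_ignition_probability(P_i_n, P_i_h)
  P_f <- fire_probability(P_b, P_m, P_i)
  q <- extinguish_probability(p_d, params)
  u <- spread_rate(veg_class, wind, wetness, params)
  a1 <- daily_burned_area(u, wind, params)
  data.frame(P_b = P_b, P_m = P_m, upsilon_F = ups, P_i_n = P_i_n,
             P_i_h = P_i_h, P_i = P_i, P_f = P_f, q = q,
             tau_bar = expected_duration(q),
             theta = duration_amplification(q), u = u, a_1day = a1,
             A_b = cell_burned_area(P_f, a1, q, A_g, crop_frac, params))
}
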