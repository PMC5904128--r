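#' Static site fields: potential NPP and climatological wetness
#'
#' Generates the time-invariant geography every other generator hangs off:
#' a climatological root-zone wetness (wet tropics and mid-latitude storm
#' tracks, dry subtropics) and a potential net primary productivity field
#' proportional to insolation and moisture. Population concentrates where NPP
#' is moderate-to-high, so the spatial covariation of people, productivity and
#' fire that the emergent population-fire curve relies on is built in.
#'
#' @param grid an `fc_grid`.
#' @param seed RNG seed.
#' @param params `fc_forcing_params`.
#' @return list with `wet_base` (fraction) and `npp_potential`
#'   (kg C m-2 yr-1), both per cell.
#' @export
site_fields <- function(grid, seed, params = forcing_params()) {
  with_seed(seed, {
    n <- length(grid$lat)
    rad <- grid$lat * pi / 180
    wet_base <- 0.4 + 0.35 * cos(3 * rad)^2 + stats::rnorm(n, 0, 0.08)
    wet_base <- pmin(0.95, pmax(0.1, wet_base))
    insol <- pmax(0, cos(rad))
    npp <- params$npp_max * insol * wet_base^0.8 * exp(stats::rnorm(n, 0, 0.2))
    list(wet_base = wet_base, npp_potential = npp)
  })
}

logistic_ramp <- function(t, n, mid, width) {
  # monotone 0 -> 1 over t = 1..n, exactly pinned at both endpoints
  if (n == 1L) return(rep(1, length(t)))
  s <- stats::plogis((t - mid) / width)
  s1 <- stats::plogis((1 - mid) / width)
  sn <- stats::plogis((n - mid) / width)
  (s - s1) / (sn - s1)
}

#' Generate the population-density field
#'
#' A static seeded spatial pattern, concentrated in productive cells (near-zero
#' where potential NPP is lowest), scaled through time by a shared
#' logistic-in-time growth curve so the global total rises monotonically by
#' exactly `growth_factor` over the span.
#'
#' @param grid an `fc_grid`.
#' @param years number of years in the span (>= 1).
#' @param growth_factor total multiplicative growth of the global population.
#' @param seed RNG seed.
#' @param params `fc_forcing_params`.
#' @param npp_potential optional per-cell potential NPP; derived from
#'   `site_fields(grid, seed, params)` when missing.
#' @return matrix people km-2 of land, cells x years.
#' @export
generate_population <- function(grid, years, growth_factor = 7, seed = 1,
                                params = forcing_params(),
                                npp_potential = NULL) {
  stop_if(!is.numeric(years) || length(years) != 1 || years < 1,
          "years must be a positive span")
  stop_if(growth_factor <= 0, "growth_factor must be > 0")
  years <- as.integer(years)
  if (is.null(npp_potential)) {
    npp_potential <- site_fields(grid, seed, params)$npp_potential
  }
  land <- grid$area_km2 * params$land_frac
  w <- with_seed(seed + 17L, {
    base <- pmax(0, npp_potential - 0.12)^1.3 * exp(-npp_potential / 0.9)
    base * exp(stats::rnorm(length(base), 0, 0.5))
  })
  # scale so the area-weighted mean density equals pop_mean_density at year 1
  target_people <- params$pop_mean_density * sum(land)
  p0 <- if (sum(w * land) > 0) w * target_people / sum(w * land) else w
  g <- 1 + (growth_factor - 1) *
    logistic_ramp(seq_len(years), years, params$pop_logistic_mid,
                  params$pop_logistic_width)
  if (growth_factor == 1 || years == 1L) g <- rep(1, years)
  outer(p0, g)
}

#' Generate the crop-fraction field
#'
#' Global crop area interpolates linearly from `start_area` to `end_area`;
#' expansion is allocated greedily to cells ranked by potential NPP times
#' initial population density (productive, populated cells convert first),
#' each cell filling up to `crop_max_frac` of its land area before the next
#' is opened. Per-cell crop fraction is monotone non-decreasing in time by
#' construction.
#'
#' @param grid an `fc_grid`.
#' @param years span in years.
#' @param start_area,end_area km2 global crop area at the first/last year.
#' @param seed RNG seed (kept for interface symmetry; the allocation itself is
#'   deterministic given the inputs).
#' @param params `fc_forcing_params`.
#' @param npp_potential optional per-cell potential NPP.
#' @param p_d0 optional initial population density used for ranking.
#' @return matrix of crop fraction of land area in [0, 1], cells x years.
#' @export
generate_crop_fraction <- function(grid, years, start_area = 5e6,
                                   end_area = 15e6, seed = 1,
                                   params = forcing_params(),
                                   npp_potential = NULL, p_d0 = NULL) {
  stop_if(!is.numeric(years) || length(years) != 1 || years < 1,
          "years must be a positive span")
  stop_if(start_area < 0 || end_area < start_area,
          "need 0 <= start_area <= end_area")
  years <- as.integer(years)
  if (is.null(npp_potential)) {
    npp_potential <- site_fields(grid, seed, params)$npp_potential
  }
  if (is.null(p_d0)) {
    p_d0 <- generate_population(grid, years, params$growth_factor, seed,
                                params, npp_potential)[, 1L]
  }
  land <- grid$area_km2 * params$land_frac
  stop_if(end_area > sum(land),
          "end_area %.4g km2 exceeds total land area %.4g km2",
          end_area, sum(land))
  capacity <- params$crop_max_frac * land
  rank_key <- npp_potential * p_d0
  ord <- order(-rank_key, -npp_potential, seq_along(rank_key))
  cum_cap <- cumsum(capacity[ord])
  stop_if(end_area > cum_cap[length(cum_cap)],
          "end_area exceeds allocatable capacity under crop_max_frac")
  target <- start_area +
    (end_area - start_area) * (seq_len(years) - 1) / max(1L, years - 1L)
  if (start_area == end_area) target <- rep(start_area, years)
  # soft greedy frontier: cells convert in rank order, but the conversion wave
  # has a finite width (several cells convert simultaneously), which keeps the
  # global expansion smooth; the shift lambda is solved so the area-weighted
  # fill matches the target exactly, and is monotone in the target, so every
  # cell's crop fraction is monotone non-decreasing in time.
  centers <- cum_cap - capacity[ord] / 2
  width <- 1.5 * mean(capacity)
  fill_at <- function(lambda) sum(capacity[ord] *
                                    stats::plogis((lambda - centers) / width))
  crop <- matrix(0, length(land), years)
  total_cap <- cum_cap[length(cum_cap)]
  for (y in seq_len(years)) {
    a <- target[y]
    if (a <= 0) next
    lambda <- stats::uniroot(function(l) fill_at(l) - a,
                             lower = -20 * width,
                             upper = total_cap + 20 * width,
                             tol = 1e-9 * max(1, a))$root
    alloc <- numeric(length(land))
    alloc[ord] <- capacity[ord] * stats::plogis((lambda - centers) / width)
    crop[, y] <- ifelse(land > 0, alloc / land, 0)
  }
  crop
}

#' Generate the static lightning climatology
#'
#' Cloud-to-ground flash density with a tropical maximum, poleward decay and a
#' summer-peaked seasonal cycle in each hemisphere. The magnitude is synthetic
#' (the generating model's thresholds `F_low`/`F_high` delimit the regimes the
#' ignition scalar distinguishes; the default field contains cells below and
#' above both).
#'
#' @param grid an `fc_grid`.
#' @param seed RNG seed.
#' @param params `fc_forcing_params`.
#' @return matrix flashes km-2 month-1, cells x 12 months.
#' @export
generate_lightning <- function(grid, seed = 1, params = forcing_params()) {
  with_seed(seed, {
    n <- length(grid$lat)
    rad <- grid$lat * pi / 180
    base <- params$lightning_max * cos(rad)^2 * exp(stats::rnorm(n, 0, 0.6))
    peak <- ifelse(grid$lat >= 0, 7, 1) # thunderstorm season per hemisphere
    seas <- 1 + 0.6 * cos(2 * pi * (outer(rep(1, n), 1:12) -
                                      matrix(peak, n, 12)) / 12)
    pmax(base * seas, 0)
  })
}

#' Generate the climate driver fields (wetness, wind)
#'
#' Monthly root-zone/litter wetness in [0, 1] with a seasonal cycle, AR(1)
#' interannual anomalies shared across the months of a year, and independent
#' monthly weather noise; monthly wind speed with a seasonal cycle and annual
#' anomalies. With `transient = FALSE` the first `climate_block` years are
#' generated and recycled exactly for the remainder of the span, mirroring a
#' fixed pre-industrial meteorological block.
#'
#' @param grid an `fc_grid`.
#' @param years span in years.
#' @param transient if `FALSE`, recycle the first `climate_block` years.
#' @param seed RNG seed.
#' @param params `fc_forcing_params`.
#' @param wet_base optional climatological wetness per cell.
#' @return list of arrays `wetness` and `wind`, each cells x 12 x years.
#' @export
generate_climate <- function(grid, years, transient = TRUE, seed = 1,
                             params = forcing_params(), wet_base = NULL) {
  stop_if(!is.numeric(years) || length(years) != 1 || years < 1,
          "years must be a positive span")
  years <- as.integer(years)
  if (is.null(wet_base)) wet_base <- site_fields(grid, seed, params)$wet_base
  n <- length(grid$lat)
  ygen <- if (transient) years else min(params$climate_block, years)
  out <- with_seed(seed + 31L, {
    peak <- ifelse(grid$lat >= 0, 2, 8) # wet-season peak month per hemisphere
    seas <- params$wet_seasonal_amp *
      cos(2 * pi * (outer(rep(1, n), 1:12) - matrix(peak, n, 12)) / 12)
    rho <- params$wet_ar1
    innov_sd <- params$wet_anom_sd * sqrt(1 - rho^2)
    anom <- matrix(0, n, ygen)
    a <- stats::rnorm(n, 0, params$wet_anom_sd)
    for (y in seq_len(ygen)) {
      anom[, y] <- a
      a <- rho * a + stats::rnorm(n, 0, innov_sd)
    }
    wet <- array(0, c(n, 12L, ygen))
    wind <- array(0, c(n, 12L, ygen))
    wind_base <- pmax(2, 8 + 6 * abs(sin(2 * grid$lat * pi / 180)) +
                        stats::rnorm(n, 0, 1.5))
    wind_seas <- 3 * cos(2 * pi * (outer(rep(1, n), 1:12) -
                                     matrix(peak + 6, n, 12)) / 12)
    for (y in seq_len(ygen)) {
      wnoise <- matrix(stats::rnorm(n * 12L, 0, params$wet_month_sd), n, 12L)
      wet[, , y] <- clamp01(wet_base + seas + anom[, y] + wnoise)
      wind[, , y] <- pmax(wind_base + wind_seas + stats::rnorm(n, 0, 1.2),
                          0.3)
    }
    list(wetness = wet, wind = wind)
  })
  if (!transient && years > ygen) {
    idx <- ((seq_len(years) - 1L) %% ygen) + 1L
    out$wetness <- out$wetness[, , idx, drop = FALSE]
    out$wind <- out$wind[, , idx, drop = FALSE]
  }
  out
}

#' Generate the atmospheric CO2 trajectory
#'
#' Monotone linear interpolation between the endpoint concentrations.
#'
#' @param years span in years.
#' @param start_ppm,end_ppm endpoint concentrations (> 0).
#' @return numeric vector of annual ppm values.
#' @export
generate_co2 <- function(years, start_ppm = 285, end_ppm = 397) {
  stop_if(!is.numeric(years) || length(years) != 1 || years < 1,
          "years must be a positive span")
  stop_if(start_ppm <= 0 || end_ppm <= 0, "CO2 concentrations must be > 0")
  years <- as.integer(years)
  if (years == 1L) return(start_ppm)
  seq(start_ppm, end_ppm, length.out = years)
}

#' Assemble the full synthetic forcing set
#'
#' Generates all driver fields for a span with one master seed (each component
#' uses a deterministic offset of it) and validates their range invariants.
#'
#' @param grid an `fc_grid`.
#' @param years span in years.
#' @param params `fc_forcing_params`.
#' @param seed master RNG seed.
#' @return an object of class `fc_forcing` holding the grid, per-cell land
#'   area, `npp_potential`, `population` (cells x years), `crop_frac`
#'   (cells x years), `lightning` (cells x 12), `wetness` and `wind`
#'   (cells x 12 x years), `co2` (years) and bookkeeping fields.
#' @export
make_forcing <- function(grid, years = 165, params = forcing_params(),
                         seed = 42) {
  years <- as.integer(years)
  site <- site_fields(grid, seed + 1L, params)
  pop <- generate_population(grid, years, params$growth_factor, seed + 2L,
                             params, site$npp_potential)
  crop <- generate_crop_fraction(grid, years, params$crop_start_area,
                                 params$crop_end_area, seed + 3L, params,
                                 site$npp_potential, pop[, 1L])
  light <- generate_lightning(grid, seed + 4L, params)
  clim <- generate_climate(grid, years, transient = TRUE, seed + 5L, params,
                           site$wet_base)
  co2 <- generate_co2(years, params$co2_start, params$co2_end)
  f <- structure(
    list(grid = grid, years = years, seed = seed, params = params,
         land_area_km2 = grid$area_km2 * params$land_frac,
         npp_potential = site$npp_potential, wet_base = site$wet_base,
         population = pop, crop_frac = crop, lightning = light,
         wetness = clim$wetness, wind = clim$wind, co2 = co2),
    class = "fc_forcing")
  validate_forcing(f)
  f
}

validate_forcing <- function(f) {
  stop_if(any(f$population < 0), "population must be >= 0")
  stop_if(any(f$crop_frac < 0 | f$crop_frac > 1), "crop_frac must be in [0,1]")
  stop_if(any(f$lightning < 0), "lightning must be >= 0")
  stop_if(any(f$wetness < 0 | f$wetness > 1), "wetness must be in [0,1]")
  stop_if(any(f$wind < 0), "wind must be >= 0")
  stop_if(any(f$co2 <= 0), "co2 must be > 0")
  invisible(f)
}

#' @export
print.fc_forcing <- function(x, ...) {
  cat(sprintf("<fc_forcing> %d cells x %d years (seed %d)\n",
              length(x$grid$lat), x$years, x$seed))
  invisible(x)
}

#' Specify a factorial scenario
#'
#' Declares which forcings evolve transiently; the others are held at their
#' first-year (pre-industrial analog) state, with frozen climate recycling the
#' first `climate_block` years. Optionally freezes the population field after
#' a given year while everything else stays transient.
#'
#' @param transient character subset of
#'   `c("climate", "co2", "population", "landuse")`.
#' @param population_freeze_year optional year after which the population
#'   field is held at its value in that year; must lie within the span.
#' @param years span in years.
#' @param seed RNG seed recorded with results.
#' @param id scenario label.
#' @return an object of class `fc_scenario`.
#' @export
scenario_spec <- function(transient = character(),
                          population_freeze_year = NULL,
                          years = 165, seed = 42, id = NULL) {
  all_f <- c("climate", "co2", "population", "landuse")
  transient <- unique(as.character(transient))
  bad <- setdiff(transient, all_f)
  stop_if(length(bad) > 0, "unknown forcing(s): %s", paste(bad, collapse = ", "))
  years <- as.integer(years)
  if (!is.null(population_freeze_year)) {
    stop_if(population_freeze_year < 1 || population_freeze_year > years,
            "population_freeze_year must lie within the simulation span")
    population_freeze_year <- as.integer(population_freeze_year)
  }
  if (is.null(id)) {
    id <- if (length(transient) == 0) "control"
    else if (setequal(transient, all_f)) "all" else
      paste(sort(transient), collapse = "+")
    if (!is.null(population_freeze_year)) id <- paste0(id, "_popfreeze")
  }
  structure(list(transient = transient,
                 population_freeze_year = population_freeze_year,
                 years = years, seed = as.integer(seed), id = id),
            class = "fc_scenario")
}

#' Apply a scenario to a transient forcing set
#'
#' Frozen forcings are replaced by their baseline-year fields (bit-identical
#' for every subsequent year); frozen climate recycles the first
#' `climate_block` years of the transient realization; a population freeze
#' pins the field at the freeze-year values thereafter.
#'
#' @param forcing an `fc_forcing` (fully transient).
#' @param spec an `fc_scenario`.
#' @return an `fc_forcing` with the scenario's frozen fields substituted.
#' @export
scenario_forcing <- function(forcing, spec) {
  stop_if(!inherits(forcing, "fc_forcing"), "forcing must be an fc_forcing")
  stop_if(!inherits(spec, "fc_scenario"), "spec must be an fc_scenario")
  stop_if(spec$years > forcing$years,
          "scenario span exceeds the generated forcing span")
  y <- spec$years
  f <- forcing
  f$years <- y
  sel <- seq_len(y)
  f$population <- f$population[, sel, drop = FALSE]
  f$crop_frac <- f$crop_frac[, sel, drop = FALSE]
  f$wetness <- f$wetness[, , sel, drop = FALSE]
  f$wind <- f$wind[, , sel, drop = FALSE]
  f$co2 <- f$co2[sel]
  if (!("climate" %in% spec$transient)) {
    block <- min(forcing$params$climate_block, y)
    idx <- ((sel - 1L) %% block) + 1L
    f$wetness <- f$wetness[, , idx, drop = FALSE]
    f$wind <- f$wind[, , idx, drop = FALSE]
  }
  if (!("co2" %in% spec$transient)) f$co2 <- rep(f$co2[1L], y)
  if (!("population" %in% spec$transient)) {
    f$population <- matrix(f$population[, 1L], nrow(f$population), y)
  }
  if (!("landuse" %in% spec$transient)) {
    f$crop_frac <- matrix(f$crop_frac[, 1L], nrow(f$crop_frac), y)
  }
  fy <- spec$population_freeze_year
  if (!is.null(fy) && fy < y) {
    f$population[, (fy + 1L):y] <- f$population[, fy]
  }
  f$scenario <- spec
  f
}
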