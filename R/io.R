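#' Default run configuration
#'
#' The full configuration record: grid, span, seed, spin-up controls, all
#' generator, fire and carbon parameters, and the scenario list. Every entry
#' can be overridden from a YAML file via [load_config()]; unknown keys are
#' rejected.
#'
#' @return a validated configuration list of class `fc_config`.
#' @export
default_config <- function() {
  cfg <- list(
    grid = list(n_lat = 10L, n_lon = 20L),
    years = 165L,
    freeze_year = 110L,
    seed = 42L,
    spinup = list(max_years = 300L, tol = 2e-5),
    forcing = unclass(forcing_params()),
    fire = unclass(fire_params()),
    carbon = unclass(carbon_params()),
    scenarios = c("control", "climate", "co2", "population", "landuse",
                  "all", "population_frozen")
  )
  validate_config(cfg)
}

merge_config <- function(user, default, path = "") {
  for (nm in names(user)) {
    key <- if (path == "") nm else paste(path, nm, sep = ".")
    if (!nm %in% names(default)) config_error("unknown key", key)
    if (is.list(default[[nm]]) && !is.null(names(default[[nm]]))) {
      if (!is.list(user[[nm]])) config_error("expected a mapping", key)
      default[[nm]] <- merge_config(user[[nm]], default[[nm]], key)
    } else {
      default[[nm]] <- user[[nm]]
    }
  }
  default
}

#' Validate (and normalize) a configuration
#'
#' @param cfg a configuration list.
#' @return the validated configuration, class `fc_config`.
#' @export
validate_config <- function(cfg) {
  if (is.null(cfg$grid$n_lat) || is.null(cfg$grid$n_lon)) {
    config_error("missing grid dimensions", "grid")
  }
  check_number(cfg$grid$n_lat, "n_lat", lower = 2, key = "grid.n_lat")
  check_number(cfg$grid$n_lon, "n_lon", lower = 2, key = "grid.n_lon")
  check_number(cfg$years, "years", lower = 1, key = "years")
  check_number(cfg$seed, "seed", key = "seed")
  check_number(cfg$freeze_year, "freeze_year", lower = 1, upper = cfg$years,
               key = "freeze_year")
  check_number(cfg$spinup$max_years, "max_years", lower = 1,
               key = "spinup.max_years")
  check_number(cfg$spinup$tol, "tol", lower = 0, key = "spinup.tol")
  cfg$years <- as.integer(cfg$years)
  cfg$seed <- as.integer(cfg$seed)
  cfg$freeze_year <- as.integer(cfg$freeze_year)
  cfg$scenarios <- as.character(unlist(cfg$scenarios))
  known <- c("control", "climate", "co2", "population", "landuse", "all",
             "population_frozen")
  bad <- setdiff(cfg$scenarios, known)
  if (length(bad)) config_error(paste("unknown scenario(s):",
                                      paste(bad, collapse = ", ")),
                                "scenarios")
  cfg$fire$u_max <- unlist(cfg$fire$u_max)
  cfg$fire <- unclass(do.call(fire_params, cfg$fire))
  cfg$carbon <- unclass(do.call(carbon_params, cfg$carbon))
  cfg$forcing <- unclass(do.call(forcing_params, cfg$forcing))
  structure(cfg, class = "fc_config")
}

#' Load a configuration from a YAML file
#'
#' Missing keys fall back to defaults; unknown keys are rejected with the
#' offending key path. Which keys came from the file (versus defaults) is
#' recorded in the `"provenance"` attribute.
#'
#' @param path YAML file; an empty file yields the default configuration.
#' @return a validated `fc_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("file '%s' not found", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) config_error("config must be a YAML mapping")
  cfg <- merge_config(user, unclass(default_config()))
  cfg <- validate_config(cfg)
  attr(cfg, "provenance") <- flatten_keys(user)
  cfg
}

flatten_keys <- function(x, path = "") {
  out <- character()
  for (nm in names(x)) {
    key <- if (path == "") nm else paste(path, nm, sep = ".")
    if (is.list(x[[nm]]) && !is.null(names(x[[nm]]))) {
      out <- c(out, flatten_keys(x[[nm]], key))
    } else {
      out <- c(out, key)
    }
  }
  out
}

#' Write a configuration to YAML
#'
#' @param cfg an `fc_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  attributes(x) <- list(names = names(x))
  x$fire$u_max <- as.list(cfg$fire$u_max)
  yaml::write_yaml(x, path)
  invisible(path)
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  write_config(cfg, f)
  unname(tools::md5sum(f))
}

# numeric columns serialized at full double precision so CSV round-trips are
# bit-exact
write_csv_full <- function(df, file) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
}

#' Write a simulation result to disk
#'
#' Lays a result out as plain-text gridded files following the NetCDF
#' convention structurally: a JSON header declaring the dimensions (time,
#' lat, lon) and per-variable units attributes, long-format CSV for the
#' per-cell annual fields, a CSV for the global series, and a manifest
#' recording the package version, scenario, seed, configuration hash and an
#' md5 checksum per file.
#'
#' @param result an `fc_result`.
#' @param path output directory (created if needed).
#' @param config optional `fc_config` whose hash is recorded.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, config = NULL) {
  stop_if(!inherits(result, "fc_result"), "result must be an fc_result")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- result$grid
  write_csv_full(result$series, file.path(path, "global_series.csv"))
  cells <- data.frame(cell = seq_along(g$lat), lat = g$lat, lon = g$lon,
                      area_km2 = g$area_km2,
                      land_area_km2 = result$land_area_km2)
  write_csv_full(cells, file.path(path, "cells.csv"))
  long <- function(m) {
    data.frame(time = rep(seq_len(ncol(m)), each = nrow(m)),
               cell = rep(seq_len(nrow(m)), times = ncol(m)),
               lat = rep(g$lat, times = ncol(m)),
               lon = rep(g$lon, times = ncol(m)),
               value = as.vector(m))
  }
  for (nm in names(result$percell)) {
    write_csv_full(long(result$percell[[nm]]),
                   file.path(path, paste0(nm, ".csv")))
  }
  header <- list(
    conventions = "NetCDF-style dimensions/attributes, plain-text carrier",
    dimensions = list(time = result$years, lat = g$n_lat, lon = g$n_lon),
    coordinates = list(time = "integer synthetic year",
                       lat = "degrees_north (cell centers)",
                       lon = "degrees_east (cell centers)"),
    variables = list(
      burned_Mha = list(units = "Mha yr-1",
                        long_name = "global area burned"),
      e_fire_Pg = list(units = "Pg C yr-1",
                       long_name = "global fire CO2 emissions"),
      e_luc_Pg = list(units = "Pg C yr-1",
                      long_name = "global land-use-change emissions"),
      npp_Pg = list(units = "Pg C yr-1", long_name = "global NPP"),
      rh_Pg = list(units = "Pg C yr-1",
                   long_name = "global heterotrophic respiration"),
      nee_Pg = list(units = "Pg C yr-1",
                    long_name = "net atmosphere-land CO2 flux (positive = sink)"),
      burned_frac = list(units = "fraction of land area yr-1",
                         long_name = "per-cell burned fraction"),
      e_fire_kg = list(units = "kg C yr-1",
                       long_name = "per-cell fire CO2 emissions"),
      p_d = list(units = "people km-2",
                 long_name = "population density")))
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files <- setdiff(list.files(path), "manifest.json")
  manifest <- list(
    package = "firecarbon",
    version = as.character(utils::packageVersion("firecarbon")),
    scenario = result$scenario,
    seed = result$seed,
    years = result$years,
    config_hash = if (!is.null(config)) config_hash(config) else NA,
    checksums = as.list(stats::setNames(
      unname(tools::md5sum(file.path(path, files))), files)))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a simulation result from disk
#'
#' Verifies every file against the manifest checksums before reading;
#' `read_result(write_result(x))` reproduces the numeric content exactly.
#'
#' @param path directory written by [write_result()].
#' @return an `fc_result` (without the final carbon state).
#' @export
read_result <- function(path) {
  man_file <- file.path(path, "manifest.json")
  stop_if(!file.exists(man_file), "no manifest in '%s'", path)
  man <- jsonlite::read_json(man_file, simplifyVector = TRUE)
  for (f in names(man$checksums)) {
    got <- unname(tools::md5sum(file.path(path, f)))
    stop_if(is.na(got) || got != man$checksums[[f]],
            "checksum mismatch for '%s' (corrupt or modified file)", f)
  }
  num_csv <- function(f) utils::read.csv(file.path(path, f))
  series <- num_csv("global_series.csv")
  for (nm in setdiff(names(series), "year")) {
    series[[nm]] <- as.numeric(series[[nm]]) # all-zero columns parse as int
  }
  cells <- num_csv("cells.csv")
  header <- jsonlite::read_json(file.path(path, "header.json"),
                                simplifyVector = TRUE)
  grid <- make_grid(header$dimensions$lat, header$dimensions$lon)
  n <- nrow(cells)
  years <- man$years
  percell <- list()
  for (nm in c("burned_frac", "e_fire_kg", "p_d")) {
    f <- paste0(nm, ".csv")
    if (file.exists(file.path(path, f))) {
      d <- num_csv(f)
      m <- matrix(0, n, years)
      m[cbind(d$cell, d$time)] <- d$value
      percell[[nm]] <- m
    }
  }
  structure(list(scenario = man$scenario, seed = man$seed, years = years,
                 grid = grid, land_area_km2 = cells$land_area_km2,
                 series = series, percell = percell),
            class = "fc_result")
}
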