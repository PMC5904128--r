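# Shared fixtures, memoised so expensive runs happen once per session.
.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

small_grid <- function() make_grid(6, 12)

small_config <- function(years = 60) {
  cfg <- unclass(default_config())
  cfg$grid <- list(n_lat = 6, n_lon = 12)
  cfg$years <- years
  cfg$freeze_year <- min(cfg$freeze_year, years)
  cfg$spinup$max_years <- 150
  validate_config(cfg)
}

# full default study conditions: 10x20 grid, 165 years, seed 42
default_runs <- function() memo("default_runs", run_experiments(default_config()))

small_runs <- function() memo("small_runs", run_experiments(small_config()))

decadal_means <- function(x, n_decades = floor(length(x) / 10)) {
  vapply(seq_len(n_decades),
         function(d) mean(x[(10 * d - 9):(10 * d)]), numeric(1))
}
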