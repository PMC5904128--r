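#' Build a global latitude-longitude grid
#'
#' Constructs an equal-angle lat-lon grid over the sphere. Cell areas follow
#' spherical band geometry (cosine-of-latitude weighting): the area of the band
#' between latitudes \eqn{\phi_1 < \phi_2} is
#' \eqn{2\pi R^2 (\sin\phi_2 - \sin\phi_1)}, divided evenly among the `n_lon`
#' cells of the band. The areas therefore sum exactly to the sphere surface
#' \eqn{4\pi R^2}.
#'
#' @param n_lat number of latitude bands (>= 2).
#' @param n_lon number of longitude columns (>= 2).
#' @param radius_km planetary radius in km (default Earth, 6371 km).
#' @return an object of class `fc_grid`: a list with `n_lat`, `n_lon`,
#'   `lat_edges` (degrees), `lat`, `lon` (cell centers, degrees), `area_km2`
#'   (per-cell area, cell-major order: latitude bands from south to north, each
#'   scanned west to east), `cells` (a data.frame of cell, lat, lon, area_km2)
#'   and `total_area_km2`.
#' @examples
#' g <- make_grid(10, 20)
#' all.equal(sum(g$area_km2), 4 * pi * 6371^2)
#' @export
make_grid <- function(n_lat, n_lon, radius_km = 6371) {
  stop_if(!is.numeric(n_lat) || !is.numeric(n_lon) || length(n_lat) != 1 ||
            length(n_lon) != 1, "n_lat and n_lon must be single numbers")
  n_lat <- as.integer(n_lat); n_lon <- as.integer(n_lon)
  stop_if(is.na(n_lat) || is.na(n_lon) || n_lat < 2L || n_lon < 2L,
          "grid dimensions must be integers >= 2")
  lat_edges <- seq(-90, 90, length.out = n_lat + 1L)
  rad <- pi / 180
  band_area <- 2 * pi * radius_km^2 * diff(sin(lat_edges * rad))
  lat_centers <- (lat_edges[-1L] + lat_edges[-(n_lat + 1L)]) / 2
  lon_centers <- seq(-180 + 360 / n_lon / 2, 180 - 360 / n_lon / 2,
                     length.out = n_lon)
  lat <- rep(lat_centers, each = n_lon)
  lon <- rep(lon_centers, times = n_lat)
  area <- rep(band_area / n_lon, each = n_lon)
  cells <- data.frame(cell = seq_along(lat), lat = lat, lon = lon,
                      area_km2 = area)
  structure(
    list(n_lat = n_lat, n_lon = n_lon, lat_edges = lat_edges,
         lat = lat, lon = lon, area_km2 = area, cells = cells,
         radius_km = radius_km, total_area_km2 = sum(area)),
    class = "fc_grid"
  )
}

#' @export
print.fc_grid <- function(x, ...) {
  cat(sprintf("<fc_grid> %d x %d cells, total area %.4g km^2\n",
              x$n_lat, x$n_lon, x$total_area_km2))
  invisible(x)
}
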