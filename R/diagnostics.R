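#' Ordinary least-squares trend
#'
#' Slope of a time series against years with its classical OLS standard
#' error (no autocorrelation correction), the "slope +/- se" format trend
#' statistics are reported in.
#'
#' @param series numeric series (no missing values).
#' @param years time axis; defaults to `seq_along(series)`.
#' @return list of class `fc_trend` with `slope`, `se`, `n`.
#' @export
ols_trend <- function(series, years = seq_along(series)) {
  stop_if(length(series) != length(years), "series and years lengths differ")
  stop_if(length(series) < 3, "need at least 3 points")
  stop_if(anyNA(series) || anyNA(years), "missing values not supported")
  stop_if(stats::var(years) == 0, "time axis is constant")
  fit <- stats::lm(series ~ years)
  sm <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) { # exact lines are legitimate input here
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  structure(list(slope = unname(sm["years", "Estimate"]),
                 se = unname(sm["years", "Std. Error"]),
                 n = length(series)),
            class = "fc_trend")
}

#' @export
print.fc_trend <- function(x, ...) {
  cat(sprintf("trend %.4g +/- %.4g per year (n = %d)\n", x$slope, x$se, x$n))
  invisible(x)
}

#' Interval-overlap test for two estimates
#'
#' Two estimates are "statistically not different" when their
#' mean +/- k * sd intervals intersect (closed intervals; touching endpoints
#' count as overlap). The default k = 1.385 corresponds to a 95% confidence
#' comparison of two independent normal estimates.
#'
#' @param mean_a,sd_a,mean_b,sd_b means and standard deviations (sd >= 0).
#' @param k half-width multiplier.
#' @return `TRUE` if the intervals overlap (not different), else `FALSE`.
#' @export
overlap_test <- function(mean_a, sd_a, mean_b, sd_b, k = 1.385) {
  stop_if(sd_a < 0 || sd_b < 0, "standard deviations must be >= 0")
  (mean_a - k * sd_a) <= (mean_b + k * sd_b) &&
    (mean_b - k * sd_b) <= (mean_a + k * sd_a)
}

#' Centered moving average
#'
#' Rolling mean over a window, ends truncated to complete windows (output
#' length `n - window + 1`).
#'
#' @param series numeric series.
#' @param window window length in samples (default 10 years).
#' @return smoothed series.
#' @export
moving_average <- function(series, window = 10) {
  stop_if(window < 1, "window must be >= 1")
  stop_if(window > length(series), "window longer than the series")
  as.numeric(zoo::rollmean(series, window, align = "center"))
}

#' Pearson correlation
#'
#' Standard product-moment correlation of two equal-length series.
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @return correlation coefficient.
#' @export
pearson_correlation <- function(a, b) {
  stop_if(length(a) != length(b), "lengths differ")
  stop_if(length(a) < 3, "need at least 3 points")
  stop_if(stats::var(a) == 0 || stats::var(b) == 0,
          "zero-variance input")
  stats::cor(a, b)
}

#' Per-cell trend map with zonal split
#'
#' OLS slope of an annual per-cell field computed cell-wise (closed-form
#' normal equations, identical to `ols_trend`'s slope), with the summed trend
#' reported separately for cells above and below a split latitude.
#'
#' @param fields matrix cells x years.
#' @param grid the `fc_grid` the cells belong to.
#' @param years time axis; defaults to column index.
#' @param split_lat_deg latitude of the zonal split (default 50 degrees N).
#' @return list with `slope` (per cell), and `zonal`, a data.frame of summed
#'   trends above/below the split latitude.
#' @export
per_cell_trend_map <- function(fields, grid, years = seq_len(ncol(fields)),
                               split_lat_deg = 50) {
  stop_if(ncol(fields) < 3, "need at least 3 years")
  t_c <- years - mean(years)
  denom <- sum(t_c^2)
  x_c <- fields - rowMeans(fields)
  slope <- as.numeric(x_c %*% t_c) / denom
  north <- grid$lat > split_lat_deg
  zonal <- data.frame(zone = c(sprintf("above %g degN", split_lat_deg),
                               sprintf("below %g degN", split_lat_deg)),
                      trend = c(sum(slope[north]), sum(slope[!north])))
  list(slope = slope, zonal = zonal)
}

#' Emergent population-fire curve
#'
#' Bins grid cells with non-zero burned area and non-zero population density
#' into log-spaced population bins and reports the per-bin median burned
#' percentage: the emergent relationship between people and fire, unimodal
#' when human ignitions dominate at low density and suppression at high
#' density.
#'
#' @param p_d per-cell population density, people km-2.
#' @param burned_pct per-cell percentage of area burned.
#' @param bins number of log-spaced bins over the observed density range.
#' @return data.frame with bin edges, bin center, per-bin median burned
#'   percentage and cell count (empty bins reported with count 0 and NA
#'   median). The center of the bin with the largest median is attached as
#'   attribute `argmax`, the full argmax bin range as `argmax_bin`.
#' @export
emergent_population_curve <- function(p_d, burned_pct, bins = 20) {
  stop_if(length(p_d) != length(burned_pct), "lengths differ")
  keep <- p_d > 0 & burned_pct > 0 & is.finite(p_d) & is.finite(burned_pct)
  stop_if(sum(keep) < 2, "need at least 2 cells with burning and people")
  p <- p_d[keep]; b <- burned_pct[keep]
  edges <- 10^seq(log10(min(p)), log10(max(p)), length.out = bins + 1)
  edges[length(edges)] <- edges[length(edges)] * (1 + 1e-12) # include max
  idx <- findInterval(p, edges, rightmost.closed = TRUE)
  idx[idx > bins] <- bins
  med <- rep(NA_real_, bins)
  cnt <- integer(bins)
  for (k in seq_len(bins)) {
    sel <- idx == k
    cnt[k] <- sum(sel)
    if (cnt[k] > 0) med[k] <- stats::median(b[sel])
  }
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    center = sqrt(edges[-length(edges)] * edges[-1]),
                    median_burned_pct = med, n_cells = cnt)
  k_max <- which.max(med)
  attr(out, "argmax") <- out$center[k_max]
  attr(out, "argmax_bin") <- c(out$bin_lo[k_max], out$bin_hi[k_max])
  out
}
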