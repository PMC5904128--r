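#' @keywords internal
"_PACKAGE"

# package-local cache (day-weight matrices etc.)
.fc_env <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so seeded generators do not disturb the global stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# validation error with a key path, used by the config loader (exit code 2 in the CLI)
config_error <- function(msg, key = NULL) {
  full <- if (is.null(key)) msg else sprintf("config key '%s': %s", key, msg)
  stop(errorCondition(full, class = c("fc_config_error", "error", "condition")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf, key = NULL) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    config_error(sprintf("%s must be a single finite number", name), key)
  }
  if (x < lower || x > upper) {
    config_error(sprintf("%s = %g outside [%g, %g]", name, x, lower, upper), key)
  }
  invisible(x)
}

stop_if <- function(cond, ...) {
  if (cond) stop(sprintf(...), call. = FALSE)
  invisible(NULL)
}

clamp01 <- function(x) { # preserves dim attributes, unlike pmax(0, x)
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# month lengths of the 365-day model year and mid-month day-of-year
.month_len <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.month_mid <- cumsum(.month_len) - .month_len / 2
.month_of_day <- rep.int(seq_len(12L), .month_len)

#' Linear monthly-to-daily interpolation weights
#'
#' 12 x 365 matrix W such that, for a cells-by-months field M, `M %*% W` gives
#' the field linearly interpolated to each day of a 365-day year between
#' mid-month anchor points (cyclic across the year boundary).
#' @keywords internal
#' @noRd
day_weights <- function() {
  if (!is.null(.fc_env$W)) return(.fc_env$W)
  W <- matrix(0, 12L, 365L)
  mids <- .month_mid
  for (d in seq_len(365L)) {
    if (d <= mids[1L]) { # wrap Dec -> Jan
      span <- (365 - mids[12L]) + mids[1L]
      w <- (d + (365 - mids[12L])) / span
      W[12L, d] <- 1 - w; W[1L, d] <- w
    } else if (d >= mids[12L]) {
      span <- (365 - mids[12L]) + mids[1L]
      w <- (d - mids[12L]) / span
      W[12L, d] <- 1 - w; W[1L, d] <- w
    } else {
      m2 <- which(mids >= d)[1L]
      m1 <- m2 - 1L
      w <- (d - mids[m1]) / (mids[m2] - mids[m1])
      W[m1, d] <- 1 - w; W[m2, d] <- w
    }
  }
  .fc_env$W <- W
  W
}

# 365 x 12 day-into-month aggregation matrix (column sums per month)
month_collapse <- function() {
  if (!is.null(.fc_env$S)) return(.fc_env$S)
  S <- matrix(0, 365L, 12L)
  S[cbind(seq_len(365L), .month_of_day)] <- 1
  .fc_env$S <- S
  S
}
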