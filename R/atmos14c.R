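#' Atmospheric Delta-14C curve
#'
#' Construct a validated atmospheric Delta-14C time series, the forcing of the
#' single-pool bomb-radiocarbon turnover model. The curve is a table of
#' (decimal calendar year, Delta-14C in per mil) pairs, optionally with a
#' per-point 1-sigma analytical uncertainty.
#'
#' @param years numeric, decimal calendar years CE, strictly increasing after
#'   sorting; at least two points.
#' @param delta14c numeric, per-mil Delta-14C at each year.
#' @param sigma optional numeric, per-mil 1-sigma uncertainties.
#' @return An object of class `atm_curve`: a data frame with columns `year`,
#'   `delta14c` and (if supplied) `sigma`.
#' @examples
#' atm_curve(c(1950, 1964.5), c(0, 1000))
#' @export
atm_curve <- function(years, delta14c, sigma = NULL) {
  years <- as.numeric(years)
  delta14c <- as.numeric(delta14c)
  if (length(years) != length(delta14c))
    stop("`years` and `delta14c` must have the same length")
  if (length(years) < 2L)
    stop("an atmospheric curve needs at least 2 points")
  if (anyNA(years) || anyNA(delta14c))
    stop("NA values are not allowed in an atmospheric curve")
  o <- order(years)
  years <- years[o]
  delta14c <- delta14c[o]
  if (any(diff(years) == 0))
    stop("duplicate years in atmospheric curve: ",
         paste(unique(years[duplicated(years)]), collapse = ", "))
  out <- data.frame(year = years, delta14c = delta14c)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)[o]
    if (length(sigma) != length(years))
      stop("`sigma` must match `years` in length")
    if (any(sigma < 0, na.rm = TRUE)) stop("`sigma` must be >= 0")
    out$sigma <- sigma
  }
  class(out) <- c("atm_curve", "data.frame")
  out
}

#' Read an atmospheric Delta-14C curve from delimited text
#'
#' Accepts the common published-compilation layout: two or three numeric
#' columns (year, Delta-14C, optional 1-sigma), whitespace- or
#' comma-delimited, with `#` comment lines. A Northern-Hemisphere zone-2
#' compilation file can be dropped in unchanged.
#'
#' @param path path to a delimited text file.
#' @return An [atm_curve()] object.
#' @export
read_atm_curve <- function(path) {
  if (!file.exists(path)) stop("curve file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) < 2L) stop("curve file has fewer than 2 data rows: ", path)
  fields <- strsplit(trimws(lines), "[,[:space:]]+")
  n_col <- lengths(fields)
  bad <- which(n_col < 2L)
  if (length(bad))
    stop("malformed row at line ", lineno[bad[1L]], " of ", path,
         ": need at least 2 columns")
  num <- lapply(fields, function(f) suppressWarnings(as.numeric(f)))
  bad <- which(vapply(num, anyNA, logical(1)))
  if (length(bad))
    stop("malformed row at line ", lineno[bad[1L]], " of ", path,
         ": non-numeric field")
  years <- vapply(num, `[[`, numeric(1), 1L)
  delta <- vapply(num, `[[`, numeric(1), 2L)
  sigma <- if (all(n_col >= 3L)) vapply(num, `[[`, numeric(1), 3L) else NULL
  atm_curve(years, delta, sigma)
}

#' Evaluate an atmospheric curve at arbitrary decimal years
#'
#' Linear interpolation inside the span of the curve; beyond the last knot the
#' last segment is extended linearly (with a warning), because sampling years
#' such as 2014 typically exceed published compilations that end around 2010.
#' Extrapolated values are capped below at -1000 per mil (zero radiocarbon).
#' Times before the first knot are an error: the model spin-up must start
#' inside the curve.
#'
#' @param curve an [atm_curve()].
#' @param t numeric vector of decimal years.
#' @param warn_extrapolation emit a warning when any `t` lies beyond the last
#'   knot (default `TRUE`; internal callers warn once per model run).
#' @return per-mil Delta-14C at each `t`.
#' @export
atm_value_at <- function(curve, t, warn_extrapolation = TRUE) {
  stopifnot(inherits(curve, "atm_curve"))
  t <- as.numeric(t)
  if (any(t < curve$year[1L]))
    stop("time ", min(t), " precedes the first curve year (",
         curve$year[1L], "); the curve must cover the requested span")
  n <- nrow(curve)
  last <- curve$year[n]
  out <- stats::approx(curve$year, curve$delta14c, xout = pmin(t, last),
                       method = "linear", rule = 2)$y
  beyond <- t > last
  if (any(beyond)) {
    if (warn_extrapolation)
      warning("extrapolating atmospheric curve beyond ", last,
              " (last two knots extended linearly)")
    slope <- (curve$delta14c[n] - curve$delta14c[n - 1L]) /
      (curve$year[n] - curve$year[n - 1L])
    out[beyond] <- pmax(curve$delta14c[n] + slope * (t[beyond] - last), -1000)
  }
  out
}

#' Synthetic bomb-spike atmospheric curve
#'
#' A deterministic stand-in for the published Northern-Hemisphere compilation,
#' for testing and simulation: zero Delta-14C before 1955, a linear ramp from
#' 1955 to the bomb peak, then an exponential decline.
#'
#' @param peak_year decimal year of the bomb peak (default 1964.5).
#' @param peak_delta per-mil Delta-14C at the peak (default 1000).
#' @param decay_rate per-year rate of the post-peak exponential decline
#'   (default 0.06).
#' @param start_year,end_year span of the curve (defaults 1900 and 2015).
#' @param step sampling step in years (default 1/12, monthly).
#' @return An [atm_curve()].
#' @examples
#' crv <- synth_bomb_curve()
#' atm_value_at(crv, 1964.5)  # the peak value
#' @export
synth_bomb_curve <- function(peak_year = 1964.5, peak_delta = 1000,
                             decay_rate = 0.06, start_year = 1900,
                             end_year = 2015, step = 1 / 12) {
  if (step <= 0) stop("`step` must be positive")
  if (!(start_year < peak_year && peak_year < end_year))
    stop("need start_year < peak_year < end_year")
  if (peak_delta <= 0) stop("`peak_delta` must be positive")
  yrs <- seq(start_year, end_year, by = step)
  if (abs(yrs[length(yrs)] - end_year) > 1e-9) yrs <- c(yrs, end_year)
  ramp_start <- 1955
  d <- numeric(length(yrs))
  ramp <- yrs >= ramp_start & yrs <= peak_year
  d[ramp] <- peak_delta * (yrs[ramp] - ramp_start) / (peak_year - ramp_start)
  post <- yrs > peak_year
  d[post] <- peak_delta * exp(-decay_rate * (yrs[post] - peak_year))
  atm_curve(yrs, d)
}
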