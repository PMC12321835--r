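#' Daily greenhouse climate series
#'
#' Validated container for the driving weather: one row per calendar day with
#' the daily mean air temperature and the daily integral of solar radiation
#' inside the greenhouse. The first date is the transplant date (DAT 0).
#'
#' @param date Vector of consecutive `Date`s (coerced with `as.Date`).
#' @param temp_mean Daily mean air temperature, degrees C.
#' @param sr Daily solar radiation integral, MJ m^-2.
#' @param temp_range Plausibility window for temperatures, degrees C.
#' @return A `data.frame` of class `straw_env` with columns `date`,
#'   `temp_mean`, `sr` and attribute `transplant` (the first date).
#' @examples
#' env <- environment_series(as.Date("2021-09-18") + 0:4,
#'                           temp_mean = c(22, 21, 23, 22, 20),
#'                           sr = c(8, 6, 9, 7, 5))
#' attr(env, "transplant")
#' @export
environment_series <- function(date, temp_mean, sr, temp_range = c(-5, 45)) {
  date <- as.Date(date)
  if (anyNA(date)) stop("climate dates contain NA/unparseable entries", call. = FALSE)
  n <- length(date)
  if (n == 0L) stop("climate series is empty", call. = FALSE)
  if (length(temp_mean) != n || length(sr) != n) {
    stop("date, temp_mean and sr must have equal length", call. = FALSE)
  }
  d <- diff(as.integer(date))
  if (any(d != 1L)) {
    i <- which(d != 1L)[1L]
    stop(sprintf("climate series must cover consecutive days; gap after %s (next is %s)",
                 date[i], date[i + 1L]), call. = FALSE)
  }
  if (any(!is.finite(sr)) || any(sr < 0)) {
    stop("solar radiation must be finite and >= 0", call. = FALSE)
  }
  out <- which(!is.finite(temp_mean) | temp_mean < temp_range[1] |
                 temp_mean > temp_range[2])
  if (length(out)) {
    stop(sprintf("temperature outside plausibility window [%g, %g] C on %s",
                 temp_range[1], temp_range[2], date[out[1L]]), call. = FALSE)
  }
  structure(data.frame(date = date, temp_mean = temp_mean, sr = sr),
            transplant = date[1L], class = c("straw_env", "data.frame"))
}

#' Dated leaf-area observations
#'
#' Sparse observations of leaf area index (LAI, destructive measurement,
#' m^2 m^-2) or of image-derived intercepted leaf-area index (iLAI), to be
#' linearly interpolated onto the daily grid. iLAI is used directly as the
#' canopy light-interception fraction, so values are clamped to \[0, 1\]
#' (with a warning above 1).
#'
#' @param date Observation dates (strictly increasing).
#' @param value Leaf-area values, m^2 m^-2, all >= 0.
#' @param mode `"lai"` (Beer-Lambert interception with extinction `k`) or
#'   `"ilai"` (values are the interception fraction; `k` unused).
#' @return A `data.frame` of class `straw_leaf_area` with attribute `mode`.
#' @examples
#' leaf_area_series(as.Date("2021-09-18") + c(0, 30, 60), c(0.3, 0.9, 1.8))
#' @export
leaf_area_series <- function(date, value, mode = c("lai", "ilai")) {
  mode <- match.arg(mode)
  date <- as.Date(date)
  if (anyNA(date)) stop("leaf-area dates contain NA/unparseable entries", call. = FALSE)
  if (length(date) == 0L) stop("leaf-area series is empty", call. = FALSE)
  if (length(value) != length(date)) {
    stop("date and value must have equal length", call. = FALSE)
  }
  if (any(diff(as.numeric(date)) <= 0)) {
    stop("leaf-area dates must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("leaf-area values must be finite and >= 0", call. = FALSE)
  }
  if (mode == "ilai" && any(value > 1)) {
    warning(sprintf("%d iLAI value(s) > 1 clamped to 1 (interception fraction)",
                    sum(value > 1)), call. = FALSE)
    value <- pmin(value, 1)
  }
  structure(data.frame(date = date, value = value),
            mode = mode, class = c("straw_leaf_area", "data.frame"))
}

#' Interpolate leaf area onto arbitrary dates
#'
#' Linear interpolation between bracketing observations; outside the observed
#' window the nearest observation is carried constant.
#'
#' @param series A [leaf_area_series()].
#' @param date Dates at which to evaluate.
#' @return Numeric vector of leaf-area values.
#' @examples
#' s <- leaf_area_series(as.Date("2021-10-01") + c(0, 10), c(1, 2))
#' interpolate_leaf_area(s, as.Date("2021-10-06")) # 1.5
#' @export
interpolate_leaf_area <- function(series, date) {
  stopifnot(inherits(series, "straw_leaf_area"))
  date <- as.Date(date)
  if (nrow(series) == 1L) return(rep(series$value, length(date)))
  stats::approx(as.numeric(series$date), series$value,
                xout = as.numeric(date), method = "linear", rule = 2)$y
}

#' Flowering schedule
#'
#' First-flower anthesis dates, one per inflorescence, in emergence order.
#' Each inflorescence is modelled as one fruit cluster whose degree-day clock
#' starts on its anthesis date.
#'
#' @param anthesis_date Strictly increasing anthesis dates.
#' @return Object of class `straw_flowering` (a `Date` vector).
#' @examples
#' flowering_schedule(as.Date("2021-09-18") + c(55, 108, 161))
#' @export
flowering_schedule <- function(anthesis_date) {
  d <- as.Date(anthesis_date)
  if (anyNA(d)) stop("anthesis dates contain NA/unparseable entries", call. = FALSE)
  if (length(d) > 1L && any(diff(as.numeric(d)) <= 0)) {
    stop("anthesis dates must be strictly increasing", call. = FALSE)
  }
  structure(d, class = c("straw_flowering", class(d)))
}
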