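#' PAR from global solar radiation
#'
#' Photosynthetically active radiation is taken as a fixed fraction (default
#' one half) of the daily global solar radiation integral.
#'
#' @param sr Daily solar radiation, MJ m^-2 (vectorised, >= 0).
#' @param params [model_parameters()].
#' @return PAR, MJ m^-2.
#' @examples
#' par_from_radiation(10) # 5
#' @export
par_from_radiation <- function(sr, params = model_parameters()) {
  params <- as_straw_params(params)
  if (any(!is.finite(sr)) || any(sr < 0)) {
    stop("solar radiation must be finite and >= 0", call. = FALSE)
  }
  sr * params$par_fraction
}

#' Light intercepted by a Beer-Lambert canopy
#'
#' Fraction `1 - exp(-k * LAI)` of incident PAR is intercepted.
#'
#' @param par Incident PAR, MJ m^-2 (>= 0).
#' @param lai Leaf area index, m^2 m^-2 (>= 0).
#' @param k Light-extinction coefficient (> 0).
#' @return Intercepted light, MJ m^-2; 0 at `lai = 0`, approaching `par` for
#'   dense canopies.
#' @examples
#' intercepted_light(5, 3, 0.85) # ~4.61
#' @export
intercepted_light <- function(par, lai, k = 0.85) {
  if (any(!is.finite(par)) || any(par < 0)) stop("par must be >= 0", call. = FALSE)
  if (any(!is.finite(lai)) || any(lai < 0)) stop("lai must be >= 0", call. = FALSE)
  if (any(k <= 0)) stop("k must be > 0", call. = FALSE)
  par * (1 - exp(-k * lai))
}

#' Light interception from image-derived cover fraction
#'
#' When leaf area is observed as the intercepted (projected) leaf-area index
#' from top-down images, it already is the interception fraction, so the
#' extinction coefficient is not needed: `I = PAR * iLAI`.
#'
#' @param par Incident PAR, MJ m^-2 (>= 0).
#' @param ilai Interception fraction in \[0, 1\]; values above 1 are clamped
#'   with a warning, negatives are an error.
#' @return Intercepted light, MJ m^-2.
#' @examples
#' intercepted_light_ilai(4, 0.6) # 2.4
#' @export
intercepted_light_ilai <- function(par, ilai) {
  if (any(!is.finite(par)) || any(par < 0)) stop("par must be >= 0", call. = FALSE)
  if (any(!is.finite(ilai)) || any(ilai < 0)) {
    stop("ilai must be finite and >= 0", call. = FALSE)
  }
  if (any(ilai > 1)) {
    warning("ilai > 1 clamped to 1 (interception fraction)", call. = FALSE)
    ilai <- pmin(ilai, 1)
  }
  par * ilai
}

#' Daily dry-matter production
#'
#' Intercepted light times light-use efficiency. The caller accumulates total
#' dry matter as `TDM_n = TDM_(n-1) + dDM_n`, with TDM at transplanting equal
#' to the initial biomass `tdm0`.
#'
#' @param i Intercepted light, MJ m^-2 (>= 0).
#' @param lue Light-use efficiency, g MJ^-1 (> 0).
#' @return Dry-matter increment, g m^-2.
#' @examples
#' dm_production(4.609, 2.75)
#' @export
dm_production <- function(i, lue = 2.75) {
  if (any(!is.finite(i)) || any(i < 0)) stop("intercepted light must be >= 0", call. = FALSE)
  if (any(lue <= 0)) stop("lue must be > 0", call. = FALSE)
  i * lue
}

#' Calibrate light-use efficiency by regression
#'
#' Ordinary least-squares straight-line fit of total above-ground dry matter
#' against cumulative intercepted PAR at the calibration sampling dates; the
#' slope is the light-use efficiency. The intercept is left free because the
#' stand starts from a nonzero transplant biomass.
#'
#' @param points `data.frame` with columns `ipar` (cumulative intercepted
#'   PAR, MJ m^-2) and `tdm` (total dry matter, g m^-2); at least 3 rows with
#'   non-identical `ipar`.
#' @return List with `lue` (slope, g MJ^-1), `intercept` (g m^-2) and the
#'   fitted `lm` object as `fit`.
#' @examples
#' pts <- data.frame(ipar = c(0, 100, 200), tdm = 19.9 + 2.75 * c(0, 100, 200))
#' estimate_lue(pts)$lue # 2.75
#' @export
estimate_lue <- function(points) {
  if (!is.data.frame(points) || !all(c("ipar", "tdm") %in% names(points))) {
    stop("points must be a data.frame with columns 'ipar' and 'tdm'", call. = FALSE)
  }
  if (nrow(points) < 3L) stop("need at least 3 calibration points", call. = FALSE)
  if (any(!is.finite(points$ipar)) || any(!is.finite(points$tdm)) ||
      any(points$ipar < 0) || any(points$tdm < 0)) {
    stop("calibration points must be finite and >= 0", call. = FALSE)
  }
  if (stats::var(points$ipar) == 0) {
    stop("calibration abscissae are degenerate (identical ipar)", call. = FALSE)
  }
  fit <- stats::lm(tdm ~ ipar, data = points)
  slope <- unname(stats::coef(fit)[["ipar"]])
  if (slope <= 0) {
    stop("calibration slope is not positive; data do not support an LUE estimate",
         call. = FALSE)
  }
  list(lue = slope, intercept = unname(stats::coef(fit)[[1L]]), fit = fit)
}
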