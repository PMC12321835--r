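# evaluate expr under a temporary RNG state so generators are pure per seed
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic forcing-culture scenario specification
#'
#' Parameters of the synthetic input generator emulating a Japanese
#' forcing-culture season: transplant in late September, harvest December
#' through April. Temperature and radiation follow annual sinusoids (peaks
#' near early August and the summer solstice) with truncated Gaussian
#' day-to-day noise; anthesis dates follow the first inflorescence at 55 DAT
#' with successive inflorescences every 53 days; leaf area rises
#' logistically from transplant to a plateau.
#'
#' @param transplant Transplant date (DAT 0).
#' @param season_days Length of the simulated season, days.
#' @param t_mean,t_amp Annual mean and amplitude of the daily mean
#'   greenhouse temperature sinusoid, degrees C (peak at `t_peak_doy`).
#' @param t_peak_doy Day of year of the temperature peak.
#' @param t_noise_sd Day-to-day temperature noise SD, degrees C.
#' @param t_bounds Physical bounds the generated daily means are truncated
#'   to, degrees C (greenhouse climate control envelope).
#' @param sr_mean,sr_amp Annual mean and amplitude of the in-greenhouse
#'   daily solar radiation sinusoid, MJ m^-2 (peak at `sr_peak_doy`).
#' @param sr_peak_doy Day of year of the radiation peak (summer solstice).
#' @param sr_noise_sd Radiation noise SD, MJ m^-2.
#' @param sr_bounds Truncation bounds for radiation, MJ m^-2.
#' @param first_anthesis_dat DAT of first-flower anthesis of inflorescence 1.
#' @param anthesis_interval Days between successive inflorescence anthesis.
#' @param n_clusters Number of inflorescences.
#' @param lai_start,lai_plateau Initial and plateau leaf area index,
#'   m^2 m^-2.
#' @param lai_mid_dat,lai_scale Midpoint (DAT) and scale (days) of the
#'   logistic LAI rise.
#' @param lai_obs_interval Days between leaf-area observations.
#' @param seed Integer seed; identical seeds give identical scenarios.
#' @return Object of class `straw_scenario` (a validated named list).
#' @export
scenario_spec <- function(transplant = as.Date("2021-09-18"),
                          season_days = 220,
                          t_mean = 17.6, t_amp = 7.0, t_peak_doy = 213,
                          t_noise_sd = 0.8, t_bounds = c(9.8, 25.5),
                          sr_mean = 4.0, sr_amp = 2.5, sr_peak_doy = 172,
                          sr_noise_sd = 1.0, sr_bounds = c(1, 18),
                          first_anthesis_dat = 55, anthesis_interval = 53,
                          n_clusters = 3,
                          lai_start = 0.3, lai_plateau = 3.0,
                          lai_mid_dat = 100, lai_scale = 30,
                          lai_obs_interval = 14,
                          seed = 0) {
  spec <- list(transplant = as.Date(transplant), season_days = season_days,
               t_mean = t_mean, t_amp = t_amp, t_peak_doy = t_peak_doy,
               t_noise_sd = t_noise_sd, t_bounds = t_bounds,
               sr_mean = sr_mean, sr_amp = sr_amp, sr_peak_doy = sr_peak_doy,
               sr_noise_sd = sr_noise_sd, sr_bounds = sr_bounds,
               first_anthesis_dat = first_anthesis_dat,
               anthesis_interval = anthesis_interval,
               n_clusters = n_clusters,
               lai_start = lai_start, lai_plateau = lai_plateau,
               lai_mid_dat = lai_mid_dat, lai_scale = lai_scale,
               lai_obs_interval = lai_obs_interval,
               seed = seed)
  if (season_days < 1) stop("season_days must be >= 1", call. = FALSE)
  if (anthesis_interval <= 0) stop("anthesis_interval must be > 0", call. = FALSE)
  if (n_clusters < 0) stop("n_clusters must be >= 0", call. = FALSE)
  if (first_anthesis_dat < 0) stop("first_anthesis_dat must be >= 0", call. = FALSE)
  if (lai_start < 0 || lai_plateau < 0) stop("LAI values must be >= 0", call. = FALSE)
  if (t_noise_sd < 0 || sr_noise_sd < 0) stop("noise SDs must be >= 0", call. = FALSE)
  if (diff(spec$t_bounds) <= 0 || diff(spec$sr_bounds) <= 0) {
    stop("bounds must be increasing intervals", call. = FALSE)
  }
  if (t_mean < spec$t_bounds[1] || t_mean > spec$t_bounds[2]) {
    stop("t_mean outside t_bounds: infeasible climate spec", call. = FALSE)
  }
  last_anthesis <- first_anthesis_dat +
    anthesis_interval * max(0, n_clusters - 1)
  if (n_clusters > 0 && last_anthesis > season_days - 1) {
    stop("anthesis schedule extends beyond the season", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  structure(spec, class = "straw_scenario")
}

sinusoid <- function(doy, mean, amp, peak_doy) {
  mean + amp * cos(2 * pi * (doy - peak_doy) / 365.25)
}

#' Generate a synthetic greenhouse climate series
#'
#' Daily mean temperature and solar radiation over the scenario window:
#' annual sinusoids plus Gaussian day-to-day noise truncated at the physical
#' bounds of the spec. Deterministic per seed.
#'
#' @param spec A [scenario_spec()].
#' @return An [environment_series()].
#' @export
generate_climate <- function(spec) {
  stopifnot(inherits(spec, "straw_scenario"))
  dates <- spec$transplant + 0:(spec$season_days - 1L)
  doy <- as.integer(format(dates, "%j"))
  with_seed(spec$seed + 1L, {
    temp <- sinusoid(doy, spec$t_mean, spec$t_amp, spec$t_peak_doy) +
      stats::rnorm(length(dates), 0, spec$t_noise_sd)
    sr <- sinusoid(doy, spec$sr_mean, spec$sr_amp, spec$sr_peak_doy) +
      stats::rnorm(length(dates), 0, spec$sr_noise_sd)
  })
  temp <- pmin(pmax(temp, spec$t_bounds[1]), spec$t_bounds[2])
  sr <- pmin(pmax(sr, spec$sr_bounds[1]), spec$sr_bounds[2])
  environment_series(dates, temp, sr)
}

#' Generate a synthetic flowering schedule
#'
#' Anthesis of inflorescence 1 at `first_anthesis_dat`, then one
#' inflorescence every `anthesis_interval` days.
#'
#' @param spec A [scenario_spec()].
#' @return A [flowering_schedule()].
#' @export
generate_flowering_schedule <- function(spec) {
  stopifnot(inherits(spec, "straw_scenario"))
  if (spec$n_clusters == 0L) return(flowering_schedule(as.Date(character())))
  dat <- spec$first_anthesis_dat +
    spec$anthesis_interval * (seq_len(spec$n_clusters) - 1L)
  flowering_schedule(spec$transplant + dat)
}

#' Generate a synthetic leaf-area trajectory
#'
#' Sparse dated observations following a logistic rise from `lai_start` to
#' `lai_plateau`. In iLAI mode the logistic LAI is mapped through the
#' Beer-Lambert interception fraction `1 - exp(-k * LAI)` to emulate
#' camera-derived canopy cover.
#'
#' @param spec A [scenario_spec()].
#' @param mode `"lai"` or `"ilai"`.
#' @param k Extinction coefficient used only for the iLAI mapping.
#' @return A [leaf_area_series()].
#' @export
generate_lai_trajectory <- function(spec, mode = c("lai", "ilai"), k = 0.85) {
  stopifnot(inherits(spec, "straw_scenario"))
  mode <- match.arg(mode)
  dat <- unique(c(seq(0, spec$season_days - 1L, by = spec$lai_obs_interval),
                  spec$season_days - 1L))
  lai <- spec$lai_start + (spec$lai_plateau - spec$lai_start) /
    (1 + exp(-(dat - spec$lai_mid_dat) / spec$lai_scale))
  value <- if (mode == "ilai") 1 - exp(-k * lai) else lai
  leaf_area_series(spec$transplant + dat, value, mode = mode)
}

#' Synthetic light-use-efficiency calibration data
#'
#' Builds calibration points the way a destructive-sampling campaign would:
#' the generated climate and leaf-area trajectory give cumulative intercepted
#' PAR at each sampling date, total dry matter is `tdm0 + lue * iPAR` plus
#' Gaussian noise.
#'
#' @param spec A [scenario_spec()].
#' @param params [model_parameters()] supplying `tdm0`, `k`, `par_fraction`
#'   and the generating `lue`.
#' @param n_points Number of sampling dates (evenly spread over the season).
#' @param noise_sd Observation noise on total dry matter, g m^-2.
#' @return `data.frame` with columns `ipar`, `tdm` for [estimate_lue()].
#' @export
generate_lue_calibration <- function(spec, params = model_parameters(),
                                     n_points = 20, noise_sd = 5) {
  stopifnot(inherits(spec, "straw_scenario"))
  params <- as_straw_params(params)
  if (n_points < 3) stop("need at least 3 calibration points", call. = FALSE)
  env <- generate_climate(spec)
  la <- generate_lai_trajectory(spec, "lai", params$k)
  lai_daily <- interpolate_leaf_area(la, env$date)
  i_daily <- intercepted_light(par_from_radiation(env$sr, params),
                               lai_daily, params$k)
  ipar_cum <- cumsum(i_daily)
  idx <- unique(round(seq(1L, nrow(env), length.out = n_points)))
  tdm_true <- params$tdm0 + params$lue * ipar_cum[idx]
  noise <- with_seed(spec$seed + 2L,
                     stats::rnorm(length(idx), 0, noise_sd))
  data.frame(ipar = ipar_cum[idx], tdm = pmax(0, tdm_true + noise))
}

#' Generate and write a complete synthetic scenario
#'
#' Writes the three input CSVs (climate, flowering, leaf area) plus a JSON
#' copy of the spec into a directory.
#'
#' @param spec A [scenario_spec()].
#' @param dir Output directory (created if missing).
#' @param mode Leaf-area mode for the written trajectory.
#' @return Invisibly, a named list of the written file paths.
#' @export
generate_scenario <- function(spec, dir, mode = c("lai", "ilai")) {
  stopifnot(inherits(spec, "straw_scenario"))
  mode <- match.arg(mode)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  env <- generate_climate(spec)
  fl <- generate_flowering_schedule(spec)
  la <- generate_lai_trajectory(spec, mode)
  paths <- list(climate = file.path(dir, "climate.csv"),
                flowering = file.path(dir, "flowering.csv"),
                leaf_area = file.path(dir, "leaf_area.csv"),
                spec = file.path(dir, "scenario.json"))
  write_climate_csv(env, paths$climate)
  write_flowering_csv(fl, paths$flowering)
  write_leaf_area_csv(la, paths$leaf_area)
  sp <- unclass(spec)
  sp$transplant <- format(sp$transplant)
  jsonlite::write_json(sp, paths$spec, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
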