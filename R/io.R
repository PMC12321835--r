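read_csv_checked <- function(path, need) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  d
}

parse_dates <- function(x, path, column) {
  d <- as.Date(x, format = "%Y-%m-%d")
  if (anyNA(d)) {
    i <- which(is.na(d))[1L]
    stop(sprintf("%s: malformed date '%s' in column '%s' (row %d); expected ISO-8601",
                 path, x[i], column, i), call. = FALSE)
  }
  d
}

#' Read a daily climate CSV
#'
#' Columns: `date` (ISO-8601), `temp_mean_c`, `solar_mj_m2`; one row per
#' consecutive day, first row = transplant day.
#'
#' @param path CSV path.
#' @return An [environment_series()].
#' @export
read_climate_csv <- function(path) {
  d <- read_csv_checked(path, c("date", "temp_mean_c", "solar_mj_m2"))
  environment_series(parse_dates(d$date, path, "date"),
                     d$temp_mean_c, d$solar_mj_m2)
}

#' Write a climate series to CSV
#' @param env An [environment_series()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_climate_csv <- function(env, path) {
  stopifnot(inherits(env, "straw_env"))
  utils::write.csv(data.frame(date = format(env$date),
                              temp_mean_c = env$temp_mean,
                              solar_mj_m2 = env$sr),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flowering-schedule CSV
#'
#' Columns: `inflorescence_index`, `anthesis_date` (ISO-8601); rows sorted
#' by index.
#'
#' @param path CSV path.
#' @return A [flowering_schedule()].
#' @export
read_flowering_csv <- function(path) {
  d <- read_csv_checked(path, c("inflorescence_index", "anthesis_date"))
  d <- d[order(d$inflorescence_index), , drop = FALSE]
  flowering_schedule(parse_dates(d$anthesis_date, path, "anthesis_date"))
}

#' Write a flowering schedule to CSV
#' @param flowering A [flowering_schedule()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_flowering_csv <- function(flowering, path) {
  utils::write.csv(data.frame(inflorescence_index = seq_along(flowering),
                              anthesis_date = format(as.Date(as.vector(flowering),
                                                             origin = "1970-01-01"))),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a leaf-area CSV
#'
#' Columns: `date` (ISO-8601), `value` (m^2 m^-2); the mode (LAI vs iLAI) is
#' declared by the caller or the run config, not stored in the file.
#'
#' @param path CSV path.
#' @param mode `"lai"` or `"ilai"`.
#' @return A [leaf_area_series()].
#' @export
read_leaf_area_csv <- function(path, mode = c("lai", "ilai")) {
  mode <- match.arg(mode)
  d <- read_csv_checked(path, c("date", "value"))
  leaf_area_series(parse_dates(d$date, path, "date"), d$value, mode = mode)
}

#' Write a leaf-area series to CSV
#' @param series A [leaf_area_series()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_leaf_area_csv <- function(series, path) {
  stopifnot(inherits(series, "straw_leaf_area"))
  utils::write.csv(data.frame(date = format(series$date),
                              value = series$value),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a LUE calibration-points CSV
#'
#' Columns: `ipar` (cumulative intercepted PAR, MJ m^-2) and `tdm`
#' (g m^-2).
#'
#' @param path CSV path.
#' @return `data.frame` for [estimate_lue()].
#' @export
read_calibration_csv <- function(path) {
  read_csv_checked(path, c("ipar", "tdm"))
}

known_config_keys <- c("climate", "flowering", "leaf_area", "leaf_area_mode",
                       "out_dir", "seed", "params")

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) run config naming the three input CSVs, the
#' leaf-area mode and optional parameter overrides, loads and validates the
#' inputs, and applies the default parameters where not overridden. Unknown
#' config or parameter keys are rejected.
#'
#' @param config Path to a YAML/JSON config file, or an equivalent named
#'   list. Recognised keys: `climate`, `flowering`, `leaf_area`,
#'   `leaf_area_mode` (`"lai"`/`"ilai"`), `out_dir`, `seed`, `params` (named
#'   overrides of any [model_parameters()] field).
#' @return List with `env`, `flowering`, `leaf_area`, `params`, `config`.
#' @export
load_inputs <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a named list", call. = FALSE)
  unknown <- setdiff(names(config), known_config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (key in c("climate", "flowering", "leaf_area")) {
    if (is.null(config[[key]])) stop("config is missing '", key, "'", call. = FALSE)
  }
  mode <- config$leaf_area_mode %||% "lai"
  overrides <- config$params %||% list()
  bad <- setdiff(names(overrides), names(formals(model_parameters)))
  if (length(bad)) {
    stop("unknown parameter override(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  params <- do.call(model_parameters, overrides)
  list(env = read_climate_csv(config$climate),
       flowering = read_flowering_csv(config$flowering),
       leaf_area = read_leaf_area_csv(config$leaf_area, mode),
       params = params,
       config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write simulation outputs and metadata
#'
#' Writes the daily trajectory CSV, the monthly-yield CSV and a JSON
#' metadata sidecar (package version, parameters, input-file digests) to a
#' directory.
#'
#' @param result A [simulate_season()] result.
#' @param dir Output directory (created if needed).
#' @param inputs Optional named character vector of input file paths whose
#'   MD5 digests go into the sidecar.
#' @return Invisibly, a named list of written paths.
#' @export
write_outputs <- function(result, dir, inputs = character()) {
  stopifnot(inherits(result, "straw_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(trajectory = file.path(dir, "trajectory.csv"),
                monthly = file.path(dir, "monthly_yield.csv"),
                metadata = file.path(dir, "run_metadata.json"))
  traj <- as.data.frame(result)
  traj$date <- format(traj$date)
  utils::write.csv(traj, paths$trajectory, row.names = FALSE, quote = FALSE)
  mo <- monthly_yield(result)
  mo$month <- format(mo$month)
  utils::write.csv(mo, paths$monthly, row.names = FALSE, quote = FALSE)
  meta <- list(
    package = "strawsim",
    version = as.character(utils::packageVersion("strawsim")),
    leaf_area_mode = attr(result, "leaf_area_mode"),
    n_clusters = attr(result, "n_clusters"),
    parameters = unclass(attr(result, "params")),
    inputs = if (length(inputs)) {
      as.list(tools::md5sum(unlist(inputs)))
    } else list()
  )
  jsonlite::write_json(meta, paths$metadata, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
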