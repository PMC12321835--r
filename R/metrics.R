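check_pairs <- function(sim, obs, min_n = 1L) {
  if (length(sim) != length(obs)) {
    stop("simulated and observed series must have equal length", call. = FALSE)
  }
  if (length(sim) < min_n) {
    stop(sprintf("need at least %d paired values", min_n), call. = FALSE)
  }
  if (anyNA(sim) || anyNA(obs)) stop("paired series contain NA", call. = FALSE)
  invisible(TRUE)
}

#' Root mean squared error
#'
#' @param sim,obs Paired simulated and observed values (equal length >= 1).
#' @return `sqrt(mean((sim - obs)^2))`, in the units of the inputs.
#' @examples
#' rmse(c(2, 4, 6), c(1, 4, 8)) # sqrt(5/3)
#' @export
rmse <- function(sim, obs) {
  check_pairs(sim, obs, 1L)
  sqrt(mean((sim - obs)^2))
}

#' Relative root mean squared error
#'
#' RMSE divided by the observed mean; dimensionless.
#'
#' @param sim,obs Paired simulated and observed values; `mean(obs)` must be
#'   nonzero.
#' @return `rmse(sim, obs) / mean(obs)`.
#' @examples
#' rrmse(c(2, 4, 6), c(1, 4, 8))
#' @export
rrmse <- function(sim, obs) {
  check_pairs(sim, obs, 1L)
  om <- mean(obs)
  if (om == 0) stop("observed mean is zero; RRMSE undefined", call. = FALSE)
  rmse(sim, obs) / om
}

#' Coefficient of determination
#'
#' Agreement of simulated with observed values. The default is the
#' coefficient of determination about the observed mean,
#' `1 - sum((obs - sim)^2) / sum((obs - mean(obs))^2)`, which penalises bias;
#' `method = "pearson"` returns the squared Pearson correlation instead.
#'
#' @param sim,obs Paired values (length >= 2, observed variance > 0).
#' @param method `"determination"` (default) or `"pearson"`.
#' @return R-squared (unbounded below for `"determination"`).
#' @examples
#' r_squared(c(1.1, 2.0, 2.9), c(1, 2, 3)) # 0.99
#' @export
r_squared <- function(sim, obs, method = c("determination", "pearson")) {
  method <- match.arg(method)
  check_pairs(sim, obs, 2L)
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) stop("observed variance is zero; R^2 undefined", call. = FALSE)
  if (method == "pearson") {
    return(stats::cor(sim, obs)^2)
  }
  1 - sum((obs - sim)^2) / sst
}

#' Interval dry-matter distribution to fruit
#'
#' Realised fraction of dry-matter growth that went to fruit over each
#' interval between successive (destructive) measurements:
#' `AF' = (DF_{i+1} - DF_i) / ((TDM_{i+1} - TDM_i) / Pd)`, with fruit dry
#' weight per plant and total dry matter per ground area. Applies identically
#' to observed data and to a simulated trajectory sampled on the same dates.
#'
#' @param date Measurement dates (ordered, length >= 2).
#' @param fruit_dw Total fruit dry weight per plant at each date, g.
#' @param tdm Total dry matter at each date, g m^-2, strictly increasing
#'   between consecutive measurements.
#' @param pd Plant density, plants m^-2.
#' @return `data.frame` with one row per interval: `from`, `to`, `af`.
#' @examples
#' interval_fruit_fraction(as.Date("2022-01-01") + c(0, 30),
#'                         fruit_dw = c(0, 10), tdm = c(100, 241), pd = 7.05)
#' @export
interval_fruit_fraction <- function(date, fruit_dw, tdm, pd = 7.05) {
  date <- as.Date(date)
  n <- length(date)
  if (n < 2L) stop("need at least 2 measurement dates", call. = FALSE)
  if (length(fruit_dw) != n || length(tdm) != n) {
    stop("date, fruit_dw and tdm must have equal length", call. = FALSE)
  }
  if (any(diff(as.numeric(date)) <= 0)) {
    stop("measurement dates must be strictly increasing", call. = FALSE)
  }
  d_tdm <- diff(tdm)
  if (any(d_tdm <= 0)) {
    i <- which(d_tdm <= 0)[1L]
    stop(sprintf("total DM not increasing over interval %s to %s",
                 date[i], date[i + 1L]), call. = FALSE)
  }
  data.frame(from = date[-n], to = date[-1L],
             af = diff(fruit_dw) / (d_tdm / pd))
}

#' Interval fruit fraction of a simulated trajectory
#'
#' Convenience wrapper sampling a [simulate_season()] result at the given
#' measurement dates and computing [interval_fruit_fraction()] on it.
#'
#' @param result A `straw_sim` object.
#' @param date Measurement dates, all present in the trajectory.
#' @return As [interval_fruit_fraction()].
#' @export
simulated_fruit_fraction <- function(result, date) {
  stopifnot(inherits(result, "straw_sim"))
  date <- as.Date(date)
  idx <- match(date, result$date)
  if (anyNA(idx)) {
    stop("measurement date(s) not in the simulated trajectory: ",
         paste(date[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  interval_fruit_fraction(date, result$fruit_dw[idx], result$tdm[idx],
                          attr(result, "params")$pd)
}

#' Validation report for a simulated trajectory
#'
#' Matches observations to the simulation by exact date and computes RMSE,
#' RRMSE and R-squared per observed variable.
#'
#' @param result A `straw_sim` object.
#' @param obs `data.frame` with columns `date`, `variable` (one of `yield`,
#'   `tdm`, `fruit_dw`) and `value`.
#' @return `data.frame` with one row per variable: `variable`, `n`, `rmse`,
#'   `rrmse`, `r_squared`.
#' @export
validate_simulation <- function(result, obs) {
  stopifnot(inherits(result, "straw_sim"))
  need <- c("date", "variable", "value")
  if (!is.data.frame(obs) || !all(need %in% names(obs))) {
    stop("obs must have columns date, variable, value", call. = FALSE)
  }
  obs$date <- as.Date(obs$date)
  sim_col <- c(yield = "y", tdm = "tdm", fruit_dw = "fruit_dw")
  bad <- setdiff(unique(obs$variable), names(sim_col))
  if (length(bad)) {
    stop("unknown observed variable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(obs, obs$variable), function(g) {
    idx <- match(g$date, result$date)
    if (anyNA(idx)) {
      stop(sprintf("observation date(s) for '%s' not simulated: %s",
                   g$variable[1L],
                   paste(g$date[is.na(idx)], collapse = ", ")), call. = FALSE)
    }
    s <- result[[sim_col[[g$variable[1L]]]]][idx]
    data.frame(variable = g$variable[1L], n = length(idx),
               rmse = rmse(s, g$value), rrmse = rrmse(s, g$value),
               r_squared = if (length(idx) >= 2 && stats::var(g$value) > 0)
                 r_squared(s, g$value) else NA_real_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
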