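#' Cumulative temperature since transplanting
#'
#' Degree-day clock of the whole stand: the inclusive sum of daily mean
#' temperatures from the transplant day (DAT 0) through day `n`.
#'
#' @param env An [environment_series()].
#' @param n Day index (DAT), `0 <= n < nrow(env)`. May be a vector.
#' @return Cumulative temperature, degree-days.
#' @examples
#' env <- environment_series(as.Date("2021-09-18") + 0:2,
#'                           temp_mean = c(10, 20, 30), sr = rep(5, 3))
#' cumulative_temperature(env, 2) # 60
#' @export
cumulative_temperature <- function(env, n) {
  stopifnot(inherits(env, "straw_env"))
  if (any(n < 0) || any(n >= nrow(env)) || any(n != floor(n))) {
    stop("day index n must be an integer in [0, nrow(env) - 1]", call. = FALSE)
  }
  cumsum(env$temp_mean)[n + 1L]
}

#' Leaf potential-growth curve
#'
#' Relative potential growth (0 to 1) of leaf number `p`, logistic in the
#' cumulative temperature past the leaf's emergence. Leaf `p` emerges at
#' `leaf_interval * p` degree-days after transplanting; its curve passes 1/2
#' at `leaf_mid` degree-days past emergence with scale `leaf_scale`.
#'
#' @param ct Cumulative temperature since transplanting, degree-days
#'   (vectorised).
#' @param p Leaf number (1-based emergence order).
#' @param params [model_parameters()].
#' @return Relative growth in (0, 1).
#' @examples
#' p <- model_parameters()
#' leaf_relative_growth(160 + 218.86, 1, p) # 0.5 at the logistic midpoint
#' @export
leaf_relative_growth <- function(ct, p, params = model_parameters()) {
  params <- as_straw_params(params)
  if (any(p < 1) || any(p != floor(p))) {
    stop("leaf number p must be a positive integer", call. = FALSE)
  }
  x <- ct - params$leaf_interval * p
  1 - 1 / (1 + exp((x - params$leaf_mid) / params$leaf_scale))
}

#' Daily potential-growth increments of emerged leaves
#'
#' For every leaf that has emerged by `ct_now` (leaf `p` exists once
#' `ct_now >= leaf_interval * p`), the day's increment of its potential-growth
#' curve between `ct_prev` and `ct_now`, floored at zero. Leaves not yet
#' emerged contribute nothing.
#'
#' @param ct_now,ct_prev Cumulative temperature today and yesterday,
#'   degree-days, `ct_now >= ct_prev`.
#' @param params [model_parameters()].
#' @param max_leaves Safety cap on the number of tracked leaves.
#' @return Numeric vector of increments, one per emerged leaf (possibly
#'   length 0).
#' @examples
#' active_leaf_increments(480, 465) # leaves 1..3 contribute
#' @export
active_leaf_increments <- function(ct_now, ct_prev,
                                   params = model_parameters(),
                                   max_leaves = Inf) {
  params <- as_straw_params(params)
  if (ct_now < ct_prev) stop("ct_now must be >= ct_prev", call. = FALSE)
  n_leaves <- floor(ct_now / params$leaf_interval)
  n_leaves <- min(n_leaves, max_leaves)
  if (n_leaves < 1) return(numeric(0))
  p <- seq_len(n_leaves)
  pmax(0, leaf_relative_growth(ct_now, p, params) -
         leaf_relative_growth(ct_prev, p, params))
}

#' Fruit-cluster potential-growth curve
#'
#' Relative potential growth (0 to 1) of a fruit cluster, logistic in the
#' cumulative temperature since the inflorescence's first-flower anthesis:
#' `RFG = 1 / (1 + fruit_amp * exp(-fruit_rate * tf))`.
#'
#' @param tf Cumulative post-anthesis temperature, degree-days (>= 0,
#'   vectorised).
#' @param params [model_parameters()].
#' @return Relative growth in (0, 1); `1 / (1 + fruit_amp)` at anthesis.
#' @examples
#' fruit_relative_growth(0)                       # ~2.17e-4
#' fruit_relative_growth(log(4615.91) / 0.011)    # 0.5
#' @export
fruit_relative_growth <- function(tf, params = model_parameters()) {
  params <- as_straw_params(params)
  if (any(!is.finite(tf)) || any(tf < 0)) {
    stop("post-anthesis temperature sum tf must be finite and >= 0", call. = FALSE)
  }
  1 / (1 + params$fruit_amp * exp(-params$fruit_rate * tf))
}

#' Daily dry-weight growth increments of fruit clusters
#'
#' Each cluster's potential daily growth in grams: the increment of its
#' relative-growth curve times the cluster potential dry weight, floored at
#' zero. Clusters whose anthesis has not occurred (`tf_now = 0` and
#' `tf_prev = 0` by convention) contribute nothing.
#'
#' @param tf_now,tf_prev Per-cluster cumulative post-anthesis temperature
#'   today and yesterday, degree-days, elementwise `tf_now >= tf_prev`.
#' @param params [model_parameters()].
#' @return Numeric vector of increments, g per cluster.
#' @examples
#' cluster_increments(15, 0) # first day after anthesis
#' @export
cluster_increments <- function(tf_now, tf_prev,
                               params = model_parameters()) {
  params <- as_straw_params(params)
  if (length(tf_now) != length(tf_prev)) {
    stop("tf_now and tf_prev must have equal length", call. = FALSE)
  }
  if (length(tf_now) == 0L) return(numeric(0))
  if (any(tf_now < tf_prev)) stop("tf_now must be >= tf_prev", call. = FALSE)
  inc <- params$cluster_potential_dw *
    (fruit_relative_growth(tf_now, params) -
       fruit_relative_growth(tf_prev, params))
  # before anthesis both clocks sit at 0: difference is already 0
  pmax(0, inc)
}

#' Generative sink strength
#'
#' Total potential fruit growth of the day weighted by the fruit sink
#' coefficient: `GS = fruit_sink * sum(dRFG)`.
#'
#' @param drfg Per-cluster daily growth increments, g (>= 0).
#' @param params [model_parameters()].
#' @return Sink strength, g.
#' @examples
#' generative_sink(c(1.03, 0.40)) # 0.3432
#' @export
generative_sink <- function(drfg, params = model_parameters()) {
  params <- as_straw_params(params)
  if (any(drfg < 0)) stop("increments must be >= 0", call. = FALSE)
  params$fruit_sink * sum(drfg)
}

#' Vegetative sink strength
#'
#' Total potential leaf growth of the day weighted by the leaf sink
#' coefficient, scaled up to the whole vegetative plant (leaves, crown,
#' peduncles): `VS = veg_adjust * leaf_sink * sum(dRLG)`.
#'
#' @param drlg Per-leaf daily growth increments, dimensionless (>= 0).
#' @param params [model_parameters()].
#' @return Sink strength, g.
#' @examples
#' vegetative_sink(c(0.05, 0.04, 0.03)) # 0.01092
#' @export
vegetative_sink <- function(drlg, params = model_parameters()) {
  params <- as_straw_params(params)
  if (any(drlg < 0)) stop("increments must be >= 0", call. = FALSE)
  params$veg_adjust * params$leaf_sink * sum(drlg)
}
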