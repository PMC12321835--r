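#' Fraction of daily dry matter allocated to fruit
#'
#' Ratio of generative to total sink strength, `AF = GS / (GS + VS)`. When
#' both sinks are zero (before any leaf has emerged and any cluster has
#' flowered) the fraction is defined as 0.
#'
#' @param gs Generative sink strength, g (>= 0).
#' @param vs Vegetative sink strength, g (>= 0).
#' @return Allocation fraction in \[0, 1\].
#' @examples
#' fruit_partition_fraction(0.3432, 0.01092) # ~0.969
#' @export
fruit_partition_fraction <- function(gs, vs) {
  if (any(gs < 0) || any(vs < 0)) stop("sink strengths must be >= 0", call. = FALSE)
  tot <- gs + vs
  ifelse(tot > 0, gs / tot, 0)
}

#' Allocate the day's dry matter to fruit clusters
#'
#' The fruit share of the per-plant dry-matter increment, `(dDM / Pd) * AF`,
#' is divided among clusters in proportion to their potential growth
#' increments. When no cluster is growing all allocations are zero.
#'
#' @param ddm Daily dry-matter production, g m^-2 (>= 0).
#' @param af Fruit allocation fraction in \[0, 1\].
#' @param drfg Per-cluster potential growth increments, g (>= 0).
#' @param params [model_parameters()].
#' @return Per-cluster allocation, g per plant per cluster; sums exactly to
#'   `(ddm / pd) * af` whenever `sum(drfg) > 0`.
#' @examples
#' allocate_to_clusters(14.1, 0.8, c(1, 1)) # 0.8 g each
#' @export
allocate_to_clusters <- function(ddm, af, drfg, params = model_parameters()) {
  params <- as_straw_params(params)
  if (ddm < 0) stop("ddm must be >= 0", call. = FALSE)
  if (af < 0 || af > 1) stop("af must lie in [0, 1]", call. = FALSE)
  if (any(drfg < 0)) stop("increments must be >= 0", call. = FALSE)
  tot <- sum(drfg)
  if (length(drfg) == 0L || tot == 0) return(rep(0, length(drfg)))
  (ddm / params$pd) * af * (drfg / tot)
}

#' Accumulate cluster dry and fresh weights
#'
#' Cluster dry weight is the running sum of its daily allocations since
#' anthesis; fresh weight is dry weight divided by the fruit dry-matter
#' content.
#'
#' @param df_prev Per-cluster cumulative dry weight so far, g.
#' @param dmf Per-cluster allocation of the day, g (>= 0).
#' @param dmc Fruit dry-matter content, g g^-1, in (0, 1).
#' @return List with updated `df` (dry weight, g) and `ff` (fresh weight, g).
#' @examples
#' update_cluster_weights(c(2.0), c(0.5), 0.10)
#' @export
update_cluster_weights <- function(df_prev, dmf, dmc = 0.10) {
  if (any(dmf < 0)) stop("allocations must be >= 0", call. = FALSE)
  if (dmc <= 0 || dmc >= 1) stop("dmc must lie in (0, 1)", call. = FALSE)
  if (length(df_prev) != length(dmf)) {
    stop("df_prev and dmf must have equal length", call. = FALSE)
  }
  df <- df_prev + dmf
  list(df = df, ff = df / dmc)
}

#' Yield per unit ground area
#'
#' Per-plant fruit fresh weight summed over clusters, scaled by plant density
#' and converted to kilograms: `Y = sum(FF) * Pd / 1000`.
#'
#' @param ff Per-cluster cumulative fresh weight, g per plant (>= 0).
#' @param pd Plant density, plants m^-2.
#' @return Cumulative yield, kg m^-2.
#' @examples
#' yield_per_area(c(25, 15, 5), 7.05) # ~0.317
#' @export
yield_per_area <- function(ff, pd = 7.05) {
  if (any(ff < 0)) stop("fresh weights must be >= 0", call. = FALSE)
  if (pd <= 0) stop("pd must be > 0", call. = FALSE)
  sum(ff) * pd / 1000
}

#' Run the daily growth and yield simulation
#'
#' Executes the full daily loop over the climate series: leaf area is
#' interpolated onto each day; intercepted PAR and light-use efficiency give
#' the day's dry-matter production; degree-day clocks drive the potential
#' growth of every emerged leaf and every flowered cluster, whose weighted
#' sums are the vegetative and generative sink strengths; the generative
#' share of the day's assimilate is split among clusters in proportion to
#' their potential growth and accumulated into cluster dry and fresh weight,
#' finally scaled to a yield per square metre. Total dry matter starts at
#' `tdm0` on the transplant day and accumulates from the next day onward.
#'
#' @param env [environment_series()] covering the whole season, first day =
#'   transplant.
#' @param flowering [flowering_schedule()] (or a vector of anthesis dates);
#'   may be empty for a purely vegetative run.
#' @param leaf_area [leaf_area_series()] in LAI or iLAI mode.
#' @param params [model_parameters()].
#' @param max_leaves Safety cap on tracked leaves (default unlimited).
#' @return Object of class `straw_sim`: a `data.frame` with one row per day
#'   (columns `date`, `dat`, `temp_mean`, `sr`, `leaf_area`, `par`, `i`,
#'   `ddm`, `tdm`, `ct`, `n_leaves`, `gs`, `vs`, `af`, `fruit_dw`, `f`, `y`,
#'   plus wide per-cluster columns `dmf_q*`, `df_q*`, `ff_q*`), with the
#'   parameters and leaf-area mode attached as attributes.
#' @examples
#' env <- environment_series(as.Date("2021-09-18") + 0:59,
#'                           temp_mean = rep(18, 60), sr = rep(6, 60))
#' la <- leaf_area_series(as.Date("2021-09-18") + c(0, 59), c(0.3, 1.2))
#' fl <- flowering_schedule(as.Date("2021-09-18") + 55)
#' sim <- simulate_season(env, fl, la)
#' tail(sim$y, 1)
#' @export
simulate_season <- function(env, flowering, leaf_area,
                            params = model_parameters(),
                            max_leaves = Inf) {
  stopifnot(inherits(env, "straw_env"))
  params <- as_straw_params(params)
  if (!inherits(flowering, "straw_flowering")) {
    flowering <- flowering_schedule(flowering)
  }
  stopifnot(inherits(leaf_area, "straw_leaf_area"))
  mode <- attr(leaf_area, "mode")

  dates <- env$date
  n_days <- length(dates)
  if (length(flowering) &&
      (min(flowering) < dates[1L] || max(flowering) > dates[n_days])) {
    bad <- flowering[flowering < dates[1L] | flowering > dates[n_days]]
    stop(sprintf("anthesis date(s) outside the climate window %s..%s: %s",
                 dates[1L], dates[n_days],
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  la_range <- range(leaf_area$date)
  if (la_range[1L] > dates[n_days] || la_range[2L] < dates[1L]) {
    stop(sprintf("leaf-area observations (%s..%s) do not overlap the climate window %s..%s",
                 la_range[1L], la_range[2L], dates[1L], dates[n_days]),
         call. = FALSE)
  }

  la_daily <- interpolate_leaf_area(leaf_area, dates)
  if (mode == "ilai" && any(la_daily > 1)) la_daily <- pmin(la_daily, 1)
  par_daily <- par_from_radiation(env$sr, params)
  i_daily <- if (mode == "ilai") {
    intercepted_light_ilai(par_daily, la_daily)
  } else {
    intercepted_light(par_daily, la_daily, params$k)
  }
  ddm <- dm_production(i_daily, params$lue)
  ddm[1L] <- 0 # transplant day: initial biomass is tdm0, accumulation starts DAT 1
  tdm <- params$tdm0 + cumsum(ddm)
  ct <- cumsum(env$temp_mean)

  n_cl <- length(flowering)
  tf <- rep(0, n_cl)
  df <- rep(0, n_cl)
  ct_prev <- 0
  out_gs <- out_vs <- out_af <- out_nl <- numeric(n_days)
  out_dmf <- out_df <- out_ff <- matrix(0, n_days, n_cl)

  for (i in seq_len(n_days)) {
    ct_now <- ct[i]
    drlg <- active_leaf_increments(ct_now, ct_prev, params, max_leaves)
    tf_prev <- tf
    if (n_cl) {
      active <- dates[i] >= flowering
      tf <- tf + ifelse(active, env$temp_mean[i], 0)
    }
    drfg <- cluster_increments(tf, tf_prev, params)
    gs <- generative_sink(drfg, params)
    vs <- vegetative_sink(drlg, params)
    af <- fruit_partition_fraction(gs, vs)
    dmf <- allocate_to_clusters(ddm[i], af, drfg, params)
    upd <- update_cluster_weights(df, dmf, params$dmc)
    df <- upd$df
    out_gs[i] <- gs; out_vs[i] <- vs; out_af[i] <- af
    out_nl[i] <- length(drlg)
    if (n_cl) {
      out_dmf[i, ] <- dmf; out_df[i, ] <- df; out_ff[i, ] <- upd$ff
    }
    ct_prev <- ct_now
  }

  f <- if (n_cl) rowSums(out_ff) else numeric(n_days)
  y <- f * params$pd / 1000
  res <- data.frame(
    date = dates, dat = seq_len(n_days) - 1L,
    temp_mean = env$temp_mean, sr = env$sr, leaf_area = la_daily,
    par = par_daily, i = i_daily, ddm = ddm, tdm = tdm, ct = ct,
    n_leaves = out_nl, gs = out_gs, vs = out_vs, af = out_af,
    fruit_dw = if (n_cl) rowSums(out_df) else numeric(n_days),
    f = f, y = y
  )
  if (n_cl) {
    q <- seq_len(n_cl)
    dmf_df <- as.data.frame(out_dmf); names(dmf_df) <- paste0("dmf_q", q)
    df_df <- as.data.frame(out_df);  names(df_df) <- paste0("df_q", q)
    ff_df <- as.data.frame(out_ff);  names(ff_df) <- paste0("ff_q", q)
    res <- cbind(res, dmf_df, df_df, ff_df)
  }
  structure(res,
            params = params, leaf_area_mode = mode,
            n_clusters = n_cl, anthesis = as.Date(as.vector(flowering),
                                                  origin = "1970-01-01"),
            class = c("straw_sim", "data.frame"))
}

#' @export
print.straw_sim <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Strawberry season simulation: %d days (%s to %s), %d fruit cluster(s)\n",
              n, x$date[1L], x$date[n], attr(x, "n_clusters")))
  cat(sprintf("  leaf-area mode: %s\n", attr(x, "leaf_area_mode")))
  cat(sprintf("  final total DM: %.1f g/m^2; final yield: %.3f kg/m^2\n",
              x$tdm[n], x$y[n]))
  invisible(x)
}

#' Monthly yield increments
#'
#' Splits the cumulative yield trajectory into calendar-month increments
#' (cumulative yield at month end minus at the previous month end); the
#' increments sum exactly to the final cumulative yield.
#'
#' @param result A [simulate_season()] result.
#' @return `data.frame` with columns `month` (first day of month, `Date`),
#'   `yield` (increment, kg m^-2) and `yield_cum` (kg m^-2 at month end).
#' @export
monthly_yield <- function(result) {
  stopifnot(inherits(result, "straw_sim"), nrow(result) > 0L)
  month <- as.Date(format(result$date, "%Y-%m-01"))
  last <- !duplicated(month, fromLast = TRUE)
  cum <- result$y[last]
  data.frame(month = unique(month),
             yield = diff(c(0, cum)),
             yield_cum = cum)
}
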