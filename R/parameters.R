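#' Model parameters
#'
#' Container for every fixed coefficient of the simulator. Defaults are the
#' published calibration for 'Benihoppe' in forcing culture; any field can be
#' overridden for other cultivars or seasons.
#'
#' @param k Light-extinction coefficient of the canopy (dimensionless,
#'   Beer-Lambert). Not used when leaf area is supplied as an intercepted
#'   cover fraction (iLAI).
#' @param lue Light-use efficiency, g dry matter per MJ intercepted PAR.
#' @param dmc Fruit dry-matter content, g dry weight per g fresh weight.
#' @param tdm0 Initial above-ground dry matter at transplanting, g m^-2.
#' @param pd Plant density, plants m^-2.
#' @param par_fraction Fraction of global solar radiation that is PAR.
#' @param leaf_interval Cumulative temperature between successive leaf
#'   emergences, degree-days; leaf p emerges at `leaf_interval * p`.
#' @param leaf_mid Midpoint offset of the leaf potential-growth logistic,
#'   degree-days past emergence.
#' @param leaf_scale Scale of the leaf logistic, degree-days.
#' @param fruit_amp Pre-exponential constant of the fruit-cluster logistic
#'   (dimensionless); sets the relative size at anthesis,
#'   `1 / (1 + fruit_amp)`.
#' @param fruit_rate Rate constant of the fruit-cluster logistic, per
#'   degree-day.
#' @param cluster_potential_dw Potential final dry weight of one fruit
#'   cluster, g (dry-weight equivalent of a 250 g fresh harvest at
#'   `dmc = 0.10`).
#' @param fruit_sink Sink coefficient of fruit clusters (ratio of remaining
#'   fruit DW to plant DW at maximum fruit load).
#' @param leaf_sink Sink coefficient of individual leaves (ratio of remaining
#'   leaf DW to plant DW).
#' @param veg_adjust Multiplier converting the leaf sink to the whole
#'   vegetative sink (leaves + crown + peduncles), the reciprocal of the
#'   leaf-to-vegetative dry-weight ratio.
#'
#' @return An object of class `straw_params` (a validated named list).
#' @examples
#' p <- model_parameters()
#' p$lue
#' model_parameters(tdm0 = 19.0) # second-season initial biomass
#' @export
model_parameters <- function(k = 0.85,
                             lue = 2.75,
                             dmc = 0.10,
                             tdm0 = 19.9,
                             pd = 7.05,
                             par_fraction = 0.5,
                             leaf_interval = 160,
                             leaf_mid = 218.86,
                             leaf_scale = 74.61,
                             fruit_amp = 4615.91,
                             fruit_rate = 0.011,
                             cluster_potential_dw = 25,
                             fruit_sink = 0.24,
                             leaf_sink = 0.07,
                             veg_adjust = 1.3) {
  p <- list(
    k = k, lue = lue, dmc = dmc, tdm0 = tdm0, pd = pd,
    par_fraction = par_fraction, leaf_interval = leaf_interval,
    leaf_mid = leaf_mid, leaf_scale = leaf_scale,
    fruit_amp = fruit_amp, fruit_rate = fruit_rate,
    cluster_potential_dw = cluster_potential_dw,
    fruit_sink = fruit_sink, leaf_sink = leaf_sink,
    veg_adjust = veg_adjust
  )
  bad <- names(p)[!vapply(p, function(x) {
    is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
  }, logical(1))]
  if (length(bad)) {
    stop("model parameters must be single positive finite numbers; bad: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (p$dmc >= 1) stop("dmc must lie in (0, 1)", call. = FALSE)
  if (p$par_fraction >= 1) stop("par_fraction must lie in (0, 1)", call. = FALSE)
  if (p$k > 2) stop("k must lie in (0, 2]", call. = FALSE)
  structure(p, class = "straw_params")
}

#' @export
print.straw_params <- function(x, ...) {
  cat("Strawberry model parameters\n")
  cat(sprintf("  canopy:     k = %.3g, PAR fraction = %.2g, LUE = %.3g g/MJ\n",
              x$k, x$par_fraction, x$lue))
  cat(sprintf("  stand:      Pd = %.3g plants/m^2, TDM0 = %.3g g/m^2\n",
              x$pd, x$tdm0))
  cat(sprintf("  leaves:     emergence every %g degree-days, logistic mid %g, scale %g\n",
              x$leaf_interval, x$leaf_mid, x$leaf_scale))
  cat(sprintf("  clusters:   logistic amp %g, rate %g /degree-day, potential %g g\n",
              x$fruit_amp, x$fruit_rate, x$cluster_potential_dw))
  cat(sprintf("  sinks:      fruit %.3g, leaf %.3g x adjust %.3g; fruit DMC %.3g g/g\n",
              x$fruit_sink, x$leaf_sink, x$veg_adjust, x$dmc))
  invisible(x)
}

as_straw_params <- function(x) {
  if (inherits(x, "straw_params")) return(x)
  if (is.list(x)) return(do.call(model_parameters, x))
  stop("cannot interpret 'params'; use model_parameters()", call. = FALSE)
}
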