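---
title: "Modelling greenhouse strawberry yield from source-sink dry-matter partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling greenhouse strawberry yield from source-sink dry-matter partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strawsim)
```

## The model

`strawsim` simulates daily dry-matter (DM) production and fresh-weight yield
of June-bearing strawberry in Japanese forcing culture (transplant in
September, harvest December through April). It is a classical
light-use-efficiency crop model with an explicit source-sink partitioning
step at the level of individual leaves and fruit clusters.

**Supply.** Each day $n$, photosynthetically active radiation is half the
global solar integral, $PAR_n = 0.5\,Sr_n$. A Beer-Lambert canopy intercepts

$$I_n = PAR_n\,(1 - e^{-k\,LAI_n}),$$

with extinction coefficient $k = 0.85$. When leaf area is observed as a
camera-derived intercepted leaf-area index (iLAI, a projected cover
fraction), interception is simply $I_n = PAR_n \cdot iLAI_n$ and $k$ is not
needed. Daily DM production is $\Delta DM_n = I_n \cdot LUE$ with light-use
efficiency $LUE = 2.75$ g MJ$^{-1}$, and total DM accumulates from the
transplant biomass $TDM_0$ (19.9 g m$^{-2}$ by default).

**Demand.** Phenology runs on degree-days. The stand clock is
$CT_n = \sum_{0}^{n} T_n$ (inclusive of the transplant day). Leaf $p$
emerges once $CT_n \ge 160p$ and follows a logistic potential-growth curve
with midpoint 218.86 and scale 74.61 degree-days past emergence. Each
inflorescence is one fruit cluster whose clock $TF_{q,n}$ accumulates daily
mean temperature from its recorded first-flower anthesis date; its relative
growth is $RFG = 1/(1 + 4615.91\,e^{-0.011\,TF})$, and its daily increment
is scaled by the cluster potential of 25 g DW (the DW equivalent of a 250 g
fresh harvest per cluster). Sink strengths weight the summed daily
increments: generative $GS_n = 0.24 \sum_q \Delta RFG_{q,n}$ and vegetative
$VS_n = 1.3 \times 0.07 \sum_p \Delta RLG_{p,n}$, where 0.24 and 0.07 are
the fruit-to-plant and leaf-to-plant DW ratios and 1.3 scales the leaf sink
to the whole vegetative plant (crown and peduncles included).

**Partitioning and yield.** The fruit fraction is
$AF_n = GS_n/(GS_n + VS_n)$ (0 when both sinks are idle). The per-plant DM
increment $\Delta DM_n / P_d$ is split among clusters in proportion to their
$\Delta RFG$; cluster dry weight accumulates these allocations, converts to
fresh weight through the fruit dry-matter content ($DMC = 0.10$), and the
per-plant fruit fresh weight times plant density
($P_d = 7.05$ plants m$^{-2}$) over 1000 is the cumulative yield in
kg m$^{-2}$.

Two printed recurrences required a reading choice. The cluster dry-weight
recurrence, taken literally, adds only two consecutive daily allocations; we
accumulate the full running sum, the only reading under which cluster DW is
a cumulative dry weight that can be converted to the fresh weight of the
harvested cluster. Similarly the yield equation, taken literally, would
re-sum an already cumulative per-plant fresh weight over days; we compute
$Y_n = F_n \times P_d / 1000$ directly. The resulting cumulative yield
curves are monotone and close exactly on the per-cluster dry weights, which
the tests assert daily.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `k` | 0.85 | – | canopy light extinction (LAI mode only) |
| `lue` | 2.75 | g MJ$^{-1}$ | DM per MJ intercepted PAR |
| `dmc` | 0.10 | g g$^{-1}$ | fruit dry-matter content |
| `tdm0` | 19.9 | g m$^{-2}$ | above-ground DM at transplanting |
| `pd` | 7.05 | plants m$^{-2}$ | plant density |
| `leaf_interval` | 160 | °C d | degree-days between leaf emergences |
| `leaf_mid`, `leaf_scale` | 218.86, 74.61 | °C d | leaf logistic midpoint/scale |
| `fruit_amp`, `fruit_rate` | 4615.91, 0.011 | –, (°C d)$^{-1}$ | cluster logistic constants |
| `cluster_potential_dw` | 25 | g | potential cluster dry weight |
| `fruit_sink`, `leaf_sink`, `veg_adjust` | 0.24, 0.07, 1.3 | – | sink coefficients |

All are fields of `model_parameters()` and can be overridden per run; they
are a single-cultivar calibration ('Benihoppe') and should be re-estimated
for other cultivars.

## Design choices

* **LUE calibration** (`estimate_lue()`) fits an ordinary least-squares line
  of total DM on cumulative intercepted PAR with a *free* intercept and
  reports the slope. The calibration data start from a nonzero transplant
  biomass, so forcing the line through the origin would bias the slope; the
  free intercept recovers `tdm0` as a by-product.
* **Leaf-area interpolation** is linear between observation dates
  (`stats::approx`), with constant-nearest extrapolation outside the
  observed window — the conservative choice when the observation campaign
  starts after transplanting or ends before the last harvest.
* **iLAI semantics.** iLAI is treated as a light-interception fraction and
  clamped to [0, 1] with a warning; its nominal unit (m² m$^{-2}$) is kept
  in the interfaces for symmetry with LAI.
* **Summation bounds.** The stand degree-day clock includes the transplant
  day; a cluster's clock starts accumulating on its anthesis day. DM
  accumulation starts the day after transplanting so that the day-0 state
  equals the measured `tdm0`.
* **Monotone state.** Daily increments of both logistic curves are floored
  at zero, so leaf and cluster state is monotone even under pathological
  temperature inputs; under any non-decreasing temperature path the floor is
  inactive and increments telescope exactly (no drift, step-size invariant
  to machine precision).
* **No senescence or harvest submodel.** Fully expanded leaves naturally
  stop contributing to the vegetative sink; simulated cluster fresh weight
  is compared with cumulative yield directly, with no ripeness lag or
  removal rule.
* **R²** is reported as the coefficient of determination
  $1 - SSE/SST$ about the observed mean, which penalises bias; the squared
  Pearson correlation is available via `method = "pearson"`.
* **Degenerate inputs.** `AF = 0` when both sinks are zero; allocations are
  all zero on days with no growing cluster; interval fruit fractions require
  strictly increasing total DM and name the offending interval otherwise.

## The synthetic scenario generator

No greenhouse records ship with the package; `scenario_spec()` and the
`generate_*()` functions build complete, seed-reproducible input sets that
emulate a forcing-culture season:

* transplant 2021-09-18, 220-day season;
* daily mean temperature: annual sinusoid (mean 17.6 °C, amplitude 7 °C,
  peak at day-of-year 213) plus Gaussian noise (sd 0.8 °C), truncated to the
  climate-control envelope 9.8–25.5 °C;
* in-greenhouse solar radiation: sinusoid peaking at the summer solstice
  with mean 4.0 and amplitude 2.5 MJ m$^{-2}$ d$^{-1}$, noise sd 1.0,
  truncated to 1–18 MJ m$^{-2}$ d$^{-1}$, hence declining mid-winter. These
  constants were fixed by a one-off design calculation so that the default
  season's final total DM lands at the magnitude observed in forcing-culture
  validation stands (~630 g m$^{-2}$); the resulting cumulative yield
  (~4.7 kg m$^{-2}$) is typical of a full Japanese forcing season;
* anthesis of inflorescence 1 at 55 days after transplanting, then every
  53 days (3 clusters);
* LAI rising logistically from ~0.3 to a plateau of 3.0 (midpoint 100 DAT,
  scale 30 d), observed every 14 days; in iLAI mode the trajectory is mapped
  through $1 - e^{-k\,LAI}$;
* optional top-down canopy images: green ellipses on a soil background
  (`render_canopy_image()`), with the exact painted-pixel fraction returned
  as ground truth for the excess-green cover estimator
  (`estimate_ilai_from_image()`, classifying pixels by $2G - R - B$ above a
  configurable threshold — standard canopy-cover practice).

What the generator does *not* emulate: correlated multi-day weather spells,
canopy height growth under the camera, leaf overlap statistics of a real
canopy, pollination failures, or fruit thinning. Tests passing on synthetic
scenarios therefore demonstrate internal consistency of the implementation
and qualitative behaviour (e.g. the interval fruit fraction rising from the
pre-harvest to the full-harvest period), not predictive skill on real
greenhouse data, which requires the user's own climate, flowering and
leaf-area records.

## Problem sizes and numerical tolerances

The shipped tests simulate the full 220-day default season (a fraction of a
second) and check, daily: exact conservation
$\sum_q DMF_{q,n} = AF_n\,\Delta DM_n/P_d$ to $10^{-12}$ relative;
monotone TDM, cluster DW and yield; $AF \in [0,1]$; and the identity
$Y = (\sum_q DF_q / DMC)\,P_d/1000$. Telescoping of logistic increments is
asserted to $10^{-12}$ and step-size invariance to $10^{-6}$. LUE recovery
is exact ($10^{-9}$) on noiseless calibration data and within 5% across 20
seeded replicates with 5 g m$^{-2}$ observation noise. A pinned regression
freezes the default-season endpoint (TDM 639.12 g m$^{-2}$, yield
4.735 kg m$^{-2}$ at seed 0) against accidental behavioural drift.

## Known limitations

* Constant LUE assumes ~400 ppm CO₂ and no temperature or developmental
  dependence; CO₂-enriched houses need a dynamic LUE.
* No supra-optimal temperature correction: degree-days keep accruing above
  the optimum, which tends to overestimate early and late-season fruit
  growth.
* Allocation is supply-driven: cluster dry weight is not capped at the
  cluster potential, and with the published sink coefficients the fruit
  fraction approaches ~0.95 whenever clusters grow rapidly, so simulated
  yield is an upper envelope at the season edges.
* The camera pathway ignores canopy height and leaf angle; upright-petiole
  cultivars underestimate intercepting area, lowering simulated DM.

## A worked season

```{r}
spec <- scenario_spec(seed = 0)
sim <- simulate_season(generate_climate(spec),
                       generate_flowering_schedule(spec),
                       generate_lai_trajectory(spec, "lai"))
sim
monthly_yield(sim)
simulated_fruit_fraction(sim, spec$transplant + c(55, 92, 148, 182))
```
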