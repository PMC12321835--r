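test_that("fruit allocation fraction follows the sink ratio", {
  expect_equal(fruit_partition_fraction(0.2, 0.2), 0.5)
  expect_equal(fruit_partition_fraction(0, 0.5), 0)
  expect_equal(fruit_partition_fraction(0, 0), 0) # degenerate convention
  expect_equal(fruit_partition_fraction(0.3432, 0.01092),
               0.969162995594714, tolerance = 1e-12)
  expect_error(fruit_partition_fraction(-0.1, 0), ">= 0")
})

test_that("cluster allocation is proportional and conservative", {
  expect_equal(allocate_to_clusters(14.1, 0.8, c(1, 1)), c(0.8, 0.8))
  expect_equal(allocate_to_clusters(10, 0.5, c(0, 0)), c(0, 0))
  expect_equal(allocate_to_clusters(14.1, 0.6, 2.5), 14.1 / 7.05 * 0.6)
  # conservation property over generated cases
  set.seed(7)
  for (rep in 1:25) {
    ddm <- runif(1, 0, 20)
    af <- runif(1)
    drfg <- runif(sample(1:5, 1), 0, 2)
    dmf <- allocate_to_clusters(ddm, af, drfg)
    expect_equal(sum(dmf), ddm / 7.05 * af, tolerance = 1e-12)
    expect_true(all(dmf >= 0))
  }
})

test_that("cluster weights accumulate and convert to fresh weight", {
  df <- 0
  for (dmf in c(0.5, 0.5, 1.0)) df <- update_cluster_weights(df, dmf)$df
  expect_equal(df, 2.0)
  upd <- update_cluster_weights(2.5, 0, 0.10)
  expect_equal(upd$ff, 25) # 25 g DW potential <-> 250 g FW at DMC 0.10
  expect_equal(upd$df, 2.5) # zero allocation leaves DW unchanged
  expect_error(update_cluster_weights(1, -0.1), ">= 0")
})

test_that("yield per area scales fresh weight by plant density", {
  expect_equal(yield_per_area(c(25, 15, 5), 7.05), 45 * 7.05 / 1000)
  expect_equal(yield_per_area(numeric()), 0)
  expect_equal(yield_per_area(c(10, 20), 2 * 7.05),
               2 * yield_per_area(c(10, 20), 7.05))
})

test_that("zero radiation gives no growth; no anthesis gives no yield", {
  d0 <- as.Date("2021-09-18")
  env <- environment_series(d0 + 0:59, rep(18, 60), rep(0, 60))
  la <- leaf_area_series(d0 + c(0, 59), c(0.5, 2))
  dark <- simulate_season(env, d0 + 30, la)
  expect_true(all(dark$tdm == 19.9))
  expect_true(all(dark$y == 0))

  env2 <- environment_series(d0 + 0:59, rep(18, 60), rep(6, 60))
  veg <- simulate_season(env2, as.Date(character()), la)
  expect_true(all(veg$af == 0))
  expect_true(all(veg$y == 0))
  expect_gt(veg$tdm[60], veg$tdm[1])
})

test_that("anthesis outside the climate window is rejected", {
  d0 <- as.Date("2021-09-18")
  env <- environment_series(d0 + 0:29, rep(18, 30), rep(6, 30))
  la <- leaf_area_series(d0 + c(0, 29), c(0.5, 1))
  expect_error(simulate_season(env, d0 + 55, la), "outside the climate window")
  la_far <- leaf_area_series(d0 + 400 + c(0, 10), c(1, 2))
  expect_error(simulate_season(env, d0 + 10, la_far), "do not overlap")
})

test_that("daily allocation conserves dry matter along the whole season", {
  sim <- default_sim()
  p <- attr(sim, "params")
  dmf_cols <- grep("^dmf_q", names(sim))
  dmf_sum <- unname(rowSums(sim[dmf_cols]))
  target <- sim$af * sim$ddm / p$pd
  nz <- target > 0
  expect_true(all(abs(dmf_sum[nz] - target[nz]) / target[nz] < 1e-12))
  expect_true(all(dmf_sum[!nz] == 0))
  # vegetative share is the complement
  expect_equal(dmf_sum + (1 - sim$af) * sim$ddm / p$pd, sim$ddm / p$pd,
               tolerance = 1e-12)
})

test_that("state variables are monotone and mass closure holds", {
  sim <- default_sim()
  expect_true(all(diff(sim$tdm) >= 0))
  expect_true(all(diff(sim$y) >= 0))
  expect_true(all(sim$af >= 0 & sim$af <= 1))
  for (col in grep("^df_q", names(sim), value = TRUE)) {
    expect_true(all(diff(sim[[col]]) >= 0))
  }
  p <- attr(sim, "params")
  # fruit DW per plant cannot exceed total DM per plant
  expect_true(all(sim$fruit_dw <= sim$tdm / p$pd + 1e-9))
  # cumulative yield equals (sum DF / dmc) * pd / 1000 on every day
  expect_equal(sim$y, sim$fruit_dw / p$dmc * p$pd / 1000, tolerance = 1e-12)
})

test_that("the default synthetic season reproduces its pinned trajectory", {
  sim <- default_sim()
  n <- nrow(sim)
  expect_equal(n, 220L)
  # pinned regression values, computed once and frozen
  expect_equal(sim$tdm[n], 639.1178280252, tolerance = 1e-8)
  expect_equal(sim$y[n], 4.7353545176, tolerance = 1e-8)
  expect_gt(sim$tdm[n], 400)
  expect_lt(sim$tdm[n], 900)
  expect_gt(sim$y[n], 1)
  expect_lt(sim$y[n], 8)
})

test_that("monthly yields telescope to the cumulative total", {
  sim <- default_sim()
  mo <- monthly_yield(sim)
  expect_equal(sum(mo$yield), sim$y[nrow(sim)], tolerance = 1e-12)
  expect_true(all(mo$yield >= 0))
  expect_equal(mo$yield[1:2], c(0, 0)) # pre-anthesis months
  # one-month simulation collapses to a single row equal to the final yield
  d0 <- as.Date("2022-01-01")
  env <- environment_series(d0 + 0:30, rep(15, 31), rep(5, 31))
  la <- leaf_area_series(d0 + c(0, 30), c(2, 2.5))
  one <- simulate_season(env, d0 + 5, la)
  mo1 <- monthly_yield(one)
  expect_equal(nrow(mo1), 1L)
  expect_equal(mo1$yield, one$y[31])
})
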