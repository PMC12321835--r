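test_that("climate generation is deterministic per seed and bounded", {
  spec <- scenario_spec(seed = 0)
  a <- generate_climate(spec)
  b <- generate_climate(spec)
  expect_identical(a, b)
  c <- generate_climate(scenario_spec(seed = 1))
  expect_false(identical(a$temp_mean, c$temp_mean))
  expect_equal(nrow(a), 220L)
  expect_equal(a$date[1], as.Date("2021-09-18"))
  expect_true(all(a$temp_mean >= 9.8 & a$temp_mean <= 25.5))
  expect_true(all(a$sr >= 1 & a$sr <= 18))
  # mid-winter radiation is lower than early-autumn radiation
  expect_lt(mean(a$sr[a$date >= as.Date("2021-12-15") &
                        a$date <= as.Date("2022-01-15")]),
            mean(a$sr[a$date <= as.Date("2021-10-10")]))
})

test_that("noise-free climate equals the closed-form sinusoid", {
  spec <- scenario_spec(t_noise_sd = 0, sr_noise_sd = 0, seed = 5)
  env <- generate_climate(spec)
  doy <- as.integer(format(env$date, "%j"))
  t_expect <- pmin(pmax(17.6 + 7.0 * cos(2 * pi * (doy - 213) / 365.25),
                        9.8), 25.5)
  expect_equal(env$temp_mean, t_expect, tolerance = 1e-12)
})

test_that("flowering schedule places inflorescences at 55 + 53k DAT", {
  spec <- scenario_spec(seed = 0)
  fl <- generate_flowering_schedule(spec)
  expect_equal(as.integer(fl - spec$transplant), c(55, 108, 161))
  one <- generate_flowering_schedule(scenario_spec(n_clusters = 1))
  expect_equal(as.integer(one - spec$transplant), 55)
  expect_error(scenario_spec(anthesis_interval = 0), "> 0")
  expect_error(scenario_spec(n_clusters = 5), "beyond the season")
})

test_that("leaf-area trajectory rises to the plateau; iLAI maps cover", {
  spec <- scenario_spec(seed = 0)
  la <- generate_lai_trajectory(spec)
  expect_true(all(diff(as.numeric(la$date)) > 0))
  expect_true(all(diff(la$value) > 0))
  expect_equal(la$value[nrow(la)], 3.0, tolerance = 0.1)
  expect_lt(la$value[1], 0.45) # starts near the transplant LAI of ~0.3
  # iLAI mapping at a fixed LAI of 3: 1 - exp(-0.85 * 3)
  flat <- scenario_spec(lai_start = 3, lai_plateau = 3, seed = 0)
  ilai <- generate_lai_trajectory(flat, "ilai", k = 0.85)
  expect_equal(unique(round(ilai$value, 10)), round(1 - exp(-2.55), 10))
  expect_equal(attr(ilai, "mode"), "ilai")
})

test_that("LUE is recovered from model-generated calibration data", {
  spec <- scenario_spec(seed = 0)
  exact <- estimate_lue(generate_lue_calibration(spec, noise_sd = 0))
  expect_equal(exact$lue, 2.75, tolerance = 1e-9)
  for (s in 1:5) {
    noisy <- estimate_lue(generate_lue_calibration(scenario_spec(seed = s)))
    expect_lt(abs(noisy$lue - 2.75) / 2.75, 0.05)
  }
})

test_that("end-to-end simulation runs on a freshly generated scenario", {
  spec <- scenario_spec(seed = 3, season_days = 200, n_clusters = 3,
                        anthesis_interval = 50)
  sim <- simulate_season(generate_climate(spec),
                         generate_flowering_schedule(spec),
                         generate_lai_trajectory(spec, "ilai"))
  expect_equal(nrow(sim), 200L)
  expect_true(all(diff(sim$tdm) >= 0))
  expect_true(all(sim$af >= 0 & sim$af <= 1))
  expect_gt(sim$y[200], 0)
})

test_that("canopy rendering reports exact cover and is seed-stable", {
  bare <- render_canopy_image(canopy_image_spec(n_leaves = 0,
                                                width = 60, height = 40))
  expect_equal(bare$cover, 0)
  expect_equal(estimate_ilai_from_image(bare$image), 0)
  full <- render_canopy_image(canopy_image_spec(n_leaves = 1,
                                                leaf_radius = 4000,
                                                width = 60, height = 40))
  expect_equal(full$cover, 1)
  expect_equal(estimate_ilai_from_image(full$image), 1)
  a <- render_canopy_image(canopy_image_spec(seed = 9))
  b <- render_canopy_image(canopy_image_spec(seed = 9))
  expect_identical(a, b)
  expect_error(render_canopy_image(canopy_image_spec(width = 0)),
               "positive size")
})

test_that("excess-green estimator recovers rendered ground truth", {
  for (s in c(1, 2, 3)) {
    r <- render_canopy_image(canopy_image_spec(seed = s, n_leaves = 40))
    expect_gt(r$cover, 0.1)
    expect_lt(abs(estimate_ilai_from_image(r$image) - r$cover), 0.02)
  }
  expect_error(estimate_ilai_from_image(matrix(0, 3, 3)), "RGB")
})
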