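test_that("cumulative temperature is the inclusive sum from transplanting", {
  env <- make_env(rep(15, 11))
  expect_equal(cumulative_temperature(env, 10), 165)
  env2 <- make_env(c(18, 20))
  expect_equal(cumulative_temperature(env2, 0), 18)
  env3 <- make_env(c(10, 20, 30))
  expect_equal(cumulative_temperature(env3, 2), 60)
  expect_equal(cumulative_temperature(env3, 0:2), c(10, 30, 60))
  expect_error(cumulative_temperature(env3, 3), "day index")
})

test_that("leaf growth curve has the printed midpoint, tail and saturation", {
  expect_equal(leaf_relative_growth(160 * 1 + 218.86, 1), 0.5)
  expect_equal(leaf_relative_growth(160 * 4 + 218.86, 4), 0.5)
  expect_equal(leaf_relative_growth(160, 1), 0.0505275901561287,
               tolerance = 1e-12) # curve value right at emergence
  expect_gt(leaf_relative_growth(160 + 5000, 1), 1 - 1e-6)
  ct <- seq(0, 2000, by = 10)
  expect_true(all(diff(leaf_relative_growth(ct, 2)) > 0))
  expect_true(all(leaf_relative_growth(ct, 2) >= 0 &
                    leaf_relative_growth(ct, 2) <= 1))
  expect_error(leaf_relative_growth(100, 0), "positive integer")
})

test_that("only emerged leaves contribute daily increments", {
  expect_equal(active_leaf_increments(500, 500), rep(0, 3))
  expect_length(active_leaf_increments(480, 465), 3) # floor(480/160) = 3
  expect_length(active_leaf_increments(479, 465), 2)
  expect_length(active_leaf_increments(100, 90), 0)
  expect_length(active_leaf_increments(900, 880, max_leaves = 2), 2)
  # emergence bookkeeping vs brute force over a degree-day grid
  for (ct in seq(0, 2500, by = 170)) {
    n_brute <- sum(160 * seq_len(50) <= ct)
    expect_length(active_leaf_increments(ct, ct - 1e-9), n_brute)
  }
})

test_that("leaf increments telescope to the endpoint difference", {
  path <- seq(0, 1500, by = 15) # leaf 1 emerges at CT = 160
  incs <- vapply(seq_along(path)[-1], function(i) {
    d <- active_leaf_increments(path[i], path[i - 1])
    if (length(d)) d[1] else 0
  }, numeric(1))
  # first contribution happens on the step entering CT >= 160 (prev CT 150)
  expect_equal(sum(incs),
               leaf_relative_growth(1500, 1) - leaf_relative_growth(150, 1),
               tolerance = 1e-12)
})

test_that("fruit growth curve has the printed anthesis value and midpoint", {
  expect_equal(fruit_relative_growth(0), 1 / 4616.91, tolerance = 1e-12)
  mid <- log(4615.91) / 0.011
  expect_equal(fruit_relative_growth(mid), 0.5, tolerance = 1e-12)
  expect_gt(fruit_relative_growth(3000), 1 - 1e-9)
  tf <- seq(0, 3000, by = 25)
  expect_true(all(diff(fruit_relative_growth(tf)) > 0))
  expect_error(fruit_relative_growth(-1), ">= 0")
})

test_that("cluster increments telescope to the cluster potential", {
  expect_equal(cluster_increments(c(100, 200), c(100, 200)), c(0, 0))
  # one cluster, 15 degree-days per day for 200 days: total ~ potential 25 g
  tf <- seq(0, 3000, by = 15)
  incs <- cluster_increments(tf[-1], tf[-length(tf)])
  closed <- 25 * (fruit_relative_growth(3000) - fruit_relative_growth(0))
  expect_equal(sum(incs), closed, tolerance = 1e-12)
  expect_equal(sum(incs), 24.9945851224126, tolerance = 1e-9)
  # derivative-at-midpoint oracle: 25 * 0.25 * 0.011 * 15 ~ 1.03 g
  mid <- log(4615.91) / 0.011
  inc_mid <- cluster_increments(mid + 7.5, mid - 7.5)
  expect_equal(inc_mid, 25 * 0.25 * 0.011 * 15, tolerance = 0.05)
  expect_equal(inc_mid, 1.03066548572243, tolerance = 1e-9)
  expect_error(cluster_increments(10, 20), ">=")
})

test_that("step-size halving leaves cumulative cluster growth unchanged", {
  coarse <- seq(0, 3000, by = 15)
  fine <- seq(0, 3000, by = 7.5)
  s_coarse <- sum(cluster_increments(coarse[-1], coarse[-length(coarse)]))
  s_fine <- sum(cluster_increments(fine[-1], fine[-length(fine)]))
  expect_lt(abs(s_coarse - s_fine), 1e-6)
})

test_that("sink strengths apply the printed coefficients", {
  expect_equal(generative_sink(numeric()), 0)
  expect_equal(generative_sink(1.0), 0.24)
  expect_equal(generative_sink(c(1.03, 0.40)), 0.3432)
  expect_equal(vegetative_sink(numeric()), 0)
  expect_equal(vegetative_sink(1.0), 0.091)
  expect_equal(vegetative_sink(c(0.05, 0.04, 0.03)), 0.01092)
  expect_error(generative_sink(-1), ">= 0")
  expect_error(vegetative_sink(-1), ">= 0")
})
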