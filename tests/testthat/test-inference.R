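test_that("homing estimator inverts the transmission map", {
  expect_equal(estimate_homing(0.5), 0)
  expect_equal(estimate_homing(1), 1)
  expect_equal(estimate_homing(0.975), 0.95)
  expect_error(estimate_homing(0.4), "\\[0.5, 1\\]")
  # estimate_homing((1+e)/2) == e on a grid of e
  for (e in seq(0, 1, by = 0.05)) {
    expect_equal(estimate_homing((1 + e) / 2), e, tolerance = 1e-12)
  }
})

test_that("embryonic end-joining estimator reproduces the odds-ratio form", {
  expect_equal(estimate_embryonic_ej(0.975, 0.975), 0)
  expect_equal(estimate_embryonic_ej(0.596, 0.975), 0.7978947,
               tolerance = 1e-6)
  # limit: maternal transmission -> 0.5 implies full embryonic conversion
  expect_gt(estimate_embryonic_ej(0.5001, 0.975), 0.999)
  expect_error(estimate_embryonic_ej(0.6, 0.5), "no homing signal")
  expect_error(estimate_embryonic_ej(0.45, 0.975), "outside the model")
  expect_error(estimate_embryonic_ej(0.9, 0.8), ">=")
})

test_that("embryonic estimator is scale-free in the homing odds", {
  set.seed(21)
  for (i in 1:20) {
    ep <- stats::runif(1, 0.2, 1)
    em <- ep * stats::runif(1, 0.05, 1)
    cc <- stats::runif(1, 0.3, 1 / ep)
    base <- estimate_embryonic_ej((1 + em) / 2, (1 + ep) / 2)
    scaled <- estimate_embryonic_ej((1 + cc * em) / 2, (1 + cc * ep) / 2)
    expect_equal(base, scaled, tolerance = 1e-12)
  }
})

test_that("pooled transmission counts feed the estimators", {
  tab <- data.frame(lineage = c("a", "b", "c", "d"),
                    origin = c("maternal", "maternal", "paternal",
                               "paternal"),
                    n_positive = c(30, 29, 39, 98),  # pools: 59/100, 137/140
                    n_total = c(50, 50, 40, 100))
  est <- estimate_rates(tab)
  expect_equal(est$transmission_maternal, 0.59)
  expect_equal(est$transmission_paternal, 137 / 140)
  expect_equal(est$e_hat, 2 * 137 / 140 - 1)
  expect_equal(est$gamma_e_hat,
               1 - (2 * 0.59 - 1) / (2 * 137 / 140 - 1))
})

test_that("dominance fitting recovers the generating value on noise-free data", {
  base <- model_params()
  for (d_true in c(0.55, 0.7, 0.9)) {
    obs <- summarize_trajectory(simulate_drive(model_params(d = d_true),
                                               n_generations = 14))
    fit <- fit_dominance(obs, base, grid = seq(0.4, 1, by = 0.01))
    expect_equal(fit$d_hat, d_true, tolerance = 0.0100001)
    expect_false(fit$poorly_identified)
    # unique minimum on the grid
    expect_equal(sum(fit$sse_profile$sse == min(fit$sse_profile$sse)), 1)
  }
})

test_that("degenerate all-zero observations give a flagged boundary fit", {
  obs <- data.frame(generation = 0:10, drive_carrier_fraction = 0)
  fit <- fit_dominance(obs, model_params())
  expect_true(fit$poorly_identified)
})

test_that("dominance fitting validates its inputs", {
  obs <- data.frame(generation = 0:5, drive_carrier_fraction = 0.5)
  expect_error(fit_dominance(obs, model_params(), grid = numeric(0)),
               "empty")
  expect_error(fit_dominance(obs[1, ], model_params()), ">= 2")
  expect_error(fit_dominance(obs, model_params(), grid = c(0.5, 0.2)),
               "increasing")
})

test_that("fecundity summaries are plain mean +/- sample sd", {
  one <- fecundity_summary(data.frame(eggs = 100, hatch = 0.8))
  expect_equal(one["clutch_size", "mean"], 100)
  expect_true(is.na(one["clutch_size", "sd"]))

  two <- fecundity_summary(data.frame(eggs = c(100, 140),
                                      hatch = c(0.8, 0.7)))
  expect_equal(two["clutch_size", "mean"], 120)
  expect_equal(two["clutch_size", "sd"], 28.28427, tolerance = 1e-6)
  expect_equal(two["hatch_rate", "mean"], 0.75)
  expect_equal(two["hatch_rate", "sd"], 0.0707107, tolerance = 1e-6)

  same <- fecundity_summary(data.frame(eggs = c(90, 90), hatch = c(0.5, 0.5)))
  expect_equal(same["clutch_size", "sd"], 0)
  expect_error(fecundity_summary(data.frame(eggs = numeric(0),
                                            hatch = numeric(0))),
               "no clutch")
})
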