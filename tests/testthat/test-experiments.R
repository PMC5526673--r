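test_that("late-time decay exponent of the mean is -1 without response", {
  d <- decay_lambda0()
  expect_gt(d$slope_analytic, -1.15)
  expect_lt(d$slope_analytic, -0.85)
  # reproducible bit-identically
  d2 <- decay_lambda0()
  expect_identical(d$table, d2$table)
})

test_that("absorption scaling validates its design and censors openly", {
  expect_error(absorption_scaling(N_list = c(50, 100)), "at least 3")
  expect_error(absorption_scaling(N_list = c(100, 50, 200)),
               "ascending")
  expect_error(absorption_scaling(M = 5), ">= 10")
  # without quorum sensing and a quasi-continuous initial distribution,
  # fixation within a short cutoff is rare: censoring is reported,
  # not hidden
  expect_error(
    suppressWarnings(absorption_scaling(
      N_list = c(50, 100, 200), s = 0.2, lam = 0,
      R = response_fn("linear"), M = 10, t_cutoff = 5,
      init = init_dist("uniform"), seed = 1)),
    "censored|fewer than 3")
})

test_that("absorption times grow with N in the heterogeneous phase", {
  sc <- absorption_scaling(N_list = c(30, 60, 120), M = 10,
                           t_cutoff = 5e3, seed = 4)
  expect_true(all(sc$table$n_completed > 0))
  expect_gt(sc$gamma, 0)
  expect_true(is.finite(sc$gamma_se))
})

test_that("phase diagram separates the lambda window and needs kappa > 0", {
  pd <- phase_diagram(lam_grid = c(0.05, 0.15), kappa_grid = c(0, 0.2),
                      N = 500, M = 2, t_max = 300, seed = 6)
  tb <- pd$table
  expect_equal(pd$lambda_up, 0.1)
  cell <- function(l, k) tb[tb$lambda == l & tb$kappa == k, ]
  expect_true(cell(0.05, 0.2)$heterogeneous_sim)
  expect_true(cell(0.05, 0.2)$heterogeneous_theory)
  expect_false(cell(0.15, 0.2)$heterogeneous_sim)
  expect_false(cell(0.05, 0)$heterogeneous_sim)
  expect_false(cell(0.15, 0)$heterogeneous_sim)
  expect_error(phase_diagram(kappa_grid = 0.5), "1/pi")
})

test_that("simulated variance tracks the analytic order parameter", {
  v <- variance_vs_lambda(lam_grid = c(0.05, 0.12), N = 1000, M = 3,
                          t_max = 100, seed = 8)
  tb <- v$table
  expect_lt(abs(tb$variance_sim[1] - 0.1), 0.03)
  expect_lt(tb$variance_sim[2], 0.01)
  expect_equal(tb$variance_theory, c(0.1, 0))
})

test_that("bifurcation approach slows the relaxation monotonically", {
  bt <- bifurcation_timescale(a_grid = c(-0.4, -0.1, -0.02))
  expect_true(all(is.finite(bt$rate)))
  # clean exponential far from the bifurcation
  expect_gt(bt$r_squared[1], 0.99)
  # relaxation time strictly increases approaching the bifurcation
  expect_true(all(diff(bt$relaxation_time) > 0))
  expect_error(bifurcation_timescale(a_grid = c(-0.1, 0.1)),
               "negative")
})

test_that("homogeneous quench approaches its fixed point exponentially", {
  # above threshold the mean approaches the stable fixed point of R
  # exponentially fast
  R <- sinusoidal_R(0.2)
  tr <- mf_integrate(init_dist("uniform"), s = 0.2, lam = 0.2, R,
                     t_max = 60, record_every = 1)
  u <- 1 - tr$means
  ok <- u > 1e-3 & u < u[1] * 0.5
  fit <- lm(log(u[ok]) ~ tr$times[ok])
  expect_gt(summary(fit)$r.squared, 0.98)
  expect_lt(coef(fit)[2], 0)
})

test_that("noise channels broaden but do not destroy bimodality", {
  nr <- noise_robustness(sigma_grid = c(0, 0.02),
                         channels = "inherit", N = 2000, t_max = 100,
                         seed = 12)
  expect_equal(nrow(nr), 2L)
  noisy <- nr[nr$sigma > 0, ]
  expect_equal(noisy$modal_clusters, 2L)
  # the two bands stay separated by the order-R(beta) gap
  expect_gt(noisy$center_high - noisy$center_low, 0.5)
  expect_lt(abs(noisy$window_variance - 0.1), 0.03)
})

test_that("experiment dispatch writes reproducible artifacts", {
  expect_error(run_experiment("not_an_experiment"), "unknown experiment")
  d1 <- withr::local_tempdir()
  r1 <- run_experiment("decay_lambda0", out_dir = d1,
                       make_plots = FALSE)
  expect_true(file.exists(file.path(d1, "analytic.csv")))
  expect_true(file.exists(file.path(d1, "manifest.yaml")))
  d2 <- withr::local_tempdir()
  run_experiment("decay_lambda0", out_dir = d2, make_plots = FALSE)
  expect_identical(readLines(file.path(d1, "analytic.csv")),
                   readLines(file.path(d2, "analytic.csv")))
  # config-driven dispatch with overrides
  cfg <- parse_config(text = paste(
    "model: {N: 400, s: 0.2, lam: 0.05, seed: 3}",
    "response: {family: sinusoidal, kappa: 0.2}",
    "experiment: {id: histogram_evolution, M: 2, t_max: 20}",
    sep = "\n"))
  res <- run_experiment("histogram_evolution", config = cfg)
  expect_equal(res$ensemble$M, 2L)
  expect_equal(max(res$ensemble$times), 20)
})

test_that("initial-distribution robustness driver needs several inits", {
  expect_error(initial_robustness(init_list = list(init_dist("uniform"))),
               "at least 2")
})
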