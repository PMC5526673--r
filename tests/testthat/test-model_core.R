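test_that("fitness is the affine cost of production and validates inputs", {
  expect_equal(fitness(0, 0.2), 1.0)
  expect_equal(fitness(1, 0.2), 0.8)
  expect_equal(fitness(0.5, 0), 1.0)
  # affine and order-reversing for s > 0
  p <- sort(runif(50))
  expect_true(all(diff(fitness(p, 0.3)) <= 0))
  expect_true(all(fitness(p, 0.99) > 0))
  expect_error(fitness(1.2, 0.2), "\\[0, 1\\]")
  expect_error(fitness(0.5, 1), "s must satisfy")
  expect_error(fitness(-0.1, 0.2), "\\[0, 1\\]")
})

test_that("sinusoidal response up-regulates and stays in [0, 1]", {
  R <- sinusoidal_R(0.2)
  expect_equal(response_eval(R, 0.5), 0.7)
  expect_equal(response_eval(R, 0), 0)
  expect_equal(response_eval(R, 1), 1)
  x <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(response_eval(R, x) > x))
  expect_true(all(response_eval(R, x) <= 1))
  # the up-regulation gain is symmetric about x = 1/2
  expect_equal(response_eval(R, x) - x,
               response_eval(R, 1 - x) - (1 - x))
  expect_equal(response_eval(response_fn("linear"), 0.37), 0.37)
  expect_error(response_fn("sinusoidal", kappa = 0.4), "1/pi")
  expect_error(response_eval(R, 1.5), "\\[0, 1\\]")
})

test_that("response derivatives agree with finite differences", {
  for (R in list(sinusoidal_R(0.15),
                 response_fn("hill_bistable", hill_n = 4,
                             hill_theta = 0.5),
                 response_fn("pitchfork", a = -0.2, b = 1))) {
    x <- seq(0.05, 0.95, by = 0.09)
    h <- 1e-6
    num <- (response_eval(R, x + h) - response_eval(R, x - h)) / (2 * h)
    expect_equal(response_deriv(R, x), num, tolerance = 1e-5)
  }
})

test_that("fixed points and their stability match the sketched families", {
  fp <- response_fixed_points(sinusoidal_R(0.2))
  expect_equal(fp$location, c(0, 1))
  expect_equal(fp$stability, c("unstable", "stable"))

  fp2 <- response_fixed_points(response_fn("hill_bistable", hill_n = 4,
                                           hill_theta = 0.5))
  expect_equal(nrow(fp2), 3L)
  expect_equal(fp2$stability, c("stable", "unstable", "stable"))
  expect_equal(fp2$location[c(1, 3)], c(0, 1))
  expect_gt(fp2$location[2], 0)
  expect_lt(fp2$location[2], 1)

  # the identity response is a marginal continuum, flagged as such
  fp3 <- response_fixed_points(sinusoidal_R(0))
  expect_equal(fp3$stability, c("marginal", "marginal"))
})

test_that("fixed-point finder agrees with a brute-force grid scan", {
  fams <- list(sinusoidal_R(0.1), sinusoidal_R(0.3),
               response_fn("hill_bistable", hill_n = 3,
                           hill_theta = 0.4),
               response_fn("pitchfork", a = 0.2, b = 1),
               response_fn("pitchfork", a = -0.3, b = 1))
  for (R in fams) {
    found <- response_fixed_points(R)$location
    brute <- grid_fixed_points(R)
    expect_equal(length(found), length(brute))
    expect_true(all(abs(found - brute) < 1e-3))
  }
})

test_that("initial distributions expose correct moments and sampling", {
  u <- init_dist("uniform")
  expect_equal(init_mean(u), 0.5)
  expect_equal(init_mean_fitness(u, 0.2), 0.9)
  st <- sample_init(u, 1e4, seed = 1)
  expect_lt(abs(mean(st$degrees) - 0.5), 4 * sqrt(1 / 12 / 1e4))

  a <- init_dist("atoms", locations = c(0, 1), weights = c(0.5, 0.5))
  st2 <- sample_init(a, 100, seed = 7)
  expect_true(all(st2$degrees %in% c(0, 1)))

  d <- init_dist("atoms", locations = 0.3, weights = 1)
  expect_true(all(sample_init(d, 10, seed = 2)$degrees == 0.3))

  tg <- init_dist("truncgauss", mean = 0.3, sd = 0.15)
  st3 <- sample_init(tg, 2e4, seed = 3)
  expect_lt(abs(mean(st3$degrees) - init_mean(tg)),
            4 * sd(st3$degrees) / sqrt(2e4))
  expect_true(all(st3$degrees >= 0 & st3$degrees <= 1))

  tb <- init_dist("table", table = cbind(c(0, 0.5, 1), c(0, 2, 0)))
  st4 <- sample_init(tb, 2e4, seed = 4)
  expect_lt(abs(mean(st4$degrees) - 0.5),
            4 * sd(st4$degrees) / sqrt(2e4))
  expect_equal(init_mean(tb), 0.5, tolerance = 1e-6)

  # identical seeds are bit-identical
  expect_identical(sample_init(u, 500, seed = 11)$degrees,
                   sample_init(u, 500, seed = 11)$degrees)
})

test_that("atom measures normalize, merge and report exact moments", {
  m <- atom_measure(c(0, 0.7), c(2, 5))
  expect_equal(sum(m$weights), 1)
  expect_equal(measure_mean(m), 0.5)
  expect_equal(measure_var(m), 0.1)

  # atoms closer than the merge tolerance collapse to the centroid
  m2 <- atom_measure(c(0.3, 0.3 + 5e-5, 0.8), c(1, 1, 2))
  expect_equal(length(m2$locations), 2L)
  expect_equal(m2$locations[1], 0.3 + 2.5e-5)
  expect_true(all(diff(m2$locations) > 1e-4))

  expect_error(atom_measure(c(0.2, 1.3), c(1, 1)), "\\[0, 1\\]")
  expect_error(atom_measure(0.5, 0), "positive")

  st <- population_state(c(0.2, 0.2, 0.8, 0.8, 0.8))
  sm <- state_measure(st)
  expect_equal(sm$locations, c(0.2, 0.8))
  expect_equal(sm$weights, c(0.4, 0.6))
})

test_that("model parameter validation enforces the model's ranges", {
  expect_error(model_params(1, 0.2, 0.05), "N must be")
  expect_error(model_params(100, 1, 0.05), "0 <= s < 1")
  expect_error(model_params(100, -0.1, 0.05), "0 <= s < 1")
  expect_error(model_params(100, 0.2, 1.5), "0 <= lam <= 1")
  expect_error(noise_settings(sigma_inherit = -1), "non-negative")
  p <- model_params(100, 0.2, 0.05, seed = 5)
  expect_equal(p$N, 100L)
  expect_equal(p$seed, 5L)
})
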