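test_that("kinetic-equation right-hand side conserves mass by construction", {
  R <- sinusoidal_R(0.2)
  # single atom without response: stationary
  m1 <- atom_measure(0.4, 1)
  r1 <- autoinducer_rhs(m1, s = 0.2, lam = 0, R)
  expect_equal(r1$dweights, 0)
  expect_equal(r1$injection_rate, 0)

  # two equal atoms at 0 and 1: replicator transfer at rate s/4
  m2 <- atom_measure(c(0, 1), c(0.5, 0.5))
  r2 <- autoinducer_rhs(m2, s = 0.2, lam = 0, R)
  expect_equal(r2$dweights, c(0.05, -0.05))

  # single atom at a fixed point with response: injection lands on the
  # atom and cancels its decay
  m3 <- atom_measure(1, 1)
  r3 <- autoinducer_rhs(m3, s = 0.2, lam = 0.3, R)
  expect_equal(r3$injection_location, 1)
  expect_equal(sum(r3$dweights) + r3$injection_rate, 0)

  # mass conservation on random measures at random parameters
  set.seed(8)
  for (k in 1:20) {
    m <- random_measure()
    r <- autoinducer_rhs(m, s = runif(1, 0.01, 0.9), lam = runif(1), R)
    expect_lt(abs(sum(r$dweights) + r$injection_rate), 1e-12)
  }
  expect_error(autoinducer_rhs(structure(list(locations = 0.5,
                                              weights = 2,
                                              merge_tol = 1e-4),
                                         class = "atom_measure"),
                               0.2, 0.1, R),
               "normalized")
})

test_that("integrator conserves normalization at every record", {
  tr <- mf_integrate(init_dist("uniform"), s = 0.3, lam = 0.08,
                     sinusoidal_R(0.2), t_max = 30, record_every = 1)
  for (m in tr$measures)
    expect_lt(abs(sum(m$weights) - 1), 1e-9)
})

test_that("integrator reproduces the closed form without response", {
  m0 <- discretize_init(init_dist("uniform"), 400)
  tr <- mf_integrate(m0, s = 0.2, lam = 0, response_fn("linear"),
                     t_max = 50, record_every = 5)
  for (k in seq_along(tr$times)) {
    cf <- closed_form_lambda0(m0, s = 0.2, t = tr$times[k])
    expect_lt(measure_distance(tr$measures[[k]], cf), 1e-3)
  }
})

test_that("integrator reproduces the linear-response lambda = 1/2 mixture", {
  m0 <- discretize_init(init_dist("uniform"), 400)
  tr <- mf_integrate(m0, s = 0.2, lam = 0.5, response_fn("linear"),
                     t_max = 10, record_every = 1)
  for (k in seq_along(tr$times)) {
    cf <- closed_form_linear_half(m0, s = 0.2, t = tr$times[k])
    expect_lt(measure_distance(tr$measures[[k]], cf), 1e-3)
  }
})

test_that("two-atom reduction without response is the logistic ODE", {
  m0 <- atom_measure(c(0, 1), c(0.5, 0.5))
  tr <- mf_integrate(m0, s = 0.2, lam = 0, response_fn("linear"),
                     t_max = 10, dt_max = 1e-3, record_every = 0.5)
  w1 <- vapply(tr$measures, function(m) {
    if (length(m$locations) == 2L) m$weights[2L] else 0
  }, numeric(1))
  expect_lt(max(abs(w1 - logistic_producer(0.5, 0.2, tr$times))), 1e-6)
})

test_that("closed forms evaluate their printed formulas", {
  u <- init_dist("uniform")
  # t = 0 returns the initial distribution
  cf0 <- closed_form_lambda0(u, s = 0.2, t = 0)
  expect_equal(cf0$mean, 0.5, tolerance = 1e-10)
  # quadrature oracle: mean of e^(-stp) reweighted uniform
  cf <- closed_form_lambda0(u, s = 0.2, t = 10)
  expect_equal(cf$mean, uniform_reweighted_mean(0.2, 10),
               tolerance = 1e-9)
  expect_equal(cf$mean, 0.34348236, tolerance = 1e-6)
  # a single atom is stationary
  a <- closed_form_lambda0(init_dist("atoms", locations = 0.3,
                                     weights = 1), s = 0.2, t = 37)
  expect_equal(a$locations, 0.3)
  expect_equal(a$weights, 1)

  # lambda = 1/2 mixture weights
  m_t0 <- closed_form_linear_half(u, s = 0.2, t = 0)
  expect_equal(measure_mean(m_t0), 0.5, tolerance = 1e-12)
  m5 <- closed_form_linear_half(u, s = 0.2, t = 5)
  # mass at the initial mean is 1 - exp(-phibar0 t) plus the central
  # atoms of the discretized uniform
  y5 <- exp(-0.9 * 5)
  expect_equal(y5, 0.011109, tolerance = 1e-4)
  k <- which.max(m5$weights)
  expect_equal(m5$locations[k], 0.5, tolerance = 2e-3)
  expect_gt(m5$weights[k], 1 - y5 - 1e-6)
  m_inf <- closed_form_linear_half(u, s = 0.2, t = 1e3)
  expect_equal(measure_mean(m_inf), 0.5, tolerance = 1e-9)
  expect_lt(measure_var(m_inf), 1e-6)

  expect_error(closed_form_linear_half(u, 0.2, 1, R = sinusoidal_R(0.2)),
               "linear")
  expect_error(closed_form_linear_half(u, 0.2, 1, lam = 0.3), "1/2")
})

test_that("transport distance is a metric with known values", {
  d1 <- atom_measure(0.2, 1)
  expect_equal(measure_distance(d1, atom_measure(0.2, 1)), 0)
  expect_equal(measure_distance(atom_measure(0, 1), atom_measure(1, 1)),
               1)
  # uniform grid vs its median: mean absolute deviation = 1/4
  grid <- atom_measure((seq_len(100) - 0.5) / 100, rep(0.01, 100))
  expect_equal(measure_distance(grid, atom_measure(0.5, 1)), 0.25,
               tolerance = 1e-3)
  set.seed(5)
  for (k in 1:15) {
    a <- random_measure(); b <- random_measure(); c <- random_measure()
    dab <- measure_distance(a, b)
    expect_equal(dab, measure_distance(b, a), tolerance = 1e-14)
    expect_gte(dab, 0)
    expect_lte(dab,
               measure_distance(a, c) + measure_distance(c, b) + 1e-12)
  }
})

test_that("bimodal stationary measure is a fixed point of the integrator", {
  R <- sinusoidal_R(0.2)
  sol <- heterogeneous_solution(R, s = 0.2, lam = 0.05)
  m0 <- stationary_measure(sol)
  tr <- mf_integrate(m0, s = 0.2, lam = 0.05, R, t_max = 10,
                     record_every = 10)
  expect_lt(measure_distance(m0, tr$measure), 1e-3)
})

test_that("empirical and mean-field measures converge with N", {
  # transport distance between the stochastic empirical measure and the
  # mean-field solution at t = 20 decreases with N (O(N^{-1/2}))
  R <- sinusoidal_R(0.2)
  init <- init_dist("uniform")
  mf <- mf_integrate(init, s = 0.2, lam = 0.05, R, t_max = 20,
                     record_every = 20)
  dists <- vapply(c(100, 1000, 10000), function(N) {
    ds <- vapply(1:3, function(r) {
      pars <- model_params(N, 0.2, 0.05, seed = derive_seed(77, N + r))
      tr <- simulate_qs(pars, R, init, t_max = 20, record_every = 20)
      measure_distance(state_measure(tr$final_state), mf$measure)
    }, numeric(1))
    mean(ds)
  }, numeric(1))
  expect_true(all(diff(dists) < 0))
  expect_lt(dists[3], 0.02)
})

test_that("above-threshold integration homogenizes onto a fixed point", {
  R <- sinusoidal_R(0.2)
  st <- mf_stationary_state(init_dist("uniform"), s = 0.2, lam = 0.2, R,
                            t_max = 500)
  expect_true(st$converged)
  expect_lt(measure_var(st$measure), 1e-6)
  # the surviving atom sits at a fixed point of R (here the stable one
  # at 1)
  expect_lt(abs(measure_mean(st$measure) - 1), 1e-3)
})
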