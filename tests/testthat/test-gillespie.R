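test_that("single update steps preserve the state-space invariants", {
  set.seed(1)
  R <- sinusoidal_R(0.2)
  # lambda = 0: copying preserves a uniform state
  pars0 <- model_params(20, 0.2, 0)
  st <- population_state(rep(0.4, 20))
  for (k in 1:5) st <- gillespie_step(st, pars0, R)$state
  expect_true(all(st$degrees == 0.4))

  # lambda = 1 at a fixed point of R: state unchanged
  pars1 <- model_params(20, 0.2, 1)
  st1 <- population_state(rep(1, 20))
  for (k in 1:5) st1 <- gillespie_step(st1, pars1, R)$state
  expect_true(all(st1$degrees == 1))

  # generic steps keep N and the [0,1] range, with and without noise
  for (noise in list(noise_settings(),
                     noise_settings(0.05, 0.05, 0.05))) {
    pars <- model_params(30, 0.3, 0.2, noise = noise)
    st <- sample_init(init_dist("uniform"), 30)
    for (k in 1:50) {
      out <- gillespie_step(st, pars, R)
      st <- out$state
      expect_length(st$degrees, 30L)
      expect_true(all(st$degrees >= 0 & st$degrees <= 1))
      expect_gt(out$wait, 0)
    }
  }
})

test_that("noise-free degrees are inherited or assigned response values", {
  set.seed(42)
  R <- sinusoidal_R(0.2)
  pars <- model_params(30, 0.2, 0.3)
  st <- sample_init(init_dist("uniform"), 30)
  seen <- st$degrees
  for (k in 1:300) {
    out <- gillespie_step(st, pars, R)
    # any responded slot contributes R(sensed) to the provenance set
    seen <- c(seen, out$info$values[out$info$responded])
    st <- out$state
    expect_true(all(st$degrees %in% seen))
  }
})

test_that("N = 2 fixation matches the exact two-state Markov chain", {
  # degrees (0, 1), lambda = 0: one event fixes the population; the
  # waiting time is Exp(2 - s) and the survivor is the non-producer with
  # probability 1/(2 - s)
  set.seed(123)
  s <- 0.2
  M <- 10000
  R <- response_fn("linear")
  t_abs <- numeric(M)
  survivor0 <- logical(M)
  for (k in seq_len(M)) {
    pars <- model_params(2, s, 0)
    res <- absorption_time(pars, R, population_state(c(0, 1)),
                           t_cutoff = 1e3)
    t_abs[k] <- res$t_abs
    survivor0[k] <- res$final_degree == 0
  }
  expect_true(all(is.finite(t_abs)))
  m_exp <- 1 / (2 - s)
  expect_lt(abs(mean(t_abs) - m_exp), 3 * sd(t_abs) / sqrt(M))
  p_exp <- 1 / (2 - s)
  expect_lt(abs(mean(survivor0) - p_exp),
            3 * sqrt(p_exp * (1 - p_exp) / M))
  # full-distribution check against the exponential law
  expect_gt(ks.test(t_abs, "pexp", rate = 2 - s)$p.value, 0.01)
})

test_that("two-type dynamics without response follow the replicator ODE", {
  # N large, lambda = 0: producer fraction follows the logistic solution
  s <- 0.2
  pars <- model_params(10000, s, 0, seed = 21)
  init <- init_dist("atoms", locations = c(0, 1), weights = c(0.5, 0.5))
  ens <- ensemble_qs(pars, response_fn("linear"), init, t_max = 10,
                     M = 5, record_every = 1)
  x10 <- ens$mean_means[ens$times == 10]
  expected <- logistic_producer(0.5, s, 10)
  # drift-dominated spread ~ sqrt(x0(1-x0) * 2t/N) per replicate
  tol <- 3 * sqrt(0.25 * 2 * 10 / 10000) / sqrt(5)
  expect_lt(abs(x10 - expected), tol)
  # the whole mean trajectory tracks the logistic curve
  expect_lt(max(abs(ens$mean_means -
                      logistic_producer(0.5, s, ens$times))), 3 * tol)
})

test_that("simulation is bit-reproducible for a fixed seed", {
  R <- sinusoidal_R(0.2)
  pars <- model_params(300, 0.2, 0.05, seed = 99)
  t1 <- simulate_qs(pars, R, init_dist("uniform"), t_max = 10)
  t2 <- simulate_qs(pars, R, init_dist("uniform"), t_max = 10)
  expect_identical(t1$means, t2$means)
  expect_identical(t1$final_state$degrees, t2$final_state$degrees)
  e1 <- ensemble_qs(pars, R, init_dist("uniform"), t_max = 5, M = 3)
  e2 <- ensemble_qs(pars, R, init_dist("uniform"), t_max = 5, M = 3)
  expect_identical(e1$pooled_histograms, e2$pooled_histograms)
  expect_identical(e1$seeds, e2$seeds)
  expect_equal(length(unique(e1$seeds)), 3L)
})

test_that("trajectory bookkeeping: histograms sum to N, times increase", {
  pars <- model_params(500, 0.2, 0.1, seed = 3)
  tr <- simulate_qs(pars, sinusoidal_R(0.2), init_dist("uniform"),
                    t_max = 20, record_every = 2)
  expect_true(all(diff(tr$times) > 0))
  expect_true(all(rowSums(tr$histograms) == 500))
  expect_true(all(tr$variances >= 0))
})

test_that("observables report moments, histogram and cluster structure", {
  o1 <- observables(rep(0.4, 100))
  expect_equal(o1$mean, 0.4)
  expect_equal(o1$variance, 0)
  expect_equal(sum(o1$histogram > 0), 1L)
  expect_equal(o1$cluster_count, 1L)

  p2 <- c(rep(0, 50), rep(0.7, 50))
  o2 <- observables(p2, gap = 0.05)
  expect_equal(o2$mean, 0.35)
  expect_equal(o2$variance, 0.1225)
  expect_equal(o2$cluster_count, 2L)
  expect_equal(sum(o2$histogram > 0), 2L)

  # two-atom state with weights 2/7 and 5/7: moments of the bimodal
  # stationary solution
  n <- 7000
  p3 <- c(rep(0, 2000), rep(0.7, 5000))
  o3 <- observables(p3)
  expect_equal(o3$mean, 0.5)
  expect_equal(o3$variance, 0.1)

  # stragglers below the mass threshold do not count as clusters
  p4 <- c(rep(0, 500), 0.35, rep(0.7, 499))
  expect_equal(observables(p4)$cluster_count, 2L)
  expect_error(observables(p2, gap = 0), "gap")
  expect_error(observables(p2, bins = 1), "bins")
})

test_that("absorbing states are detected per the fixed-point rule", {
  R <- sinusoidal_R(0.2)
  expect_true(detect_absorbing(population_state(rep(0, 10)), R, 0.05))
  expect_false(detect_absorbing(population_state(rep(0.3, 10)), R, 0.05))
  expect_true(detect_absorbing(population_state(rep(0.3, 10)), R, 0))
  expect_false(detect_absorbing(population_state(c(0, rep(0.3, 9))), R, 0))
  # already-absorbing initial state: T_abs = 0
  pars <- model_params(10, 0.2, 0, seed = 1)
  res <- absorption_time(pars, R,
                         init_dist("atoms", locations = 0.3, weights = 1))
  expect_true(res$reached)
  expect_equal(res$t_abs, 0)
  expect_equal(res$final_degree, 0.3)
})

test_that("quasi-stationary bimodality emerges at small lambda", {
  # the paper-scale heterogeneous regime: two gap-separated
  # subpopulations near 0 and R(beta) = 0.7, variance near
  # beta (R(beta) - beta) = 0.1
  pars <- model_params(10000, 0.2, 0.05, seed = 2024)
  tr <- simulate_qs(pars, sinusoidal_R(0.2), init_dist("uniform"),
                    t_max = 100, record_every = 5)
  idx <- tr$times >= 50
  expect_lt(abs(mean(tr$variances[idx]) - 0.1), 0.02)
  pm <- production_modes(tr$final_state)
  expect_equal(pm$count, 2L)
  expect_lt(abs(pm$modes$center[1] - 0), 0.1)
  expect_lt(abs(pm$modes$center[2] - 0.7), 0.1)
})

test_that("histogram modes count subpopulations without fragmenting tails", {
  # two dense bands with a sparse scatter of drifted lineages between
  # them: two modes, even though sorted-point gaps would fragment the
  # low band
  set.seed(14)
  p <- c(runif(2500, 0, 0.12), 0.18, 0.22, 0.3,
         runif(7000, 0.68, 0.76))
  pm <- production_modes(p)
  expect_equal(pm$count, 2L)
  expect_lt(abs(pm$modes$center[1] - 0.06), 0.03)
  expect_lt(abs(pm$modes$center[2] - 0.72), 0.03)
  # a uniform state is one mode; short low-density dips do not split
  expect_equal(production_modes(rep(0.4, 500))$count, 1L)
  expect_equal(production_modes(runif(5000))$count, 1L)
  # all-sparse input yields no mode above the mass floor
  expect_equal(production_modes(seq(0, 1, length.out = 201),
                                min_frac = 0.2)$count, 0L)
})

test_that("homogenizing regime above threshold collapses the variance", {
  pars <- model_params(2000, 0.2, 0.2, seed = 5)
  tr <- simulate_qs(pars, sinusoidal_R(0.2), init_dist("uniform"),
                    t_max = 100, record_every = 10)
  n <- length(tr$times)
  expect_lt(tr$variances[n], 1e-3)
  expect_equal(tr$cluster_counts[n], 1L)
})
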