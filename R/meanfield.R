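# Mean-field layer: the kinetic ("autoinducer") equation
#
#   d/dt rho(p,t) = 2 lam phibar_t ( delta(p - R(pbar_t)) - rho(p,t) )
#                 + (1 - 2 lam) ( phi(p) - phibar_t ) rho(p,t)
#
# integrated on an adaptive atom-measure representation. Delta peaks are
# injected at the moving location R(pbar_t); a fixed-grid scheme would
# smear the gap of the bimodal attractor by numerical diffusion, which is
# why the representation is purely atomic.

#' Right-hand side of the autoinducer equation on an atom measure
#'
#' For an atom measure with locations `l_k` and weights `w_k`, the
#' sense-and-response and replicator terms give the per-atom weight
#' derivatives
#' `dw_k/dt = (-2 lam phibar + (1 - 2 lam)(phi(l_k) - phibar)) w_k`
#' with `phi(p) - phibar = -s (p - pbar)`, plus mass injected at location
#' `R(pbar)` at rate `2 lam phibar`. The derivatives and the injection
#' rate sum to zero: the equation conserves normalization.
#'
#' @param measure A normalized [atom_measure()].
#' @param s Selection strength.
#' @param lam Response probability.
#' @param R A [response_fn()] object.
#' @return A list with `dweights` (per-atom weight derivatives),
#'   `injection_location` (`R(pbar)`), and `injection_rate`
#'   (`2 lam phibar`).
#' @export
autoinducer_rhs <- function(measure, s, lam, R) {
  if (!inherits(measure, "atom_measure"))
    stop("measure must be an atom_measure", call. = FALSE)
  if (abs(sum(measure$weights) - 1) > 1e-9)
    stop("measure must be normalized", call. = FALSE)
  if (lam < 0 || lam > 1)
    stop("lam must lie in [0, 1]", call. = FALSE)
  pbar <- measure_mean(measure)
  phibar <- 1 - s * pbar
  dphi <- -s * (measure$locations - pbar)     # phi(p) - phibar
  dw <- (-2 * lam * phibar + (1 - 2 * lam) * dphi) * measure$weights
  list(dweights = dw,
       injection_location = response_eval(R, pbar),
       injection_rate = 2 * lam * phibar)
}

# one splitting step of length dt, returning updated (locs, wts)
mf_step <- function(locs, wts, s, lam, R, dt, merge_tol, weight_floor) {
  # replicator half-step: exact exponential reweighting + normalization
  g <- (1 - 2 * lam) * s
  if (g != 0) {
    wts <- wts * exp(-g * locs * (dt / 2))
    wts <- wts / sum(wts)
  }
  # sense-and-response step with pbar, phibar frozen over dt: exact
  # relaxation towards the injected delta peak
  if (lam > 0) {
    pbar <- sum(locs * wts)
    phibar <- 1 - s * pbar
    a <- exp(-2 * lam * phibar * dt)
    r <- response_eval(R, pbar)
    wts <- wts * a
    inj <- 1 - a
    k <- findInterval(r, locs)
    tgt <- if (k >= 1L && r - locs[k] <= merge_tol) k
           else if (k < length(locs) && locs[k + 1L] - r <= merge_tol)
             k + 1L
           else 0L
    if (tgt > 0L) {
      # weight-weighted centroid merge, so a peak fed by injections can
      # drift with the moving injection location R(pbar)
      w_new <- wts[tgt] + inj
      locs[tgt] <- (locs[tgt] * wts[tgt] + r * inj) / w_new
      wts[tgt] <- w_new
      if (is.unsorted(locs)) {
        o <- order(locs)
        locs <- locs[o]
        wts <- wts[o]
      }
    } else {
      locs <- append(locs, r, after = k)
      wts <- append(wts, inj, after = k)
    }
  }
  # second replicator half-step
  if (g != 0) {
    wts <- wts * exp(-g * locs * (dt / 2))
  }
  # prune and renormalize
  keep <- wts > weight_floor
  if (!all(keep)) {
    locs <- locs[keep]
    wts <- wts[keep]
  }
  wts <- wts / sum(wts)
  list(locs = locs, wts = wts)
}

#' Integrate the autoinducer equation
#'
#' Advances an atom-measure representation of the production distribution
#' by operator splitting: a replicator sub-flow solved exactly by
#' exponential reweighting (`w_k <- w_k exp(-(1-2 lam) s l_k dt)`, then
#' normalization) and a sense-and-response sub-flow solved exactly for
#' frozen mean fitness (`rho <- a rho + (1-a) delta_{R(pbar)}` with
#' `a = exp(-2 lam phibar dt)`). Both sub-flows preserve positivity and
#' total mass, so the scheme conserves normalization to machine precision,
#' and it reproduces the closed-form solution exactly when `lam = 0`.
#' Injected mass is merged into an existing atom within `merge_tol`, else
#' deposited as a new atom; atoms below `weight_floor` are pruned.
#'
#' @param init A [init_dist()] (discretized to `n_atoms` equal-mass atoms)
#'   or an [atom_measure()] used directly.
#' @param s Selection strength.
#' @param lam Response probability.
#' @param R A [response_fn()] object.
#' @param t_max End time (> 0).
#' @param dt_max Maximum step size.
#' @param record_every Recording interval.
#' @param n_atoms Number of atoms when discretizing a continuous initial
#'   distribution.
#' @param merge_tol Atom merge tolerance.
#' @param weight_floor Pruning threshold for atom weights.
#' @return An object of class `mf_trajectory`: list with `times`,
#'   `measures` (list of [atom_measure()]s), `means`, `mean_fitness`,
#'   `variances`, and the final measure as `measure`.
#' @examples
#' R <- response_fn("sinusoidal", kappa = 0.2)
#' mf <- mf_integrate(init_dist("uniform"), s = 0.2, lam = 0.05, R,
#'                    t_max = 10, n_atoms = 100)
#' mf$means[length(mf$means)]
#' @export
mf_integrate <- function(init, s, lam, R, t_max, dt_max = 1e-2,
                         record_every = 1, n_atoms = 400L,
                         merge_tol = 1e-4, weight_floor = 1e-14) {
  if (t_max <= 0) stop("t_max must be positive", call. = FALSE)
  m0 <- if (inherits(init, "atom_measure")) init
        else discretize_init(init, n_atoms)
  locs <- m0$locations
  wts <- m0$weights
  times <- seq(0, t_max, by = record_every)
  if (times[length(times)] < t_max - 1e-12)
    times <- c(times, t_max)
  measures <- vector("list", length(times))
  means <- mean_fit <- vars <- numeric(length(times))
  rec <- function(k) {
    m <- atom_measure(locs, wts, merge_tol = merge_tol)
    measures[[k]] <<- m
    means[k] <<- measure_mean(m)
    mean_fit[k] <<- 1 - s * means[k]
    vars[k] <<- measure_var(m)
  }
  rec(1L)
  t <- 0
  for (k in seq_along(times)[-1L]) {
    target <- times[k]
    while (t < target - 1e-9 * max(1, target)) {
      dt <- min(dt_max, target - t)
      if (dt < 1e-10)
        stop("integration failure: step size collapsed below 1e-10 at t = ",
             t, call. = FALSE)
      st <- mf_step(locs, wts, s, lam, R, dt, merge_tol, weight_floor)
      locs <- st$locs
      wts <- st$wts
      t <- t + dt
    }
    rec(k)
  }
  structure(list(times = times, measures = measures, means = means,
                 mean_fitness = mean_fit, variances = vars,
                 measure = measures[[length(measures)]],
                 s = s, lam = lam),
            class = "mf_trajectory")
}

#' @export
print.mf_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf(
    "Mean-field trajectory: %d records to t = %.4g (s = %g, lambda = %g)\n",
    n, x$times[n], x$s, x$lam))
  cat(sprintf("  final: %d atoms, mean = %.6g, var = %.6g\n",
              length(x$measure$locations), x$means[n], x$variances[n]))
  invisible(x)
}

#' Integrate the autoinducer equation to stationarity
#'
#' Integrates in chunks of length `t_chunk` until the measure's transport
#' motion per unit time falls below `residual_tol`, or `t_max` is reached.
#'
#' @inheritParams mf_integrate
#' @param t_chunk Chunk length over which the residual motion is measured.
#' @param residual_tol Stationarity threshold on transport distance moved
#'   per unit time.
#' @param t_max Give up after this much model time.
#' @return A list with `measure` (final [atom_measure()]), `t` (time
#'   reached), `residual` (last transport motion per unit time) and
#'   `converged` (logical).
#' @export
mf_stationary_state <- function(init, s, lam, R, t_chunk = 10,
                                residual_tol = 1e-6, t_max = 2000,
                                dt_max = 1e-2, n_atoms = 400L,
                                merge_tol = 1e-4, weight_floor = 1e-14) {
  m <- if (inherits(init, "atom_measure")) init
       else discretize_init(init, n_atoms)
  t <- 0
  residual <- Inf
  while (t < t_max) {
    tr <- mf_integrate(m, s, lam, R, t_max = t_chunk, dt_max = dt_max,
                       record_every = t_chunk, merge_tol = merge_tol,
                       weight_floor = weight_floor)
    m_new <- tr$measure
    residual <- measure_distance(m, m_new) / t_chunk
    t <- t + t_chunk
    m <- m_new
    if (residual < residual_tol) break
  }
  list(measure = m, t = t, residual = residual,
       converged = residual < residual_tol)
}

#' Closed-form solution of the autoinducer equation without response
#'
#' For `lam = 0` the autoinducer equation is the replicator equation,
#' solved exactly by exponential reweighting of the initial distribution:
#' `rho(p, t) = rho0(p) exp(-s t p) / Z(t)`. Atomic initial conditions are
#' reweighted exactly; continuous ones are returned as a density
#' evaluator with moments computed by quadrature.
#'
#' @param init An [atom_measure()], an atomic [init_dist()], or a
#'   continuous [init_dist()].
#' @param s Selection strength.
#' @param t Time (>= 0).
#' @return For atomic input, an [atom_measure()]. For continuous input, a
#'   list of class `qs_density` with `density` (vectorized function of
#'   `p`), `mean` and `var`.
#' @examples
#' closed_form_lambda0(init_dist("uniform"), s = 0.2, t = 10)$mean
#' @export
closed_form_lambda0 <- function(init, s, t) {
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  if (inherits(init, "atom_measure")) {
    return(atom_measure(init$locations,
                        init$weights * exp(-s * t * init$locations),
                        merge_tol = init$merge_tol))
  }
  if (!inherits(init, "qs_init"))
    stop("init must be an atom_measure or qs_init", call. = FALSE)
  if (init$family == "atoms") {
    return(atom_measure(init$locations,
                        init$weights * exp(-s * t * init$locations)))
  }
  dens0 <- switch(init$family,
    uniform = {
      lo <- init$min; hi <- init$max
      function(p) ifelse(p >= lo & p <= hi, 1 / (hi - lo), 0)
    },
    truncgauss = {
      mu <- init$mean; sd <- init$sd
      Z0 <- stats::pnorm(1, mu, sd) - stats::pnorm(0, mu, sd)
      function(p) ifelse(p >= 0 & p <= 1, stats::dnorm(p, mu, sd) / Z0, 0)
    },
    table = {
      tb <- init$table
      f <- stats::approxfun(tb[, 1L], tb[, 2L], yleft = 0, yright = 0)
      Z0 <- stats::integrate(f, 0, 1, subdivisions = 500L)$value
      function(p) f(p) / Z0
    })
  w <- function(p) dens0(p) * exp(-s * t * p)
  Z <- stats::integrate(w, 0, 1, subdivisions = 1000L,
                        rel.tol = 1e-12)$value
  mu <- stats::integrate(function(p) p * w(p) / Z, 0, 1,
                         subdivisions = 1000L, rel.tol = 1e-12)$value
  m2 <- stats::integrate(function(p) p^2 * w(p) / Z, 0, 1,
                         subdivisions = 1000L, rel.tol = 1e-12)$value
  structure(list(density = function(p) w(p) / Z, mean = mu,
                 var = m2 - mu^2, t = t, s = s),
            class = "qs_density")
}

#' Closed-form solution for linear response at lambda = 1/2
#'
#' For the identity response function and `lam = 1/2` the replicator term
#' drops out of the autoinducer equation, the population mean stays at its
#' initial value `p0bar`, and the solution is the mixture
#' `rho(p, t) = y(t) rho0(p) + (1 - y(t)) delta(p - p0bar)` with
#' `y(t) = exp(-phibar0 t)` and `phibar0 = 1 - s p0bar`: the initial
#' distribution decays exponentially into a delta peak at the initial
#' mean.
#'
#' @param init An [init_dist()] or [atom_measure()].
#' @param s Selection strength.
#' @param t Time (>= 0).
#' @param R Optional [response_fn()]; supplying a non-linear one is a
#'   contract error, since the formula only holds for the identity.
#' @param lam Must be 1/2 (the default); any other value is a contract
#'   error.
#' @param n_atoms Discretization size for continuous initial
#'   distributions.
#' @return An [atom_measure()]: the discretized initial distribution with
#'   weight `y(t)` plus mass `1 - y(t)` at `p0bar`.
#' @export
closed_form_linear_half <- function(init, s, t, R = NULL, lam = 0.5,
                                    n_atoms = 400L) {
  if (!is.null(R) && R$family != "linear")
    stop("closed_form_linear_half is only valid for the linear ",
         "(identity) response function", call. = FALSE)
  if (lam != 0.5)
    stop("closed_form_linear_half is only valid for lam = 1/2",
         call. = FALSE)
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  m0 <- if (inherits(init, "atom_measure")) init
        else discretize_init(init, n_atoms)
  p0bar <- if (inherits(init, "qs_init")) init$p0bar else measure_mean(m0)
  phibar0 <- 1 - s * p0bar
  y <- exp(-phibar0 * t)
  atom_measure(c(m0$locations, p0bar), c(m0$weights * y, 1 - y),
               merge_tol = m0$merge_tol)
}

#' First-order transport (Wasserstein-1) distance between atom measures
#'
#' Computed exactly as the integral of the absolute difference of the two
#' cumulative distribution functions over \[0, 1\]. On this compact
#' domain the transport distance bounds the bounded-Lipschitz distance, so
#' it serves as the convergence diagnostic between the stochastic
#' empirical measure and the mean-field solution.
#'
#' @param a,b Normalized [atom_measure()]s.
#' @return A non-negative scalar; 0 iff the measures coincide, at most 1
#'   on \[0, 1\]. Symmetric, and satisfies the triangle inequality.
#' @examples
#' measure_distance(atom_measure(0, 1), atom_measure(1, 1))  # 1
#' @export
measure_distance <- function(a, b) {
  if (!inherits(a, "atom_measure") || !inherits(b, "atom_measure"))
    stop("both arguments must be atom_measure objects", call. = FALSE)
  x <- sort(unique(c(a$locations, b$locations)))
  Fa <- cumsum(a$weights)[pmax(1L, findInterval(x, a$locations))]
  Fa[findInterval(x, a$locations) == 0L] <- 0
  Fb <- cumsum(b$weights)[pmax(1L, findInterval(x, b$locations))]
  Fb[findInterval(x, b$locations) == 0L] <- 0
  if (length(x) == 1L) return(0)
  sum(abs(Fa[-length(x)] - Fb[-length(x)]) * diff(x))
}
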