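#' Noise settings for the stochastic quorum-sensing model
#'
#' Standard deviations of Gaussian perturbations applied at the three points
#' where the sense-and-response update can be noisy: inheritance of the
#' ancestor's production degree, perception of the population-average
#' production level, and the response output itself. All perturbed values are
#' clipped back to the production-degree interval \[0, 1\]. All-zero settings
#' reproduce the noise-free model exactly.
#'
#' @param sigma_inherit Std-dev of the perturbation added to a copied
#'   ancestor degree (production-degree units, >= 0).
#' @param sigma_perceive Std-dev of the perturbation added to the sensed
#'   average production level before the response function is applied (>= 0).
#' @param sigma_respond Std-dev of the perturbation added to the response
#'   function's output (>= 0).
#' @return An object of class `qs_noise`.
#' @export
noise_settings <- function(sigma_inherit = 0, sigma_perceive = 0,
                           sigma_respond = 0) {
  for (s in c(sigma_inherit, sigma_perceive, sigma_respond)) {
    if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0)
      stop("noise standard deviations must be single non-negative numbers",
           call. = FALSE)
  }
  structure(list(sigma_inherit = sigma_inherit,
                 sigma_perceive = sigma_perceive,
                 sigma_respond = sigma_respond),
            class = "qs_noise")
}

is_noiseless <- function(noise) {
  noise$sigma_inherit == 0 && noise$sigma_perceive == 0 &&
    noise$sigma_respond == 0
}

#' Parameters of the quorum-sensing birth-death model
#'
#' Bundles the population size, the selection strength of the fitness cost
#' of autoinducer production, the per-offspring response probability, the
#' noise settings and the random seed.
#'
#' @param N Population size (integer >= 2). The population is constant:
#'   every division is paired with a death (Moran scheme).
#' @param s Selection strength, `0 <= s < 1`. An individual with production
#'   degree `p` reproduces at rate `1 - s * p`, so non-producers reproduce
#'   fastest.
#' @param lam Response probability `lambda`, `0 <= lam <= 1`: the
#'   probability that an offspring adopts the response-function value
#'   evaluated at the sensed population average, rather than inheriting its
#'   ancestor's degree.
#' @param noise A [noise_settings()] object.
#' @param seed Integer random seed, or `NULL` to use the current RNG state.
#' @return An object of class `qs_params`.
#' @examples
#' model_params(N = 100, s = 0.2, lam = 0.05, seed = 1)
#' @export
model_params <- function(N, s, lam, noise = noise_settings(), seed = NULL) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 2 ||
      N != floor(N))
    stop("N must be an integer >= 2", call. = FALSE)
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0 || s >= 1)
    stop("selection strength s must satisfy 0 <= s < 1", call. = FALSE)
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) ||
      lam < 0 || lam > 1)
    stop("response probability lam must satisfy 0 <= lam <= 1",
         call. = FALSE)
  if (!inherits(noise, "qs_noise"))
    stop("noise must be created with noise_settings()", call. = FALSE)
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
        seed != floor(seed))
      stop("seed must be a single integer or NULL", call. = FALSE)
    seed <- as.integer(seed %% .Machine$integer.max)
  }
  structure(list(N = as.integer(N), s = s, lam = lam, noise = noise,
                 seed = seed),
            class = "qs_params")
}

#' @export
print.qs_params <- function(x, ...) {
  cat("Quorum-sensing model parameters\n")
  cat(sprintf("  N = %d, s = %g, lambda = %g\n", x$N, x$s, x$lam))
  if (!is_noiseless(x$noise))
    cat(sprintf("  noise: inherit %g, perceive %g, respond %g\n",
                x$noise$sigma_inherit, x$noise$sigma_perceive,
                x$noise$sigma_respond))
  if (!is.null(x$seed)) cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

#' Reproduction rate (fitness) of a production degree
#'
#' Fitness decreases affinely with the metabolic burden of autoinducer
#' production: `phi(p) = 1 - s * p`. A non-producer (`p = 0`) has fitness 1;
#' because `s < 1` the fitness is strictly positive for every degree.
#'
#' @param p Production degree(s) in \[0, 1\].
#' @param s Selection strength, `0 <= s < 1`.
#' @return Numeric vector of reproduction rates `1 - s * p`.
#' @examples
#' fitness(0, 0.2)    # 1
#' fitness(1, 0.2)    # 0.8
#' @export
fitness <- function(p, s) {
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0 || s >= 1)
    stop("selection strength s must satisfy 0 <= s < 1", call. = FALSE)
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    stop("production degrees must lie in [0, 1]", call. = FALSE)
  1 - s * p
}

# ---- response functions ----------------------------------------------------

#' Quorum-sensing response function
#'
#' The response function `R` maps the sensed average production level
#' `x` in \[0, 1\] to the production degree adopted by a responding
#' offspring. Built-in families:
#'
#' * `"sinusoidal"`: `R(x) = x + kappa * sin(pi * x)` with up-regulation
#'   magnitude `kappa` in \[0, 1/pi\] (larger values would leave \[0, 1\]).
#'   Monostable: unstable fixed point at 0, stable fixed point at 1.
#' * `"linear"`: the identity `R(x) = x` (no effective regulation).
#' * `"hill_bistable"`: a Hill sigmoid rescaled to `R(0) = 0`, `R(1) = 1`,
#'   `R(x) = x^n (1 + theta^n) / (x^n + theta^n)`; for Hill coefficient
#'   `n > 1` it has stable fixed points at 0 and 1 and an unstable
#'   threshold in between ("all-or-none" regulation).
#' * `"pitchfork"`: cubic-perturbed identity
#'   `R(x) = x + a (x - 1/2) - b (x - 1/2)^3`, a test family whose fixed
#'   points undergo a supercritical pitchfork bifurcation at `a = 0`
#'   (one fixed point at 1/2 for `a <= 0`, three for `a > 0`).
#' * `"table"`: piecewise-linear interpolation of user-supplied
#'   `(x, R(x))` pairs.
#'
#' @param family One of `"sinusoidal"`, `"linear"`, `"hill_bistable"`,
#'   `"pitchfork"`, `"table"`.
#' @param kappa Up-regulation magnitude for the sinusoidal family.
#' @param hill_n,hill_theta Hill coefficient and threshold for the bistable
#'   family.
#' @param a,b Linear and cubic coefficients for the pitchfork family.
#' @param table Two-column matrix or data.frame of `(x, R(x))` pairs for the
#'   table family; `x` must be sorted, span \[0, 1\] and all values must lie
#'   in \[0, 1\].
#' @return An object of class `qs_response`.
#' @examples
#' R <- response_fn("sinusoidal", kappa = 0.2)
#' response_eval(R, 0.5)          # 0.7
#' response_fixed_points(R)
#' @export
response_fn <- function(family = c("sinusoidal", "linear", "hill_bistable",
                                   "pitchfork", "table"),
                        kappa = 0.2, hill_n = 4, hill_theta = 0.5,
                        a = -0.1, b = 1, table = NULL) {
  family <- match.arg(family)
  obj <- list(family = family)
  if (family == "sinusoidal") {
    if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) ||
        kappa < 0 || kappa > 1 / pi)
      stop("kappa must lie in [0, 1/pi] for the sinusoidal family ",
           "(larger values map outside [0, 1])", call. = FALSE)
    obj$kappa <- kappa
  } else if (family == "hill_bistable") {
    if (!is.numeric(hill_n) || hill_n <= 0 ||
        !is.numeric(hill_theta) || hill_theta <= 0 || hill_theta >= 1)
      stop("hill_bistable requires hill_n > 0 and hill_theta in (0, 1)",
           call. = FALSE)
    obj$hill_n <- hill_n
    obj$hill_theta <- hill_theta
  } else if (family == "pitchfork") {
    if (!is.numeric(a) || !is.numeric(b) || b <= 0)
      stop("pitchfork requires numeric a and b > 0", call. = FALSE)
    obj$a <- a
    obj$b <- b
  } else if (family == "table") {
    if (is.null(table)) stop("table family requires a table", call. = FALSE)
    tb <- as.matrix(table)
    if (ncol(tb) != 2L || nrow(tb) < 2L)
      stop("table must have two columns (x, R(x)) and >= 2 rows",
           call. = FALSE)
    if (is.unsorted(tb[, 1L], strictly = TRUE))
      stop("table x values must be strictly increasing", call. = FALSE)
    if (tb[1L, 1L] != 0 || tb[nrow(tb), 1L] != 1)
      stop("table x values must span [0, 1]", call. = FALSE)
    if (any(tb[, 2L] < 0) || any(tb[, 2L] > 1))
      stop("table response values must lie in [0, 1]", call. = FALSE)
    obj$table <- tb
  }
  obj <- structure(obj, class = "qs_response")
  # range check on a fine grid for families whose range is not analytic
  if (family %in% c("pitchfork", "table")) {
    v <- response_eval(obj, seq(0, 1, length.out = 2001L))
    if (any(v < -1e-12) || any(v > 1 + 1e-12))
      stop("response function leaves [0, 1] on [0, 1]", call. = FALSE)
  }
  obj
}

#' @export
print.qs_response <- function(x, ...) {
  desc <- switch(x$family,
    sinusoidal = sprintf("R(x) = x + %g sin(pi x)", x$kappa),
    linear = "R(x) = x",
    hill_bistable = sprintf("rescaled Hill, n = %g, threshold = %g",
                            x$hill_n, x$hill_theta),
    pitchfork = sprintf("R(x) = x + %g (x - 1/2) - %g (x - 1/2)^3",
                        x$a, x$b),
    table = sprintf("piecewise-linear table with %d nodes", nrow(x$table)))
  cat("Response function:", desc, "\n")
  invisible(x)
}

#' Evaluate a response function
#'
#' @param R A [response_fn()] object.
#' @param x Sensed average production level(s) in \[0, 1\].
#' @return `R(x)`, guaranteed to lie in \[0, 1\].
#' @export
response_eval <- function(R, x) {
  if (!inherits(R, "qs_response"))
    stop("R must be a qs_response object", call. = FALSE)
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop("sensed level x must lie in [0, 1]", call. = FALSE)
  v <- switch(R$family,
    linear = x,
    sinusoidal = x + R$kappa * sin(pi * x),
    hill_bistable = {
      tn <- R$hill_theta^R$hill_n
      x^R$hill_n * (1 + tn) / (x^R$hill_n + tn)
    },
    pitchfork = {
      u <- x - 0.5
      x + R$a * u - R$b * u^3
    },
    table = stats::approx(R$table[, 1L], R$table[, 2L], xout = x,
                          rule = 2)$y)
  pmin(1, pmax(0, v))
}

#' Derivative of a response function
#'
#' Analytic for the built-in families; central finite difference
#' (`h = 1e-6`) for table-interpolated response functions.
#'
#' @inheritParams response_eval
#' @return `R'(x)`.
#' @export
response_deriv <- function(R, x) {
  if (!inherits(R, "qs_response"))
    stop("R must be a qs_response object", call. = FALSE)
  switch(R$family,
    linear = rep(1, length(x)),
    sinusoidal = 1 + R$kappa * pi * cos(pi * x),
    hill_bistable = {
      n <- R$hill_n; tn <- R$hill_theta^n
      (1 + tn) * n * x^(n - 1) * tn / (x^n + tn)^2
    },
    pitchfork = 1 + R$a - 3 * R$b * (x - 0.5)^2,
    table = {
      h <- 1e-6
      lo <- pmax(0, x - h)
      hi <- pmin(1, x + h)
      (response_eval(R, hi) - response_eval(R, lo)) / (hi - lo)
    })
}

#' Fixed points of a response function and their stability
#'
#' Finds all solutions of `R(x) = x` on \[0, 1\] by sign-change bracketing
#' on a fine grid followed by bisection polishing, and classifies each as
#' stable (`R'(x) < 1`), unstable (`R'(x) > 1`) or marginal
#' (`|R'(x) - 1|` below tolerance). Endpoints are classified by the same
#' one-sided derivative criterion. A response function that is the identity
#' on the whole grid is reported as the two endpoints, both flagged
#' marginal.
#'
#' @param R A [response_fn()] object.
#' @param grid_n Number of grid intervals used for bracketing
#'   (resolution `1/grid_n`).
#' @param root_tol Absolute tolerance of root polishing.
#' @param marginal_tol Threshold on `|R'(x) - 1|` below which a fixed point
#'   is flagged marginal rather than classified.
#' @return A data.frame with columns `location` and `stability`
#'   (`"stable"`, `"unstable"` or `"marginal"`).
#' @examples
#' response_fixed_points(response_fn("sinusoidal", kappa = 0.2))
#' @export
response_fixed_points <- function(R, grid_n = 1000L, root_tol = 1e-10,
                                  marginal_tol = 1e-6) {
  grid <- seq(0, 1, length.out = grid_n + 1L)
  f <- response_eval(R, grid) - grid
  if (all(abs(f) < 1e-12)) {
    return(data.frame(location = c(0, 1),
                      stability = c("marginal", "marginal"),
                      stringsAsFactors = FALSE))
  }
  roots <- numeric(0)
  # grid points that are (numerically) exact roots
  exact <- which(abs(f) < 1e-12)
  roots <- c(roots, grid[exact])
  # sign changes between consecutive non-root grid points
  for (k in seq_len(grid_n)) {
    if (abs(f[k]) < 1e-12 || abs(f[k + 1L]) < 1e-12) next
    if (sign(f[k]) != sign(f[k + 1L])) {
      r <- stats::uniroot(function(x) response_eval(R, x) - x,
                          lower = grid[k], upper = grid[k + 1L],
                          tol = root_tol)
      roots <- c(roots, r$root)
    }
  }
  roots <- sort(roots)
  # collapse near-duplicates
  if (length(roots) > 1L)
    roots <- roots[c(TRUE, diff(roots) > 10 * root_tol)]
  d <- response_deriv(R, roots)
  stability <- ifelse(abs(d - 1) < marginal_tol, "marginal",
                      ifelse(d < 1, "stable", "unstable"))
  data.frame(location = roots, stability = stability,
             stringsAsFactors = FALSE)
}

# ---- initial distributions -------------------------------------------------

#' Initial distribution of production degrees
#'
#' Declares the distribution from which initial production degrees are drawn
#' (stochastic layer) or discretized (mean-field layer). Families:
#'
#' * `"uniform"`: uniform on `[min, max]` within \[0, 1\].
#' * `"atoms"`: point masses at `locations` with `weights`.
#' * `"truncgauss"`: Gaussian with the given `mean` and `sd`, truncated to
#'   \[0, 1\].
#' * `"table"`: piecewise-linear density from `(x, density)` pairs,
#'   normalized internally.
#'
#' @param family Distribution family.
#' @param min,max Support of the uniform family.
#' @param locations,weights Atom locations in \[0, 1\] and positive weights
#'   (normalized internally) for the atoms family.
#' @param mean,sd Parameters of the (pre-truncation) Gaussian.
#' @param table Two-column `(x, density)` matrix for the table family;
#'   `x` sorted within \[0, 1\], densities >= 0.
#' @return An object of class `qs_init` with derived fields `p0bar` (the
#'   initial mean production degree).
#' @examples
#' init_dist("uniform")
#' init_dist("atoms", locations = c(0, 1), weights = c(0.5, 0.5))
#' @export
init_dist <- function(family = c("uniform", "atoms", "truncgauss", "table"),
                      min = 0, max = 1, locations = NULL, weights = NULL,
                      mean = 0.5, sd = 0.2, table = NULL) {
  family <- match.arg(family)
  obj <- list(family = family)
  if (family == "uniform") {
    if (min < 0 || max > 1 || min >= max)
      stop("uniform support must satisfy 0 <= min < max <= 1",
           call. = FALSE)
    obj$min <- min
    obj$max <- max
    obj$p0bar <- (min + max) / 2
  } else if (family == "atoms") {
    if (is.null(locations) || is.null(weights) ||
        length(locations) != length(weights))
      stop("atoms family requires matching locations and weights",
           call. = FALSE)
    if (any(locations < 0) || any(locations > 1))
      stop("atom locations must lie in [0, 1]", call. = FALSE)
    if (any(weights <= 0))
      stop("atom weights must be positive", call. = FALSE)
    o <- order(locations)
    locations <- locations[o]
    weights <- weights[o] / sum(weights)
    if (any(diff(locations) == 0))
      stop("atom locations must be distinct", call. = FALSE)
    obj$locations <- locations
    obj$weights <- weights
    obj$p0bar <- sum(locations * weights)
  } else if (family == "truncgauss") {
    if (sd <= 0) stop("sd must be positive", call. = FALSE)
    obj$mean <- mean
    obj$sd <- sd
    a <- (0 - mean) / sd
    b <- (1 - mean) / sd
    Z <- stats::pnorm(b) - stats::pnorm(a)
    obj$p0bar <- mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / Z
  } else {
    tb <- as.matrix(table)
    if (is.null(table) || ncol(tb) != 2L || nrow(tb) < 2L)
      stop("table family requires a two-column (x, density) table",
           call. = FALSE)
    if (is.unsorted(tb[, 1L], strictly = TRUE) ||
        tb[1L, 1L] < 0 || tb[nrow(tb), 1L] > 1)
      stop("table x values must be strictly increasing within [0, 1]",
           call. = FALSE)
    if (any(tb[, 2L] < 0) || all(tb[, 2L] == 0))
      stop("table densities must be >= 0 and not all zero", call. = FALSE)
    obj$table <- tb
    dens <- stats::approxfun(tb[, 1L], tb[, 2L], yleft = 0, yright = 0)
    Z <- stats::integrate(dens, tb[1L, 1L], tb[nrow(tb), 1L],
                          subdivisions = 500L)$value
    obj$p0bar <- stats::integrate(function(x) x * dens(x) / Z,
                                  tb[1L, 1L], tb[nrow(tb), 1L],
                                  subdivisions = 500L)$value
  }
  structure(obj, class = "qs_init")
}

#' @export
print.qs_init <- function(x, ...) {
  cat(sprintf("Initial distribution (%s), mean p0 = %.6g\n",
              x$family, x$p0bar))
  invisible(x)
}

#' Initial mean production degree and mean fitness
#'
#' @param init A [init_dist()] object.
#' @param s Selection strength (for `init_mean_fitness`).
#' @return `init_mean`: the mean production degree of the distribution;
#'   `init_mean_fitness`: `1 - s * init_mean(init)`.
#' @export
init_mean <- function(init) {
  if (!inherits(init, "qs_init"))
    stop("init must be a qs_init object", call. = FALSE)
  init$p0bar
}

#' @rdname init_mean
#' @export
init_mean_fitness <- function(init, s) {
  1 - s * init_mean(init)
}

#' Sample an initial population state
#'
#' Draws `N` i.i.d. production degrees from an initial distribution using
#' the current RNG state (or a supplied seed), giving a reproducible
#' [population_state()].
#'
#' @param init A [init_dist()] object.
#' @param N Population size (>= 2).
#' @param seed Optional integer seed; if supplied, `set.seed(seed)` is
#'   called first so two calls with the same seed are bit-identical.
#' @return A `population_state` of `N` degrees at time 0.
#' @export
sample_init <- function(init, N, seed = NULL) {
  if (!inherits(init, "qs_init"))
    stop("init must be a qs_init object", call. = FALSE)
  if (N < 2) stop("N must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  N <- as.integer(N)
  p <- switch(init$family,
    uniform = stats::runif(N, init$min, init$max),
    atoms = sample(init$locations, N, replace = TRUE,
                   prob = init$weights),
    truncgauss = {
      a <- stats::pnorm(0, init$mean, init$sd)
      b <- stats::pnorm(1, init$mean, init$sd)
      stats::qnorm(stats::runif(N, a, b), init$mean, init$sd)
    },
    table = {
      # numeric inverse CDF on a fine grid
      xs <- seq(init$table[1L, 1L], init$table[nrow(init$table), 1L],
                length.out = 2001L)
      dens <- stats::approx(init$table[, 1L], init$table[, 2L],
                            xout = xs)$y
      cdf <- cumsum((dens[-1L] + dens[-length(dens)]) / 2 * diff(xs))
      cdf <- c(0, cdf / cdf[length(cdf)])
      stats::approx(cdf, xs, xout = stats::runif(N), ties = "ordered")$y
    })
  population_state(pmin(1, pmax(0, p)), time = 0)
}

#' Quantile-midpoint discretization of an initial distribution
#'
#' Converts an initial distribution into an [atom_measure()] of `n`
#' equal-mass atoms placed at the quantile midpoints `(k - 1/2)/n`.
#' Equal-mass placement makes transport-distance convergence to the
#' continuous distribution uniform in `n`. Atomic distributions are
#' returned exactly.
#'
#' @param init A [init_dist()] object.
#' @param n Number of atoms for continuous families.
#' @return An [atom_measure()].
#' @export
discretize_init <- function(init, n = 400L) {
  if (!inherits(init, "qs_init"))
    stop("init must be a qs_init object", call. = FALSE)
  if (init$family == "atoms")
    return(atom_measure(init$locations, init$weights))
  q <- (seq_len(n) - 0.5) / n
  locs <- switch(init$family,
    uniform = init$min + q * (init$max - init$min),
    truncgauss = {
      a <- stats::pnorm(0, init$mean, init$sd)
      b <- stats::pnorm(1, init$mean, init$sd)
      stats::qnorm(a + q * (b - a), init$mean, init$sd)
    },
    table = {
      xs <- seq(init$table[1L, 1L], init$table[nrow(init$table), 1L],
                length.out = 2001L)
      dens <- stats::approx(init$table[, 1L], init$table[, 2L],
                            xout = xs)$y
      cdf <- cumsum((dens[-1L] + dens[-length(dens)]) / 2 * diff(xs))
      cdf <- c(0, cdf / cdf[length(cdf)])
      stats::approx(cdf, xs, xout = q, ties = "ordered")$y
    })
  atom_measure(pmin(1, pmax(0, locs)), rep(1 / n, n))
}

# ---- state containers ------------------------------------------------------

#' Microscopic population state
#'
#' The state of the stochastic process: a vector of `N` production degrees
#' together with the elapsed model time (units in which a population of
#' non-producers reproduces once per individual per unit time on average).
#'
#' @param degrees Numeric vector of production degrees in \[0, 1\],
#'   length >= 2.
#' @param time Elapsed model time (>= 0).
#' @return An object of class `population_state`.
#' @export
population_state <- function(degrees, time = 0) {
  if (!is.numeric(degrees) || length(degrees) < 2L || anyNA(degrees))
    stop("degrees must be a numeric vector of length >= 2", call. = FALSE)
  if (any(degrees < 0) || any(degrees > 1))
    stop("production degrees must lie in [0, 1]", call. = FALSE)
  structure(list(degrees = as.numeric(degrees), time = time),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Population state: N = %d, t = %.4g, <p> = %.4g, Var(p) = %.4g\n",
              length(x$degrees), x$time, mean(x$degrees),
              stats::var(x$degrees) * (length(x$degrees) - 1) /
                length(x$degrees)))
  invisible(x)
}

#' Finite atom measure on the production-degree interval
#'
#' A finite weighted set of point masses on \[0, 1\], the representation of
#' the production distribution used by the mean-field integrator. Atoms
#' closer than `merge_tol` are merged (weight-weighted centroid),
#' non-positive weights are dropped, and the weights are normalized to total
#' mass 1.
#'
#' @param locations Atom locations in \[0, 1\].
#' @param weights Matching positive masses.
#' @param merge_tol Merge tolerance: no two atoms of the result are closer
#'   than this.
#' @return An object of class `atom_measure` with strictly increasing
#'   `locations` and `weights` summing to 1.
#' @examples
#' m <- atom_measure(c(0, 0.7), c(2, 5))
#' measure_mean(m)   # 0.5
#' measure_var(m)    # 0.1
#' @export
atom_measure <- function(locations, weights, merge_tol = 1e-4) {
  if (length(locations) != length(weights) || length(locations) == 0L)
    stop("locations and weights must be non-empty and of equal length",
         call. = FALSE)
  if (anyNA(locations) || any(locations < 0) || any(locations > 1))
    stop("atom locations must lie in [0, 1]", call. = FALSE)
  keep <- weights > 0
  if (!any(keep)) stop("total mass must be positive", call. = FALSE)
  locations <- locations[keep]
  weights <- weights[keep]
  o <- order(locations)
  locations <- locations[o]
  weights <- weights[o]
  # merge runs of atoms closer than merge_tol into weighted centroids
  if (length(locations) > 1L) {
    grp <- cumsum(c(1L, as.integer(diff(locations) > merge_tol)))
    if (grp[length(grp)] < length(locations)) {
      w <- as.numeric(tapply(weights, grp, sum))
      l <- as.numeric(tapply(weights * locations, grp, sum)) / w
      locations <- l
      weights <- w
    }
  }
  weights <- weights / sum(weights)
  structure(list(locations = locations, weights = weights,
                 merge_tol = merge_tol),
            class = "atom_measure")
}

#' @export
print.atom_measure <- function(x, ...) {
  cat(sprintf("Atom measure: %d atoms, mean = %.6g, var = %.6g\n",
              length(x$locations), measure_mean(x), measure_var(x)))
  if (length(x$locations) <= 8L) {
    for (k in seq_along(x$locations))
      cat(sprintf("  %.6g : %.6g\n", x$locations[k], x$weights[k]))
  }
  invisible(x)
}

#' Moments of an atom measure
#'
#' @param m An [atom_measure()].
#' @return Mean or variance of the measure.
#' @export
measure_mean <- function(m) {
  if (!inherits(m, "atom_measure"))
    stop("m must be an atom_measure", call. = FALSE)
  sum(m$locations * m$weights)
}

#' @rdname measure_mean
#' @export
measure_var <- function(m) {
  mu <- measure_mean(m)
  sum((m$locations - mu)^2 * m$weights)
}

#' Convert a population state to its empirical atom measure
#'
#' @param state A [population_state()].
#' @param merge_tol Atom merge tolerance.
#' @return An [atom_measure()] with one atom per distinct degree.
#' @export
state_measure <- function(state, merge_tol = 1e-4) {
  if (!inherits(state, "population_state"))
    stop("state must be a population_state", call. = FALSE)
  r <- rle(sort(state$degrees))
  atom_measure(r$values, r$lengths, merge_tol = merge_tol)
}
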