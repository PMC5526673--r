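# Independent oracles used to compute expected values.

# logistic solution of the replicator ODE dx/dt = -s x (1 - x) for the
# producer fraction in a two-type population (producers at p = 1)
logistic_producer <- function(x0, s, t) {
  x0 * exp(-s * t) / (1 - x0 + x0 * exp(-s * t))
}

# mean of the exponentially reweighted uniform density on [0,1]:
# rho ~ e^(-s t p), by the closed-form antiderivative
uniform_reweighted_mean <- function(s, t) {
  if (s * t == 0) return(0.5)
  1 / (s * t) - 1 / (exp(s * t) - 1)
}

# brute-force fixed points of R on a fine grid (sign changes of R(x) - x)
grid_fixed_points <- function(R, res = 1e-4) {
  x <- seq(0, 1, by = res)
  f <- response_eval(R, x) - x
  roots <- x[abs(f) < 1e-12]
  sgn <- sign(f)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- sort(c(roots, (x[flips] + x[flips + 1]) / 2))
  roots[c(TRUE, diff(roots) > 2 * res)]
}

# random atom measure for property-style loops
random_measure <- function(n_atoms = 10) {
  atom_measure(runif(n_atoms), runif(n_atoms, 0.1, 1))
}

sinusoidal_R <- function(kappa = 0.2) response_fn("sinusoidal",
                                                  kappa = kappa)
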