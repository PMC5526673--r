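# Stationary states and phase structure of the autoinducer equation:
# the bimodal two-atom solution, its existence window 0 < lambda < s/2,
# the continuous transition at lambda_up and the discontinuous jump of the
# low-peak weight as lambda -> 0.

#' Balance parameter beta = 2 lambda / s
#'
#' Quantifies the balance between fitness differences (selection strength
#' `s`) and sense-and-response (response probability `lam`); it equals the
#' stationary mean production level of the heterogeneous state.
#'
#' @param s Selection strength (> 0; the balance is undefined at `s = 0`).
#' @param lam Response probability.
#' @return `2 * lam / s`.
#' @examples
#' beta_balance(0.2, 0.05)  # 0.5
#' @export
beta_balance <- function(s, lam) {
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s <= 0)
    stop("s must be positive: the balance parameter is undefined at s = 0",
         call. = FALSE)
  2 * lam / s
}

#' Upper threshold of the response probability
#'
#' Heterogeneous (bimodal) stationary distributions exist only for
#' response probabilities strictly below `lambda_up = s / 2`.
#'
#' @param s Selection strength (>= 0).
#' @return `s / 2`.
#' @export
lambda_up <- function(s) {
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0)
    stop("s must be >= 0", call. = FALSE)
  s / 2
}

#' Heterogeneous (bimodal) stationary solution
#'
#' The two-atom stationary distribution of the autoinducer equation:
#' probability mass `y` at the non-producing degree `p_low = 0` and mass
#' `1 - y` at the producing degree `p_high = R(beta)`, with
#' `beta = 2 lam / s`, `y = 1 - beta / R(beta)`, mean `beta` and variance
#' `beta (R(beta) - beta)`. The solution exists iff `0 < p_high <= 1` and
#' `0 < y < 1` (which requires a nonlinear, up-regulating response
#' function and `0 < lam < s/2`).
#'
#' @param R A [response_fn()] object.
#' @param s Selection strength (> 0).
#' @param lam Response probability.
#' @return An object of class `stationary_solution` with fields `beta`,
#'   `p_high`, `p_low` (0), `y`, `mean`, `variance`, `exists` and
#'   `violated_conditions` (character vector, empty when the solution
#'   exists).
#' @examples
#' heterogeneous_solution(response_fn("sinusoidal", kappa = 0.2),
#'                        s = 0.2, lam = 0.05)
#' @export
heterogeneous_solution <- function(R, s, lam) {
  beta <- beta_balance(s, lam)
  violated <- character(0)
  if (beta > 1) {
    # R is only defined on [0, 1]; beta > 1 means lam >= s/2 anyway
    p_high <- NA_real_
    y <- NA_real_
    violated <- c(violated, "beta <= 1")
  } else {
    p_high <- response_eval(R, beta)
    if (p_high <= 0) {
      y <- NA_real_
      violated <- c(violated, "p_high > 0")
    } else {
      y <- 1 - beta / p_high
      if (p_high > 1) violated <- c(violated, "p_high <= 1")
      if (y <= 0) violated <- c(violated, "y > 0")
      if (y >= 1) violated <- c(violated, "y < 1")
    }
  }
  exists <- length(violated) == 0L
  structure(list(beta = beta, p_high = p_high, p_low = 0, y = y,
                 mean = if (exists) beta else NA_real_,
                 variance = if (exists) beta * (p_high - beta)
                            else NA_real_,
                 exists = exists, violated_conditions = violated,
                 s = s, lam = lam),
            class = "stationary_solution")
}

#' @export
print.stationary_solution <- function(x, ...) {
  cat(sprintf("Bimodal stationary solution (s = %g, lambda = %g)\n",
              x$s, x$lam))
  cat(sprintf("  beta = %.6g\n", x$beta))
  if (x$exists) {
    cat(sprintf("  p_low = %g (weight y = %.6g)\n", x$p_low, x$y))
    cat(sprintf("  p_high = %.6g (weight %.6g)\n", x$p_high, 1 - x$y))
    cat(sprintf("  mean = %.6g, variance = %.6g\n", x$mean, x$variance))
  } else {
    cat("  does not exist; violated:",
        paste(x$violated_conditions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Two-atom measure of a stationary solution
#'
#' @param sol An existing [heterogeneous_solution()].
#' @return The [atom_measure()] `y delta(0) + (1 - y) delta(p_high)`.
#' @export
stationary_measure <- function(sol) {
  if (!inherits(sol, "stationary_solution"))
    stop("sol must be a stationary_solution", call. = FALSE)
  if (!sol$exists)
    stop("stationary solution does not exist for these parameters",
         call. = FALSE)
  atom_measure(c(sol$p_low, sol$p_high), c(sol$y, 1 - sol$y))
}

#' Phase of the long-time mean-field dynamics
#'
#' Classifies the parameter point as heterogeneous (the bimodal stationary
#' solution exists, which requires `0 < lam < lambda_up = s/2` and an
#' up-regulating nonlinear response) or homogeneous. Also reports the
#' threshold `lambda_up` and, when `R(0) = 0` with `1 < R'(0) < Inf`, the
#' discontinuous limit of the low-peak weight as `lam -> 0`:
#' `1 - 1/R'(0)`.
#'
#' @inheritParams heterogeneous_solution
#' @return An object of class `phase_diagnosis` with fields `phase`
#'   (`"heterogeneous"` or `"homogeneous"`), `lambda_up`, `jump_at_zero`
#'   (`NA` when undefined) and the underlying `solution`.
#' @export
phase_classify <- function(R, s, lam) {
  sol <- heterogeneous_solution(R, s, lam)
  d0 <- response_deriv(R, 0)
  jump <- if (abs(response_eval(R, 0)) <= 1e-12 && is.finite(d0) && d0 > 1)
    1 - 1 / d0 else NA_real_
  structure(list(phase = if (sol$exists) "heterogeneous" else "homogeneous",
                 lambda_up = lambda_up(s), jump_at_zero = jump,
                 solution = sol, s = s, lam = lam),
            class = "phase_diagnosis")
}

#' @export
print.phase_diagnosis <- function(x, ...) {
  cat(sprintf("Phase at (s = %g, lambda = %g): %s\n", x$s, x$lam, x$phase))
  cat(sprintf("  lambda_up = %g\n", x$lambda_up))
  if (!is.na(x$jump_at_zero))
    cat(sprintf("  low-peak weight jump as lambda -> 0: %.6g\n",
                x$jump_at_zero))
  invisible(x)
}

#' Stationary variance as a function of the response probability
#'
#' The order parameter of the heterogeneity-homogeneity transition: for
#' each `lam` in the grid, the stationary variance
#' `beta (R(beta) - beta)` when the bimodal solution exists, 0 otherwise.
#' The variance vanishes continuously as `lam` approaches `lambda_up`
#' from below; as `lam -> 0` the variance also vanishes but the low-peak
#' weight jumps discontinuously.
#'
#' @param R A [response_fn()] object.
#' @param s Selection strength (> 0).
#' @param lam_grid Vector of response probabilities in \[0, 1\].
#' @return A data.frame with columns `lambda`, `variance` and
#'   `heterogeneous`.
#' @export
order_parameter_curve <- function(R, s, lam_grid) {
  if (any(lam_grid < 0) || any(lam_grid > 1))
    stop("lam_grid must lie within [0, 1]", call. = FALSE)
  res <- lapply(lam_grid, function(l) {
    sol <- heterogeneous_solution(R, s, l)
    data.frame(lambda = l,
               variance = if (sol$exists) sol$variance else 0,
               heterogeneous = sol$exists)
  })
  do.call(rbind, res)
}

#' Numerical stability probe of a stationary solution
#'
#' Perturbs the two-atom stationary measure (a weight shift between the
#' two peaks and/or a small location shift of the high peak), integrates
#' the autoinducer equation, and reports whether the transport distance to
#' the unperturbed solution decays. In the existence region the bimodal
#' solution is linearly stable, so the distance is expected to decay after
#' a transient.
#'
#' @param sol An existing [heterogeneous_solution()].
#' @param R,s,lam Model ingredients (must match the solution).
#' @param weight_shift Signed mass moved from the low to the high peak.
#' @param loc_shift Signed shift applied to the high-peak location.
#' @param t_probe Integration horizon.
#' @param record_every Distance recording interval.
#' @param ... Passed to [mf_integrate()].
#' @return A list with `times`, `distances` (transport distance to the
#'   stationary measure at each record), `initial`, `final` and `decayed`
#'   (`final < initial`).
#' @export
stability_probe <- function(sol, R, s, lam, weight_shift = 0.02,
                            loc_shift = 0, t_probe = 50,
                            record_every = 5, ...) {
  if (!inherits(sol, "stationary_solution") || !sol$exists)
    stop("stability_probe requires an existing stationary solution",
         call. = FALSE)
  target <- stationary_measure(sol)
  pert_size <- abs(weight_shift) * sol$p_high + abs(loc_shift)
  if (pert_size > 0.05)
    stop("perturbation exceeds 0.05 in transport distance", call. = FALSE)
  y2 <- min(1 - 1e-12, max(1e-12, sol$y - weight_shift))
  hi <- min(1, max(0, sol$p_high + loc_shift))
  m0 <- atom_measure(c(sol$p_low, hi), c(y2, 1 - y2))
  tr <- mf_integrate(m0, s, lam, R, t_max = t_probe,
                     record_every = record_every, ...)
  d <- vapply(tr$measures, measure_distance, numeric(1), b = target)
  list(times = tr$times, distances = d, initial = d[1L],
       final = d[length(d)], decayed = d[length(d)] < d[1L])
}
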