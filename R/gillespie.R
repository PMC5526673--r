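# Stochastic layer: exact Gillespie simulation of the birth-death
# quorum-sensing process. The event loop is compiled (src/gillespie.cpp);
# gillespie_step() is a pure-R single-event reference used for small-N
# oracle tests and step-level diagnostics.

# encode a qs_response for the compiled loop
response_cpp_spec <- function(R) {
  switch(R$family,
    linear = list(family = 0L, p1 = 0, p2 = 0,
                  tx = numeric(0), ty = numeric(0)),
    sinusoidal = list(family = 1L, p1 = R$kappa, p2 = 0,
                      tx = numeric(0), ty = numeric(0)),
    hill_bistable = list(family = 2L, p1 = R$hill_n, p2 = R$hill_theta,
                         tx = numeric(0), ty = numeric(0)),
    table = list(family = 3L, p1 = 0, p2 = 0,
                 tx = R$table[, 1L], ty = R$table[, 2L]),
    pitchfork = {
      # dense tabulation; the compiled loop interpolates linearly
      xs <- seq(0, 1, length.out = 4001L)
      list(family = 3L, p1 = 0, p2 = 0, tx = xs,
           ty = response_eval(R, xs))
    })
}

#' Single update step of the stochastic quorum-sensing process
#'
#' Performs one birth-death event in pure R: draws an exponential waiting
#' time with total rate `sum(1 - s * p)`, selects the reproducing
#' individual `i` proportionally to fitness, selects a death slot `j`
#' uniformly among the other individuals, and lets the two offspring (in
#' slots `i` and `j`) independently either respond to the sensed
#' population average (probability `lam`, adopting `R(<p>)`) or inherit
#' the ancestor's degree. The sensed cue is the average of the
#' pre-division state. Uses the current RNG state.
#'
#' @param state A [population_state()].
#' @param params A [model_params()] object (its `N` must match the state).
#' @param R A [response_fn()] object.
#' @return A list with elements `state` (updated [population_state()], its
#'   `time` advanced by the waiting time), `wait` (the waiting time), and
#'   `info` (list with `i`, `j`, `sensed`, `responded` (logical of length
#'   2 for slots i and j) and `values` assigned to the two slots).
#' @export
gillespie_step <- function(state, params, R) {
  if (!inherits(state, "population_state"))
    stop("state must be a population_state", call. = FALSE)
  p <- state$degrees
  N <- length(p)
  if (N != params$N)
    stop("state length does not match params$N", call. = FALSE)
  s <- params$s
  lam <- params$lam
  ns <- params$noise
  phi <- 1 - s * p
  total <- sum(phi)
  wait <- stats::rexp(1, rate = total)
  i <- sample.int(N, 1L, prob = phi)
  j <- sample.int(N - 1L, 1L)
  if (j >= i) j <- j + 1L
  p_anc <- p[i]
  sensed_base <- mean(p)
  responded <- logical(2)
  values <- numeric(2)
  slots <- c(i, j)
  for (k in 1:2) {
    sensed <- sensed_base
    if (ns$sigma_perceive > 0)
      sensed <- min(1, max(0, sensed + stats::rnorm(1, 0, ns$sigma_perceive)))
    if (stats::runif(1) < lam) {
      v <- response_eval(R, sensed)
      if (ns$sigma_respond > 0)
        v <- min(1, max(0, v + stats::rnorm(1, 0, ns$sigma_respond)))
      responded[k] <- TRUE
    } else {
      v <- p_anc
      if (ns$sigma_inherit > 0)
        v <- min(1, max(0, v + stats::rnorm(1, 0, ns$sigma_inherit)))
    }
    values[k] <- v
    p[slots[k]] <- v
  }
  list(state = population_state(p, time = state$time + wait),
       wait = wait,
       info = list(i = i, j = j, sensed = sensed_base,
                   responded = responded, values = values))
}

#' Is a population state absorbing?
#'
#' A state is absorbing when all individuals share one production degree
#' `p*` and, if sense-and-response is active (`lam > 0`), that degree is a
#' fixed point of the response function (`R(p*) = p*` within absolute
#' tolerance 1e-12). Without sense-and-response (`lam = 0`) every uniform
#' state is absorbing, because offspring can only copy the common degree.
#' Exact equality of degrees is meaningful in the noise-free dynamics,
#' which only ever copy existing values or assign `R(<p>)`.
#'
#' @param state A [population_state()].
#' @param R A [response_fn()] object.
#' @param lam Response probability.
#' @return `TRUE` or `FALSE`.
#' @export
detect_absorbing <- function(state, R, lam) {
  p <- state$degrees
  if (any(p != p[1L])) return(FALSE)
  if (lam == 0) return(TRUE)
  abs(response_eval(R, p[1L]) - p[1L]) <= 1e-12
}

#' Run the stochastic quorum-sensing simulation
#'
#' Simulates the birth-death process exactly (Gillespie algorithm) until
#' `t_max`, recording population observables on a fixed schedule. Model
#' time is in units in which a population of non-producers experiences `N`
#' birth events per unit time on average. Deterministic given
#' `params$seed`.
#'
#' @param params A [model_params()] object. If `params$seed` is non-NULL,
#'   the RNG is seeded at entry (so sampling the initial state and the
#'   event sequence are both reproducible).
#' @param R A [response_fn()] object.
#' @param init A [init_dist()] (sampled to `params$N` degrees) or a
#'   [population_state()] used as-is.
#' @param t_max End time (> 0).
#' @param record_every Recording interval; observables are recorded at
#'   times `0, record_every, 2 record_every, ...` up to `t_max`.
#' @param stop_on_absorb Stop as soon as an absorbing state is reached.
#' @param keep_states Also store the full degree vector at each record
#'   time (memory: `N` doubles per record).
#' @param bins Histogram bin count over \[0, 1\].
#' @param gap Cluster gap threshold: sorted degrees are split into
#'   subpopulations wherever consecutive values differ by more than this.
#' @param min_frac Minimum fraction of the population for a group to count
#'   as a cluster.
#' @param death_among_all If `TRUE`, the death slot is drawn uniformly
#'   among all `N` individuals (including the reproducer) instead of the
#'   other `N - 1`; the two conventions differ at O(1/N).
#' @param sense_post If `TRUE`, offspring sense the population average
#'   after the ancestor's copy has replaced the death slot, instead of the
#'   pre-division average; again an O(1/N) convention choice.
#' @return An object of class `qs_trajectory`: list with `times`, `means`,
#'   `variances`, `cluster_counts`, `histograms` (records x bins counts
#'   summing to `N` per row), `states` (if requested), `final_state`,
#'   `absorbed`, `t_abs`, `final_degree`, `n_events`.
#' @examples
#' pars <- model_params(N = 200, s = 0.2, lam = 0.05, seed = 1)
#' R <- response_fn("sinusoidal", kappa = 0.2)
#' traj <- simulate_qs(pars, R, init_dist("uniform"), t_max = 5)
#' traj$means[length(traj$means)]
#' @export
simulate_qs <- function(params, R, init, t_max, record_every = 1,
                        stop_on_absorb = FALSE, keep_states = FALSE,
                        bins = 50L, gap = 0.05, min_frac = 0.01,
                        death_among_all = FALSE, sense_post = FALSE) {
  if (!inherits(params, "qs_params"))
    stop("params must be a qs_params object", call. = FALSE)
  if (!inherits(R, "qs_response"))
    stop("R must be a qs_response object", call. = FALSE)
  if (!is.numeric(t_max) || t_max <= 0)
    stop("t_max must be positive", call. = FALSE)
  if (record_every <= 0)
    stop("record_every must be positive", call. = FALSE)
  if (!is.null(params$seed)) set.seed(params$seed)
  if (inherits(init, "qs_init")) {
    state <- sample_init(init, params$N)
  } else if (inherits(init, "population_state")) {
    state <- init
    if (length(state$degrees) != params$N)
      stop("initial state length does not match params$N", call. = FALSE)
  } else {
    stop("init must be a qs_init or population_state", call. = FALSE)
  }
  spec <- response_cpp_spec(R)
  ns <- params$noise
  res <- .qs_gillespie_run(state$degrees, params$s, params$lam,
                           spec$family, spec$p1, spec$p2, spec$tx, spec$ty,
                           ns$sigma_inherit, ns$sigma_perceive,
                           ns$sigma_respond,
                           t_max, record_every,
                           as.integer(bins), gap, min_frac,
                           stop_on_absorb, keep_states,
                           death_among_all, sense_post)
  structure(list(times = res$times, means = res$means,
                 variances = res$variances,
                 cluster_counts = res$cluster_counts,
                 histograms = res$histograms, bins = as.integer(bins),
                 states = if (keep_states) res$states else NULL,
                 final_state = population_state(res$final_degrees,
                                                time = res$final_time),
                 absorbed = res$absorbed, t_abs = res$t_abs,
                 final_degree = res$final_degree,
                 n_events = res$n_events,
                 params = params, gap = gap, min_frac = min_frac),
            class = "qs_trajectory")
}

#' @export
print.qs_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Gillespie trajectory: N = %d, %d records to t = %.4g, %g events\n",
              x$params$N, n, x$final_state$time, x$n_events))
  if (n > 0)
    cat(sprintf("  final record: <p> = %.4g, Var(p) = %.4g, clusters = %d\n",
                x$means[n], x$variances[n], x$cluster_counts[n]))
  if (x$absorbed)
    cat(sprintf("  absorbed at t = %.6g (common degree %.6g)\n",
                x$t_abs, x$final_degree))
  invisible(x)
}

#' Time to reach a homogeneous absorbing state
#'
#' Runs the stochastic process until an absorbing state is reached
#' (all individuals at one common degree that is a fixed point of the
#' response function, or any common degree when `lam = 0`) or until the
#' cutoff time. Runs hitting the cutoff are reported censored
#' (`reached = FALSE`), never dropped.
#'
#' @inheritParams simulate_qs
#' @param t_cutoff Censoring time (> 0).
#' @return A list with `t_abs` (absorption time, `NA` if censored),
#'   `final_degree` (the common degree at absorption, `NA` if censored)
#'   and `reached` (logical).
#' @export
absorption_time <- function(params, R, init, t_cutoff = 1e4) {
  if (t_cutoff <= 0) stop("t_cutoff must be positive", call. = FALSE)
  traj <- simulate_qs(params, R, init, t_max = t_cutoff,
                      record_every = 2 * t_cutoff, stop_on_absorb = TRUE)
  list(t_abs = if (traj$absorbed) traj$t_abs else NA_real_,
       final_degree = if (traj$absorbed) traj$final_degree else NA_real_,
       reached = traj$absorbed)
}

#' Population observables of a state
#'
#' Mean, population variance, histogram and gap-separated cluster
#' structure of a set of production degrees. Clusters are found by sorting
#' the degrees and splitting wherever consecutive values differ by more
#' than `gap`; only groups holding at least `min_frac` of the population
#' are counted.
#'
#' @param state A [population_state()] or a numeric vector of degrees.
#' @param bins Histogram bin count over \[0, 1\].
#' @param gap Cluster gap threshold in (0, 1).
#' @param min_frac Minimum cluster mass as a fraction of the population.
#' @return A list with `mean`, `variance`, `histogram` (counts per bin,
#'   summing to `N`), `breaks`, `cluster_count` and `clusters` (data.frame
#'   of `center` and `mass` for the counted clusters).
#' @examples
#' observables(c(rep(0, 50), rep(0.7, 50)))
#' @export
observables <- function(state, bins = 50L, gap = 0.05, min_frac = 0.01) {
  p <- if (inherits(state, "population_state")) state$degrees
       else as.numeric(state)
  if (bins < 2L) stop("bins must be >= 2", call. = FALSE)
  if (gap <= 0 || gap >= 1) stop("gap must lie in (0, 1)", call. = FALSE)
  N <- length(p)
  mu <- mean(p)
  v <- mean((p - mu)^2)
  breaks <- seq(0, 1, length.out = bins + 1L)
  idx <- pmin(bins, floor(p * bins) + 1L)
  hist <- tabulate(idx, nbins = bins)
  sp <- sort(p)
  grp <- cumsum(c(1L, as.integer(diff(sp) > gap)))
  mass <- tabulate(grp)
  centers <- as.numeric(tapply(sp, grp, mean))
  keep <- mass >= max(1, ceiling(min_frac * N))
  list(mean = mu, variance = v, histogram = hist, breaks = breaks,
       cluster_count = sum(keep),
       clusters = data.frame(center = centers[keep], mass = mass[keep]))
}

#' Subpopulation modes of the production-degree histogram
#'
#' Segments the binned histogram of production degrees into contiguous
#' high-density regions separated by low-density runs at least `gap`
#' wide, and reports the regions holding at least `min_frac` of the
#' population. This is the observable to use for "how many
#' subpopulations": unlike the sorted-point-gap rule of [observables()]
#' (which is exact for noise-free atomic states), it does not fragment a
#' subpopulation whose internal lineage structure has point gaps --
#' under demographic drift or inheritance noise a mode is a contiguous
#' band of the histogram, not a single shared value.
#'
#' @param state A [population_state()] or numeric vector of degrees;
#'   ignored when `counts` is supplied.
#' @param bins Histogram bin count over \[0, 1\].
#' @param gap Minimum width of a low-density run that separates modes.
#' @param min_frac Minimum population fraction for a mode, also used to
#'   set the low-density bin threshold (`min_frac * N / 2` per bin).
#' @param counts Optional pre-binned (possibly replicate-pooled)
#'   histogram counts over `bins` equal bins of \[0, 1\], e.g. a row of
#'   an ensemble's pooled histograms.
#' @return A list with `count` and `modes` (data.frame of mass-weighted
#'   `center` and `mass` per mode).
#' @examples
#' production_modes(c(runif(300, 0, 0.1), runif(700, 0.65, 0.75)))
#' @export
production_modes <- function(state, bins = 50L, gap = 0.05,
                             min_frac = 0.01, counts = NULL) {
  if (is.null(counts)) {
    p <- if (inherits(state, "population_state")) state$degrees
         else as.numeric(state)
    idx <- pmin(as.integer(bins), floor(p * bins) + 1L)
    counts <- tabulate(idx, nbins = bins)
  } else {
    bins <- length(counts)
  }
  N <- sum(counts)
  dense <- counts >= max(1, min_frac * N / 2)
  # merge dense runs separated by low-density runs narrower than gap
  gap_bins <- ceiling(gap * bins)
  r <- rle(dense)
  short_gap <- !r$values & r$lengths < gap_bins
  inner <- seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
  r$values[short_gap & inner] <- TRUE
  dense <- inverse.rle(r)
  seg <- cumsum(c(dense[1L], pmax(0, diff(dense)))) * dense
  mids <- (seq_len(bins) - 0.5) / bins
  rows <- lapply(setdiff(unique(seg), 0L), function(g) {
    b <- seg == g
    data.frame(center = sum(counts[b] * mids[b]) / sum(counts[b]),
               mass = sum(counts[b]))
  })
  modes <- do.call(rbind, rows)
  if (is.null(modes))
    return(list(count = 0L,
                modes = data.frame(center = numeric(0),
                                   mass = numeric(0))))
  modes <- modes[modes$mass >= max(1, ceiling(min_frac * N)), ,
                 drop = FALSE]
  modes <- modes[order(modes$center), , drop = FALSE]
  rownames(modes) <- NULL
  list(count = nrow(modes), modes = modes)
}

#' Ensemble of independent simulation replicates
#'
#' Runs `M` independent simulations with replicate seeds derived
#' deterministically from the master seed (see [derive_seed()]) and pools
#' the recorded observables: per-record ensemble means of `<p>` and
#' `Var(p)` and the replicate-averaged histogram.
#'
#' @inheritParams simulate_qs
#' @param M Number of replicates (>= 1).
#' @return An object of class `qs_ensemble`: list with `M`, `seeds`,
#'   `times`, `mean_means`, `mean_variances`, `mean_clusters`,
#'   `pooled_histograms` (records x bins, averaged over replicates) and
#'   `trajectories` (list of the `M` [simulate_qs()] results).
#' @export
ensemble_qs <- function(params, R, init, t_max, M, record_every = 1, ...) {
  if (M < 1) stop("M must be >= 1", call. = FALSE)
  master <- if (is.null(params$seed)) {
    sample.int(.Machine$integer.max, 1L)
  } else params$seed
  seeds <- vapply(seq_len(M), function(k) derive_seed(master, k),
                  integer(1))
  trajs <- vector("list", M)
  for (k in seq_len(M)) {
    pk <- params
    pk$seed <- seeds[k]
    trajs[[k]] <- simulate_qs(pk, R, init, t_max,
                              record_every = record_every, ...)
  }
  nt <- min(vapply(trajs, function(tr) length(tr$times), integer(1)))
  times <- trajs[[1L]]$times[seq_len(nt)]
  mm <- rowMeans(vapply(trajs, function(tr) tr$means[seq_len(nt)],
                        numeric(nt)))
  mv <- rowMeans(vapply(trajs, function(tr) tr$variances[seq_len(nt)],
                        numeric(nt)))
  mc <- rowMeans(vapply(trajs,
                        function(tr) as.numeric(tr$cluster_counts[seq_len(nt)]),
                        numeric(nt)))
  ph <- Reduce(`+`, lapply(trajs, function(tr)
    tr$histograms[seq_len(nt), , drop = FALSE])) / M
  structure(list(M = M, seeds = seeds, times = times, mean_means = mm,
                 mean_variances = mv, mean_clusters = mc,
                 pooled_histograms = ph, trajectories = trajs),
            class = "qs_ensemble")
}

#' @export
print.qs_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d replicates, %d records to t = %.4g\n",
              x$M, length(x$times), max(x$times)))
  invisible(x)
}
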