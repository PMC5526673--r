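# Scripted, seeded experiment drivers comparing the stochastic and
# mean-field layers: histogram evolution, algebraic decay without
# response, absorption-time scaling with N, the phase diagram in
# (lambda, kappa), the variance order parameter, robustness to initial
# distributions and to noise, and relaxation slow-down near a response
# bifurcation. Defaults are desk-scale; all drivers are bit-reproducible
# from their seed.

default_response <- function(kappa = 0.2) response_fn("sinusoidal",
                                                      kappa = kappa)

window_stats <- function(traj, t_from) {
  idx <- traj$times >= t_from
  list(var = mean(traj$variances[idx]),
       clusters = mean(traj$cluster_counts[idx]),
       mean = mean(traj$means[idx]))
}

#' Ensemble histogram evolution
#'
#' Runs an ensemble at the given parameters and returns the pooled
#' (replicate-averaged) histograms over time, the late-time window
#' statistics and the cluster structure of the final records; the
#' stochastic counterpart of the bimodal mean-field attractor when
#' `lam < s/2`.
#'
#' @param s,lam Selection strength and response probability.
#' @param R A [response_fn()].
#' @param N Population size.
#' @param M Ensemble size.
#' @param t_max End time; quasi-stationary statistics are averaged over
#'   the window `[t_max/2, t_max]`.
#' @param record_every Recording interval.
#' @param init Initial distribution.
#' @param seed Master seed.
#' @return A list with the [ensemble_qs()] result, the window-averaged
#'   variance and cluster count, and the final-state cluster table of the
#'   first replicate.
#' @export
histogram_evolution <- function(s = 0.2, lam = 0.05,
                                R = default_response(), N = 2000,
                                M = 10, t_max = 100, record_every = 5,
                                init = init_dist("uniform"), seed = 1) {
  params <- model_params(N = N, s = s, lam = lam, seed = seed)
  ens <- ensemble_qs(params, R, init, t_max = t_max, M = M,
                     record_every = record_every)
  idx <- ens$times >= t_max / 2
  final_obs <- observables(ens$trajectories[[1L]]$final_state)
  list(ensemble = ens,
       window_variance = mean(ens$mean_variances[idx]),
       window_clusters = mean(ens$mean_clusters[idx]),
       final_clusters = final_obs$clusters,
       table = data.frame(time = ens$times, mean = ens$mean_means,
                          variance = ens$mean_variances,
                          clusters = ens$mean_clusters))
}

#' Algebraic decay of the mean production level without response
#'
#' Without sense-and-response (`lam = 0`) and for a (quasi-)continuous
#' initial distribution, the mean production level decays algebraically,
#' `<p> ~ 1/(s t)` at late times. The driver computes the exact mean from
#' the closed-form solution on a logarithmic time grid, fits the log-log
#' slope over the late-time window, and optionally cross-checks with a
#' single stochastic run.
#'
#' @param s Selection strength.
#' @param t_window Late-time fit window.
#' @param n_t Number of (log-spaced) analytic evaluation times.
#' @param N Optional population size for a stochastic cross-check
#'   (`NULL` to skip).
#' @param M Replicates pooled for the stochastic cross-check; the
#'   ensemble mean tames the demographic-drift bias of a single run.
#' @param init Initial distribution (continuous).
#' @param seed Seed for the optional stochastic runs.
#' @return A list with `slope_analytic`, the analytic `table`
#'   (t, mean), and when simulated also `slope_sim` and `table_sim`.
#' @export
decay_lambda0 <- function(s = 0.2, t_window = c(50, 500), n_t = 25L,
                          N = NULL, M = 8L,
                          init = init_dist("uniform"), seed = 1) {
  ts <- exp(seq(log(t_window[1L]), log(t_window[2L]),
                length.out = n_t))
  means <- vapply(ts, function(t) closed_form_lambda0(init, s, t)$mean,
                  numeric(1))
  fit <- stats::lm(log(means) ~ log(ts))
  out <- list(slope_analytic = unname(stats::coef(fit)[2L]),
              table = data.frame(t = ts, mean = means))
  if (!is.null(N)) {
    params <- model_params(N = N, s = s, lam = 0, seed = seed)
    rec <- t_window[1L] / 2
    ens <- ensemble_qs(params, response_fn("linear"), init,
                       t_max = t_window[2L], M = M,
                       record_every = rec)
    idx <- ens$times >= t_window[1L] & ens$mean_means > 0
    sfit <- stats::lm(log(ens$mean_means[idx]) ~ log(ens$times[idx]))
    out$slope_sim <- unname(stats::coef(sfit)[2L])
    out$table_sim <- data.frame(t = ens$times[idx],
                                mean = ens$mean_means[idx])
  }
  out
}

#' Absorption-time scaling with population size
#'
#' Measures the time to reach a homogeneous absorbing state over `M`
#' replicates at each population size in `N_list` and fits
#' `log(T_abs) ~ N`: in the heterogeneous phase the escape from the
#' quasi-stationary bimodal state is driven by demographic fluctuations
#' and `T_abs` grows exponentially with `N`. Censored runs (cutoff
#' reached) are reported per level and excluded from the fit; levels with
#' no completed run are dropped with a warning. At least three usable
#' levels are required.
#'
#' @param N_list Ascending population sizes (>= 3 values).
#' @param s,lam Selection strength and response probability.
#' @param R A [response_fn()].
#' @param M Replicates per level (>= 10).
#' @param t_cutoff Censoring time.
#' @param init Initial distribution; by default the bimodal stationary
#'   solution itself (so the run starts inside the quasi-stationary
#'   state), falling back to uniform when it does not exist.
#' @param seed Master seed.
#' @return An object of class `scaling_fit`: list with the per-level
#'   table (`N`, geometric mean, 95% spread, censored fraction), the
#'   fitted `gamma`, its standard error `gamma_se`, and the raw times.
#' @export
absorption_scaling <- function(N_list = c(50, 100, 200, 400), s = 0.2,
                               lam = 0.05, R = default_response(),
                               M = 50, t_cutoff = 1e4, init = NULL,
                               seed = 1) {
  if (length(N_list) < 3L)
    stop("need at least 3 population-size levels to fit a slope",
         call. = FALSE)
  if (is.unsorted(N_list, strictly = TRUE))
    stop("N_list must be strictly ascending", call. = FALSE)
  if (M < 10) stop("M must be >= 10", call. = FALSE)
  if (is.null(init)) {
    sol <- heterogeneous_solution(R, s, lam)
    init <- if (sol$exists)
      init_dist("atoms", locations = c(sol$p_low, sol$p_high),
                weights = c(sol$y, 1 - sol$y))
    else init_dist("uniform")
  }
  raw <- list()
  rows <- list()
  for (li in seq_along(N_list)) {
    N <- N_list[li]
    tabs <- numeric(M)
    for (k in seq_len(M)) {
      params <- model_params(N = N, s = s, lam = lam,
                             seed = derive_seed(seed, li * 1000L + k))
      res <- absorption_time(params, R, init, t_cutoff = t_cutoff)
      tabs[k] <- if (res$reached) res$t_abs else NA_real_
    }
    raw[[li]] <- tabs
    ok <- tabs[!is.na(tabs)]
    rows[[li]] <- data.frame(
      N = N, n_completed = length(ok), censored_frac = mean(is.na(tabs)),
      geo_mean = if (length(ok) > 0L) exp(mean(log(ok))) else NA_real_,
      q025 = if (length(ok) > 1L) stats::quantile(ok, 0.025,
                                                  names = FALSE)
             else NA_real_,
      q975 = if (length(ok) > 1L) stats::quantile(ok, 0.975,
                                                  names = FALSE)
             else NA_real_)
  }
  tab <- do.call(rbind, rows)
  usable <- tab$n_completed > 0L
  if (any(!usable))
    warning("dropping all-censored levels: N = ",
            paste(tab$N[!usable], collapse = ", "))
  if (sum(usable) < 3L)
    stop("fewer than 3 population-size levels with completed ",
         "absorption times; cannot fit gamma", call. = FALSE)
  fit <- stats::lm(log(geo_mean) ~ N, data = tab[usable, ])
  co <- summary(fit)$coefficients
  structure(list(table = tab, gamma = co[2L, 1L], gamma_se = co[2L, 2L],
                 times = raw, N_list = N_list, seed = seed),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Absorption-time scaling: gamma = %.4g +/- %.2g per individual\n",
              x$gamma, x$gamma_se))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Phase diagram in the (lambda, kappa) plane
#'
#' Simulates the stochastic process on a grid of response probabilities
#' and up-regulation magnitudes (sinusoidal response family), records the
#' time-averaged quasi-stationary variance and cluster count over the
#' window `[t_max/2, t_max]`, and overlays the mean-field boundary
#' `lambda = s/2`: heterogeneity (two gap-separated clusters, positive
#' variance) is expected strictly below the boundary for `kappa > 0` and
#' nowhere else.
#'
#' @param lam_grid,kappa_grid Grid values (`kappa` within \[0, 1/pi\]).
#' @param s Selection strength.
#' @param N Population size.
#' @param M Replicates per cell.
#' @param t_max End time per run.
#' @param init Initial distribution.
#' @param seed Master seed.
#' @return A list with the cell `table` (lambda, kappa, variance,
#'   clusters, heterogeneous_sim, heterogeneous_theory) and `lambda_up`.
#' @export
phase_diagram <- function(lam_grid = c(0.02, 0.05, 0.08, 0.12, 0.15),
                          kappa_grid = c(0, 0.1, 0.2, 0.3), s = 0.2,
                          N = 1000, M = 3, t_max = 300,
                          init = init_dist("uniform"), seed = 1) {
  if (any(kappa_grid < 0) || any(kappa_grid > 1 / pi))
    stop("kappa_grid must lie within [0, 1/pi]", call. = FALSE)
  if (any(lam_grid < 0) || any(lam_grid > 1))
    stop("lam_grid must lie within [0, 1]", call. = FALSE)
  cell <- 0L
  rows <- list()
  for (kap in kappa_grid) {
    R <- response_fn("sinusoidal", kappa = kap)
    for (lam in lam_grid) {
      cell <- cell + 1L
      vs <- cs <- numeric(M)
      for (r in seq_len(M)) {
        params <- model_params(N = N, s = s, lam = lam,
                               seed = derive_seed(seed,
                                                  cell * 100L + r))
        traj <- simulate_qs(params, R, init, t_max = t_max,
                            record_every = t_max / 20)
        w <- window_stats(traj, t_max / 2)
        vs[r] <- w$var
        cs[r] <- w$clusters
      }
      sol <- heterogeneous_solution(R, s, lam)
      rows[[cell]] <- data.frame(
        lambda = lam, kappa = kap, variance = mean(vs),
        clusters = mean(cs),
        heterogeneous_sim = mean(cs) >= 1.5 && mean(vs) > 1e-3,
        heterogeneous_theory = sol$exists,
        variance_theory = if (sol$exists) sol$variance else 0)
    }
  }
  list(table = do.call(rbind, rows), lambda_up = lambda_up(s), s = s,
       N = N, M = M)
}

#' Stationary variance versus response probability
#'
#' The simulated order-parameter curve: time-averaged quasi-stationary
#' variance at each `lambda`, compared with the mean-field prediction
#' `beta (R(beta) - beta)` below `lambda_up` and 0 above.
#'
#' @inheritParams phase_diagram
#' @param kappa Up-regulation magnitude of the sinusoidal response.
#' @return A list with the `table` (lambda, variance_sim, variance_theory)
#'   and the analytic [order_parameter_curve()].
#' @export
variance_vs_lambda <- function(lam_grid = c(0.01, 0.03, 0.05, 0.07,
                                            0.09, 0.12), s = 0.2,
                               kappa = 0.2, N = 2000, M = 5,
                               t_max = 100,
                               init = init_dist("uniform"), seed = 1) {
  R <- response_fn("sinusoidal", kappa = kappa)
  rows <- lapply(seq_along(lam_grid), function(i) {
    lam <- lam_grid[i]
    vs <- vapply(seq_len(M), function(r) {
      params <- model_params(N = N, s = s, lam = lam,
                             seed = derive_seed(seed, i * 100L + r))
      traj <- simulate_qs(params, R, init, t_max = t_max,
                          record_every = t_max / 20)
      window_stats(traj, t_max / 2)$var
    }, numeric(1))
    sol <- heterogeneous_solution(R, s, lam)
    data.frame(lambda = lam, variance_sim = mean(vs),
               variance_sd = stats::sd(vs),
               variance_theory = if (sol$exists) sol$variance else 0)
  })
  list(table = do.call(rbind, rows),
       analytic = order_parameter_curve(R, s,
                                        seq(0, max(lam_grid),
                                            length.out = 101L)))
}

#' Robustness of the bimodal mean-field attractor to the initial
#' distribution
#'
#' Integrates the autoinducer equation from each initial distribution in
#' the list and reports the final measures, their pairwise transport
#' distances and their distances to the bimodal stationary solution. For
#' the low peak to form at production degree 0, the initial distributions
#' must place mass at (or arbitrarily close to) 0.
#'
#' @param init_list Named list of >= 2 [init_dist()] objects.
#' @param s,lam Selection strength and response probability.
#' @param R A [response_fn()].
#' @param t_final Integration horizon.
#' @param n_atoms Discretization size.
#' @return A list with `measures`, `pairwise` (distance matrix),
#'   `to_stationary` (named distances to the bimodal solution, `NA`
#'   when it does not exist) and the `solution`.
#' @export
initial_robustness <- function(init_list = list(
                                 uniform = init_dist("uniform"),
                                 two_atom = init_dist("atoms",
                                   locations = c(0, 1),
                                   weights = c(0.5, 0.5)),
                                 truncgauss = init_dist("truncgauss",
                                   mean = 0.3, sd = 0.15)),
                               s = 0.2, lam = 0.05,
                               R = default_response(), t_final = 1500,
                               n_atoms = 400L) {
  if (length(init_list) < 2L)
    stop("need at least 2 initial distributions", call. = FALSE)
  if (is.null(names(init_list)))
    names(init_list) <- paste0("init", seq_along(init_list))
  finals <- lapply(init_list, function(ini)
    mf_integrate(ini, s, lam, R, t_max = t_final,
                 record_every = t_final, n_atoms = n_atoms)$measure)
  n <- length(finals)
  pw <- matrix(0, n, n, dimnames = list(names(finals), names(finals)))
  for (i in seq_len(n)) for (j in seq_len(n))
    pw[i, j] <- measure_distance(finals[[i]], finals[[j]])
  sol <- heterogeneous_solution(R, s, lam)
  to_st <- if (sol$exists) {
    target <- stationary_measure(sol)
    vapply(finals, measure_distance, numeric(1), b = target)
  } else rep(NA_real_, n)
  list(measures = finals, pairwise = pw, to_stationary = to_st,
       solution = sol)
}

#' Robustness of bimodality to noisy inheritance, perception and response
#'
#' Simulates the stochastic process with Gaussian noise (clipped to
#' \[0, 1\]) on one channel at a time and reports the quasi-stationary
#' cluster structure: bimodality is expected to persist, with the two
#' cluster centers broadened around the noise-free peaks.
#'
#' @param sigma_grid Noise standard deviations (>= 0); 0 gives the
#'   noise-free baseline.
#' @param channels Subset of `"inherit"`, `"perceive"`, `"respond"`.
#' @param s,lam Selection strength and response probability.
#' @param R A [response_fn()].
#' @param N Population size.
#' @param t_max End time; snapshots in `[t_max/2, t_max]` are analyzed.
#' @param record_every Snapshot interval.
#' @param init Initial distribution.
#' @param gap,min_frac Cluster detection settings (see [observables()]).
#' @param seed Master seed.
#' @return A data.frame with one row per (channel, sigma): the modal
#'   cluster count over the window and the average low/high cluster
#'   centers among two-cluster snapshots.
#' @export
noise_robustness <- function(sigma_grid = c(0, 0.01, 0.03),
                             channels = c("inherit", "perceive",
                                          "respond"),
                             s = 0.2, lam = 0.05,
                             R = default_response(), N = 10000,
                             t_max = 100, record_every = 10,
                             init = init_dist("uniform"), gap = 0.05,
                             min_frac = 0.01, seed = 1) {
  rows <- list()
  run_id <- 0L
  first_channel <- TRUE
  for (ch in channels) {
    for (sg in sigma_grid) {
      # the sigma = 0 baseline is channel-independent: run it once
      if (sg == 0 && !first_channel) next
      run_id <- run_id + 1L
      ns <- switch(ch,
        inherit = noise_settings(sigma_inherit = sg),
        perceive = noise_settings(sigma_perceive = sg),
        respond = noise_settings(sigma_respond = sg))
      params <- model_params(N = N, s = s, lam = lam, noise = ns,
                             seed = derive_seed(seed, run_id))
      traj <- simulate_qs(params, R, init, t_max = t_max,
                          record_every = record_every,
                          keep_states = TRUE, gap = gap,
                          min_frac = min_frac)
      idx <- which(traj$times >= t_max / 2)
      obs <- lapply(traj$states[idx], production_modes, gap = gap,
                    min_frac = min_frac)
      counts <- vapply(obs, function(o) o$count, integer(1))
      two <- obs[counts == 2L]
      lows <- vapply(two, function(o) o$modes$center[1L], numeric(1))
      highs <- vapply(two, function(o) o$modes$center[2L], numeric(1))
      tabc <- table(counts)
      rows[[run_id]] <- data.frame(
        channel = if (sg == 0) "none" else ch, sigma = sg,
        modal_clusters = as.integer(names(tabc)[which.max(tabc)]),
        frac_bimodal = mean(counts == 2L),
        center_low = if (length(lows)) mean(lows) else NA_real_,
        center_high = if (length(highs)) mean(highs) else NA_real_,
        window_variance = mean(traj$variances[idx]))
    }
    first_channel <- FALSE
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relaxation slow-down near a bifurcation of the response function
#'
#' For the pitchfork response family at `lam = 1/2` (where the replicator
#' term drops out), the mean production level relaxes exponentially
#' towards the fixed point at 1/2 when the bifurcation parameter `a` is
#' negative; the relaxation rate is proportional to `|a|` near the
#' bifurcation at `a = 0`, so the relaxation time diverges as the
#' bifurcation is approached.
#'
#' @param a_grid Negative bifurcation-parameter values.
#' @param b Cubic coefficient of the pitchfork family.
#' @param s Selection strength.
#' @param lam Response probability (1/2 by construction).
#' @param init Initial distribution; its mean must differ from 1/2.
#' @param t_max Integration horizon per value of `a`.
#' @return A data.frame with columns `a`, `rate` (fitted exponential
#'   relaxation rate of `|mean - 1/2|`), `r_squared` of the log-linear
#'   fit, and `relaxation_time` (`1/rate`).
#' @export
bifurcation_timescale <- function(a_grid = c(-0.4, -0.2, -0.1, -0.05,
                                             -0.02), b = 1, s = 0.2,
                                  lam = 0.5,
                                  init = init_dist("uniform", min = 0,
                                                   max = 0.8),
                                  t_max = 600) {
  if (any(a_grid >= 0))
    stop("a_grid must be negative (below the bifurcation)",
         call. = FALSE)
  rows <- lapply(a_grid, function(a) {
    R <- response_fn("pitchfork", a = a, b = b)
    tr <- mf_integrate(init, s, lam, R, t_max = t_max,
                       record_every = min(1, t_max / 200),
                       n_atoms = 100L)
    u <- abs(tr$means - 0.5)
    # fit strictly above the atom-merge resolution so the noise floor of
    # the measure representation does not flatten the slope
    ok <- u > 1e-3 & u < u[1L] * 0.5 & tr$times > 0
    if (sum(ok) < 5L)
      return(data.frame(a = a, rate = NA_real_, r_squared = NA_real_,
                        relaxation_time = NA_real_))
    fit <- stats::lm(log(u[ok]) ~ tr$times[ok])
    rate <- -unname(stats::coef(fit)[2L])
    data.frame(a = a, rate = rate,
               r_squared = summary(fit)$r.squared,
               relaxation_time = 1 / rate)
  })
  do.call(rbind, rows)
}

#' Run a named experiment
#'
#' Dispatches the experiment drivers by id, optionally applying parameter
#' overrides from a configuration and writing tables, a configuration
#' echo, plots and a run manifest to an output directory. Every
#' experiment is bit-reproducible from its configuration and seed.
#'
#' @param id One of `"histogram_evolution"`, `"decay_lambda0"`,
#'   `"absorption_scaling"`, `"phase_diagram"`, `"variance_vs_lambda"`,
#'   `"initial_robustness"`, `"noise_robustness"`,
#'   `"bifurcation_timescale"`.
#' @param config Optional `qs_config`; its model parameters and
#'   `experiment` section override driver defaults.
#' @param out_dir Optional output directory.
#' @param force Overwrite a non-empty output directory.
#' @param make_plots Write diagnostic PNG plots (only when `out_dir` is
#'   given).
#' @param ... Further overrides passed to the driver.
#' @return The driver's result, invisibly when written to disk.
#' @export
run_experiment <- function(id, config = NULL, out_dir = NULL,
                           force = FALSE, make_plots = TRUE, ...) {
  ids <- c("histogram_evolution", "decay_lambda0", "absorption_scaling",
           "phase_diagram", "variance_vs_lambda", "initial_robustness",
           "noise_robustness", "bifurcation_timescale")
  if (!is.character(id) || length(id) != 1L || !id %in% ids)
    stop("unknown experiment id; valid ids: ",
         paste(ids, collapse = ", "), call. = FALSE)
  args <- list(...)
  if (!is.null(config)) {
    base <- list(s = config$params$s, lam = config$params$lam,
                 N = config$params$N, seed = config$params$seed %||% 1)
    ov <- config$experiment
    ov$id <- NULL
    base[names(ov)] <- ov
    # only pass what the driver accepts
    fmls <- names(formals(get(id)))
    base <- base[intersect(names(base), fmls)]
    base[names(args)] <- args
    args <- base
  }
  res <- do.call(id, args)
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L &&
        !force)
      stop("output directory ", out_dir,
           " is not empty; use force = TRUE", call. = FALSE)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tabs <- experiment_tables(id, res)
    for (nm in names(tabs)) {
      df <- tabs[[nm]]
      df[] <- lapply(df, fmt12)
      utils::write.csv(df, file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
    if (!is.null(config))
      write_config(config, file.path(out_dir, "config_echo.yaml"))
    yaml::write_yaml(list(experiment = id,
                          written = format(Sys.time(),
                                           "%Y-%m-%d %H:%M:%S %Z"),
                          package = as.character(
                            utils::packageVersion("quorumdyn")),
                          overrides = args[setdiff(names(args),
                                                   c("R", "init",
                                                     "init_list"))]),
                     file.path(out_dir, "manifest.yaml"))
    if (make_plots)
      tryCatch(experiment_plot(id, res, out_dir),
               error = function(e) warning("plotting failed: ",
                                           conditionMessage(e)))
    return(invisible(res))
  }
  res
}

experiment_tables <- function(id, res) {
  switch(id,
    histogram_evolution = list(trajectory = res$table),
    decay_lambda0 = {
      out <- list(analytic = res$table)
      if (!is.null(res$table_sim)) out$simulated <- res$table_sim
      out
    },
    absorption_scaling = list(scaling = res$table),
    phase_diagram = list(grid = res$table),
    variance_vs_lambda = list(curve = res$table,
                              analytic = res$analytic),
    initial_robustness = list(
      distances = data.frame(init = names(res$to_stationary),
                             to_stationary = res$to_stationary)),
    noise_robustness = list(noise = res),
    bifurcation_timescale = list(timescales = res))
}

experiment_plot <- function(id, res, out_dir) {
  path <- file.path(out_dir, paste0(id, ".png"))
  grDevices::png(path, width = 900, height = 600, res = 110)
  on.exit(grDevices::dev.off())
  switch(id,
    histogram_evolution = {
      h <- res$ensemble$pooled_histograms
      graphics::image(x = res$ensemble$times,
                      y = seq(0, 1, length.out = ncol(h)),
                      z = log1p(h), xlab = "time t",
                      ylab = "production degree p",
                      main = "pooled histogram evolution (log scale)")
    },
    decay_lambda0 = {
      graphics::plot(res$table$t, res$table$mean, log = "xy",
                     type = "l", xlab = "t", ylab = "<p>",
                     main = sprintf("algebraic decay, slope %.3f",
                                    res$slope_analytic))
      if (!is.null(res$table_sim))
        graphics::points(res$table_sim$t, res$table_sim$mean, col = 2)
    },
    absorption_scaling = {
      tb <- res$table
      graphics::plot(tb$N, tb$geo_mean, log = "y", pch = 19,
                     xlab = "N", ylab = "T_abs (geometric mean)",
                     main = sprintf("T_abs ~ exp(gamma N), gamma = %.3g",
                                    res$gamma))
      graphics::segments(tb$N, tb$q025, tb$N, tb$q975, col = "gray")
    },
    phase_diagram = {
      tb <- res$table
      graphics::plot(tb$lambda, tb$kappa,
                     pch = ifelse(tb$heterogeneous_sim, 19, 1),
                     cex = 1.8, xlab = "lambda", ylab = "kappa",
                     main = "heterogeneity (filled) vs boundary s/2")
      graphics::abline(v = res$lambda_up, lty = 2)
    },
    variance_vs_lambda = {
      graphics::plot(res$analytic$lambda, res$analytic$variance,
                     type = "l", xlab = "lambda",
                     ylab = "stationary Var(p)",
                     main = "order parameter vs response probability")
      graphics::points(res$table$lambda, res$table$variance_sim,
                       col = 2, pch = 19)
    },
    initial_robustness = {
      graphics::barplot(res$to_stationary,
                        ylab = "transport distance to bimodal solution",
                        main = "common attractor across initials")
    },
    noise_robustness = {
      graphics::plot(res$sigma, res$frac_bimodal,
                     col = as.integer(factor(res$channel)), pch = 19,
                     ylim = c(0, 1), xlab = "sigma",
                     ylab = "fraction of bimodal snapshots",
                     main = "bimodality under noise channels")
    },
    bifurcation_timescale = {
      graphics::plot(-res$a, res$rate, log = "xy", pch = 19,
                     xlab = "|a| (distance to bifurcation)",
                     ylab = "relaxation rate",
                     main = "critical slowing near the pitchfork")
    })
  invisible(path)
}
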