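#' Configuration of the Brownian-dynamics integrator
#'
#' Settings for the overdamped Langevin (Euler--Maruyama) integrator
#' used by [simulate_window()] and [first_passage_time()]. The
#' stochastic convention is fixed: It\eqn{\hat{o}} stepping with the
#' explicit divergence correction \eqn{D'(z)} in the drift, which
#' guarantees a Boltzmann stationary density even when the diffusivity
#' varies with position.
#'
#' The default timestep (0.01 ps) keeps the dimensionless stiffness
#' \eqn{k_u D \Delta t / RT} below 0.05 for the default umbrella spring
#' (1000 kJ/mol/nm^2) and bulk diffusivity.
#'
#' @param timestep Integration step, ps.
#' @param n_steps Number of production steps.
#' @param equilibration_steps Steps discarded before sampling begins.
#' @param sample_stride Record every `sample_stride`-th step.
#' @param seed Integer seed; identical seeds and settings give
#'   bit-identical trajectories.
#' @return An object of class `langevin_config`.
#' @export
langevin_config <- function(timestep = 0.01, n_steps = 2e5,
                            equilibration_steps = 2e4,
                            sample_stride = 10, seed = 1L) {
  if (timestep <= 0) abort("`timestep` must be positive (ps).")
  if (sample_stride < 1) abort("`sample_stride` must be >= 1.")
  if (n_steps < sample_stride) abort("`n_steps` must be >= `sample_stride`.")
  if (equilibration_steps < 0) abort("`equilibration_steps` must be >= 0.")
  structure(
    list(timestep = timestep, n_steps = as.integer(n_steps),
         equilibration_steps = as.integer(equilibration_steps),
         sample_stride = as.integer(sample_stride),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         stochastic_convention = "Ito-with-drift-correction"),
    class = "langevin_config"
  )
}

new_window_set <- function(df, spacing = NA_real_) {
  tibble::new_tibble(df, spacing = spacing,
                     class = c("window_set", "tbl_df", "tbl", "data.frame"))
}

#' Simulate one umbrella-sampling window
#'
#' Integrates overdamped Brownian dynamics on the model landscape under
#' a harmonic umbrella bias \eqn{k_u (z - z_0)^2 / 2} and records, at
#' each sampling stride, the position and the total systematic force on
#' the particle, \eqn{F = -W'(z) - k_u (z - z_0)} (kJ/mol/nm). The
#' long-run position histogram converges to the biased Boltzmann
#' density \eqn{\propto e^{-[W(z) + k_u (z - z_0)^2/2]/RT}}.
#'
#' @param model A [membrane_model()].
#' @param center Umbrella centre \eqn{z_0}, nm (within the support).
#' @param spring Umbrella spring constant \eqn{k_u}, kJ/mol/nm^2.
#' @param config A [langevin_config()].
#' @param thermo A [thermo_state()].
#' @param replicate Replicate label attached to the samples.
#' @return A `window_set` tibble with one row per sample and columns
#'   `center`, `spring`, `replicate`, `time` (ps), `position` (nm),
#'   `force` (kJ/mol/nm).
#' @examples
#' w <- simulate_window(membrane_model(), 0,
#'                      config = langevin_config(n_steps = 1000))
#' @export
simulate_window <- function(model, center, spring = 1000,
                            config = langevin_config(),
                            thermo = thermo_state(), replicate = 1L) {
  stopifnot(inherits(model, "membrane_model"),
            inherits(config, "langevin_config"))
  thermo <- as_thermo(thermo)
  if (spring < 0) abort("`spring` must be non-negative.")
  if (abs(center) > model$half_width) {
    abort("`center` must lie within [-L, L] of the model.")
  }
  # A typical diffusive step must stay well below the landscape scale,
  # otherwise the discretised dynamics hops over the barrier structure.
  rms_step <- sqrt(2 * model$bulk_diffusivity * config$timestep)
  if (rms_step > model$barrier_width / 2) {
    abort(paste0("Timestep too large: rms displacement ",
                 signif(rms_step, 3), " nm exceeds half the barrier ",
                 "width. Reduce `timestep`."))
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  sim <- simulate_window_cpp(model_params(model), center, spring,
                             thermo$RT, config$timestep, config$n_steps,
                             config$equilibration_steps,
                             config$sample_stride)
  dt_samp <- config$timestep * config$sample_stride
  n <- length(sim$position)
  new_window_set(tibble::tibble(
    center = rep(center, n),
    spring = rep(spring, n),
    replicate = rep(as.integer(replicate), n),
    time = dt_samp * seq_len(n),
    position = sim$position,
    force = sim$force
  ))
}

#' Generate a ladder of umbrella windows
#'
#' Simulates umbrella windows at evenly spaced centres
#' `z_min, z_min + spacing, ...` (the default 0.1 nm spacing and
#' 1000 kJ/mol/nm^2 spring mirror common umbrella protocols for
#' membrane permeation), optionally with several independent
#' replicates per centre.
#'
#' @inheritParams simulate_window
#' @param z_min,z_max Range of window centres, nm.
#' @param spacing Centre-to-centre distance, nm.
#' @param n_replicates Independent replicates per centre.
#' @return A `window_set` tibble (see [simulate_window()]) containing
#'   `floor((z_max - z_min)/spacing) + 1` centres per replicate.
#' @export
simulate_windows <- function(model, z_min = -2.5, z_max = 2.5,
                             spacing = 0.1, spring = 1000,
                             n_replicates = 1,
                             config = langevin_config(),
                             thermo = thermo_state()) {
  if (spacing <= 0) abort("`spacing` must be positive.")
  if (!(z_min < z_max)) abort("`z_min` must be smaller than `z_max`.")
  n_centers <- floor((z_max - z_min) / spacing + 1e-9) + 1
  centers <- z_min + spacing * (seq_len(n_centers) - 1)
  base_seed <- config$seed %||% 1L
  grid <- tidyr::expand_grid(replicate = seq_len(n_replicates),
                             idx = seq_len(n_centers))
  out <- purrr::pmap(grid, function(replicate, idx) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + 7919L * (replicate - 1L) + idx)
    simulate_window(model, centers[idx], spring = spring, config = cfg,
                    thermo = thermo, replicate = replicate)
  })
  new_window_set(dplyr::bind_rows(out), spacing = spacing)
}

#' Stochastic mean first-passage time
#'
#' Brute-force first-passage oracle: releases independent particles at
#' `start` and integrates unbiased Brownian dynamics on the landscape
#' until they reach the absorbing boundary, with a reflecting boundary
#' behind the start. The mean agrees with the closed-form double
#' integral computed by [mean_first_passage_theory()], which makes this
#' a stringent end-to-end check of the integrator.
#'
#' @inheritParams simulate_window
#' @param start Release position, nm.
#' @param absorbing Absorbing boundary, nm.
#' @param reflecting Reflecting boundary, nm (opposite side of `start`).
#' @param n_particles Number of independent particles (>= 2).
#' @param max_time Per-particle time budget, ps; particles that have
#'   not been absorbed are dropped with a warning.
#' @return A tibble with columns `mean` (ps), `sem` (ps), `n`.
#' @export
first_passage_time <- function(model, thermo = thermo_state(),
                               config = langevin_config(),
                               start, absorbing, reflecting,
                               n_particles = 200, max_time = 1e7) {
  stopifnot(inherits(model, "membrane_model"),
            inherits(config, "langevin_config"))
  thermo <- as_thermo(thermo)
  if (n_particles < 2) abort("`n_particles` must be at least 2.")
  lo <- min(absorbing, reflecting); hi <- max(absorbing, reflecting)
  if (start < lo || start > hi) {
    abort("`start` must lie between the reflecting and absorbing boundaries.")
  }
  if (absorbing == start) {
    return(tibble::tibble(mean = 0, sem = 0, n = as.integer(n_particles)))
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  times <- first_passage_cpp(model_params(model), thermo$RT,
                             config$timestep, start, absorbing,
                             reflecting, as.integer(n_particles),
                             max_time / config$timestep)
  if (anyNA(times)) {
    warn(sprintf("%d of %d particles not absorbed within `max_time`.",
                 sum(is.na(times)), n_particles))
    times <- times[!is.na(times)]
  }
  tibble::tibble(mean = mean(times),
                 sem = sd(times) / sqrt(length(times)),
                 n = length(times))
}

#' Simulate a first-order uptake time series
#'
#' Generates fractional uptake \eqn{1 - e^{-k t}} with optional
#' additive Gaussian noise, emulating time-resolved intracellular
#' accumulation of a permeant governed by first-order kinetics.
#'
#' @param rate First-order rate constant \eqn{k}, 1/s.
#' @param times Sampling times, s (strictly increasing, length >= 3).
#' @param noise_sd Standard deviation of additive Gaussian noise,
#'   fraction of plateau.
#' @param seed Optional integer seed.
#' @return An `uptake_series` tibble with columns `time` (s), `value`.
#' @examples
#' simulate_uptake(1e-4, seq(0, 2e4, length.out = 5))
#' @export
simulate_uptake <- function(rate, times, noise_sd = 0, seed = NULL) {
  if (rate <= 0) abort("`rate` must be positive (1/s).")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (length(times) < 3 || any(diff(times) <= 0)) {
    abort("`times` must be strictly increasing with length >= 3.")
  }
  if (!is.null(seed)) set.seed(seed)
  values <- 1 - exp(-rate * times)
  if (noise_sd > 0) values <- values + rnorm(length(times), 0, noise_sd)
  tibble::new_tibble(tibble::tibble(time = times, value = values),
                     class = c("uptake_series", "tbl_df", "tbl",
                               "data.frame"))
}
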