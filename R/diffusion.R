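#' Autocorrelation of force fluctuations in one umbrella window
#'
#' Computes \eqn{\langle \Delta F_z(t) \Delta F_z(0) \rangle} where
#' \eqn{\Delta F_z} is the instantaneous force on the permeant minus
#' its window mean, using the biased (1/N) covariance estimator. When
#' the window carries no force record (e.g. position-only pull files),
#' the harmonic restraint force \eqn{-k_u(z - z_0)} is used instead,
#' with a warning.
#'
#' @param window A single-window `window_set` tibble (one centre, one
#'   replicate).
#' @param max_lag Largest lag, ps; must be shorter than the window
#'   duration.
#' @return An `acf_series` tibble with columns `lag` (ps, uniform,
#'   starting at 0) and `value` ((kJ/mol/nm)^2). The lag-0 value is the
#'   force variance (1/N convention).
#' @export
force_acf <- function(window, max_lag = 20) {
  f <- window_force(window)
  dt <- window_dt(window)
  n <- length(f)
  if (n < 10) abort("Window must contain at least 10 samples.")
  duration <- dt * (n - 1)
  if (max_lag >= duration) {
    abort(sprintf("`max_lag` (%g ps) must be below the window duration (%g ps).",
                  max_lag, duration))
  }
  k <- min(n - 1, floor(max_lag / dt))
  ac <- acf(f, lag.max = k, type = "covariance", demean = TRUE,
            plot = FALSE)$acf[, 1, 1]
  tibble::new_tibble(
    tibble::tibble(lag = dt * (0:k), value = ac),
    class = c("acf_series", "tbl_df", "tbl", "data.frame"))
}

window_force <- function(window) {
  check_window_set(window)
  if (length(unique(window$center)) != 1 ||
      length(unique(window$replicate)) != 1) {
    abort("Expected a single (center, replicate) window.")
  }
  f <- window$force
  if (is.null(f) || all(is.na(f))) {
    warn("No force record; using the restraint force -k_u (z - z0).")
    f <- -window$spring * (window$position - window$center)
  }
  f
}

window_dt <- function(window) {
  if (!"time" %in% names(window) || nrow(window) < 2) {
    abort("Window must carry a `time` column with >= 2 samples.")
  }
  window$time[2] - window$time[1]
}

#' Fit a single-exponential decay to an ACF
#'
#' Least-squares fit of \eqn{A e^{-t/\tau}} to the autocorrelation
#' function, over lags from zero up to the first lag where the ACF
#' drops below \eqn{A e^{-3}} (capped at the series length). Starting
#' values are \eqn{A = } ACF(0) and \eqn{\tau = } the first 1/e
#' crossing. The time integral of the ACF is then taken analytically as
#' \eqn{A\tau}.
#'
#' @param acf_series An `acf_series` tibble from [force_acf()].
#' @return A list with elements `A` ((kJ/mol/nm)^2), `tau` (ps) and
#'   `n_fit` (number of lags used).
#' @export
fit_single_exponential <- function(acf_series) {
  stopifnot(is.data.frame(acf_series),
            all(c("lag", "value") %in% names(acf_series)))
  t <- acf_series$lag; v <- acf_series$value
  A0 <- v[1]
  if (!is.finite(A0) || A0 <= 0) {
    abort("ACF at lag 0 must be positive to fit an exponential decay.")
  }
  below <- which(v < A0 * exp(-3))
  n_fit <- if (length(below)) max(below[1], 4L) else length(v)
  n_fit <- min(n_fit, length(v))
  tt <- t[1:n_fit]; vv <- v[1:n_fit]
  cross <- which(vv < A0 * exp(-1))
  tau0 <- if (length(cross)) max(tt[cross[1]], tt[2]) else tt[n_fit] / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(vv ~ A * exp(-tt / tau),
                      start = list(A = A0, tau = tau0),
                      lower = c(A = 0, tau = .Machine$double.eps),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # log-linear fallback on the positive head of the decay
    pos <- vv > A0 * 1e-3
    if (sum(pos) < 3) {
      abort("Exponential fit to the ACF failed to converge.")
    }
    lf <- lm(log(vv[pos]) ~ tt[pos])
    A <- exp(coef(lf)[[1]]); tau <- -1 / coef(lf)[[2]]
    if (!is.finite(tau) || tau <= 0) {
      abort("Exponential fit to the ACF failed to converge.")
    }
  } else {
    A <- coef(fit)[["A"]]; tau <- coef(fit)[["tau"]]
  }
  list(A = A, tau = tau, n_fit = n_fit)
}

#' Local diffusion coefficient from force fluctuations
#'
#' Implements the force-correlation estimator
#' \deqn{D(z) = (RT)^2 \Big/ \int_0^\infty
#'       \langle \Delta F_z(z,t) \Delta F_z(z,0)\rangle\, dt,}
#' with the integral evaluated analytically as \eqn{A\tau} from the
#' single-exponential fit of the ACF. For a harmonic window on a
#' locally flat landscape (an Ornstein--Uhlenbeck process) the identity
#' is exact: \eqn{A = k_{eff} RT}, \eqn{\tau = RT/(k_{eff} D)}, hence
#' \eqn{(RT)^2/(A\tau) = D} independent of the effective stiffness.
#'
#' @inheritParams force_acf
#' @param thermo A [thermo_state()].
#' @return A one-row tibble: `center`, `replicate`, `D` (nm^2/ps), `A`,
#'   `tau` (ps).
#' @export
estimate_diffusion <- function(window, thermo = thermo_state(),
                               max_lag = 20) {
  thermo <- as_thermo(thermo)
  ac <- force_acf(window, max_lag = max_lag)
  fit <- fit_single_exponential(ac)
  if (!is.finite(fit$A * fit$tau) || fit$A * fit$tau <= 0) {
    abort("Non-positive ACF integral; cannot estimate D.")
  }
  tibble::tibble(center = window$center[1],
                 replicate = window$replicate[1],
                 D = thermo$RT^2 / (fit$A * fit$tau),
                 A = fit$A, tau = fit$tau)
}

block_estimates <- function(window, thermo, n_blocks = 4, max_lag = 20) {
  n <- nrow(window)
  if (n < 10 * n_blocks) {
    abort(sprintf("Window too short to split into %d blocks of >= 10 samples.",
                  n_blocks))
  }
  size <- n %/% n_blocks
  purrr::map_dfr(seq_len(n_blocks), function(b) {
    rows <- ((b - 1) * size + 1):(b * size)
    blk <- new_window_set(window[rows, , drop = FALSE])
    blk$time <- blk$time - blk$time[1] + (blk$time[2] - blk$time[1])
    est <- estimate_diffusion(blk, thermo,
                              max_lag = min(max_lag,
                                            (nrow(blk) - 2) *
                                              window_dt(blk)))
    dplyr::mutate(est, block = b)
  })
}

#' Block standard deviation of the diffusion estimate
#'
#' Splits the window time series into `n_blocks` contiguous equal
#' parts, estimates \eqn{D} independently on each, and returns the
#' standard deviation of the block values — the error bar convention
#' for force-correlation diffusion profiles. The block mean is the
#' value used in [diffusion_profile()].
#'
#' @inheritParams estimate_diffusion
#' @param n_blocks Number of contiguous blocks (default 4).
#' @return Standard deviation of the block estimates, nm^2/ps.
#' @export
block_sd <- function(window, thermo = thermo_state(), n_blocks = 4,
                     max_lag = 20) {
  sd(block_estimates(window, thermo, n_blocks, max_lag)$D)
}

#' Position-dependent diffusion profile from umbrella windows
#'
#' For every (centre, replicate) window: block-wise force-correlation
#' estimates of \eqn{D}; the replicate value is the block mean and its
#' error the block standard deviation. Replicates at the same centre
#' are then averaged, combining block errors in quadrature with the
#' replicate-scatter standard error.
#'
#' @param windows A `window_set` tibble.
#' @inheritParams block_sd
#' @return A `diffusion_profile` tibble: `z` (centre, nm), `D`
#'   (nm^2/ps), `sigma_D`, `n_replicates`.
#' @export
diffusion_profile <- function(windows, thermo = thermo_state(),
                              n_blocks = 4, max_lag = 20) {
  check_window_set(windows)
  thermo <- as_thermo(thermo)
  per_rep <- windows |>
    dplyr::group_by(.data$center, .data$replicate) |>
    dplyr::group_modify(function(d, key) {
      w <- new_window_set(dplyr::mutate(d, center = key$center,
                                        replicate = key$replicate))
      blk <- block_estimates(w, thermo, n_blocks, max_lag)
      tibble::tibble(D = mean(blk$D), block_sd = sd(blk$D))
    }) |>
    dplyr::ungroup()
  out <- per_rep |>
    dplyr::group_by(z = .data$center) |>
    dplyr::summarise(
      D_mean = mean(.data$D),
      sigma_D = sqrt(sum(.data$block_sd^2) / dplyr::n()^2 +
                       (if (dplyr::n() > 1) var(.data$D) / dplyr::n()
                        else 0)),
      n_replicates = dplyr::n(), .groups = "drop") |>
    dplyr::rename(D = "D_mean") |>
    dplyr::arrange(.data$z)
  tibble::new_tibble(out, class = c("diffusion_profile", "tbl_df",
                                    "tbl", "data.frame"))
}
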