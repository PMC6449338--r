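#' Local resistance profile of the membrane
#'
#' Combines a PMF and a diffusion profile into the local permeation
#' resistance of the inhomogeneous solubility-diffusion model,
#' \deqn{r(z) = e^{W(z)/RT} / D(z),}
#' on the PMF grid, with the diffusion profile interpolated linearly
#' (it varies slowly; the exponential of \eqn{W} dominates). First-order
#' error propagation with independent bins gives
#' \eqn{\sigma_r = r \sqrt{(\sigma_W/RT)^2 + (\sigma_D/D)^2}}.
#'
#' @param pmf A `pmf_profile` tibble (`z`, `W`, `sigma_W`).
#' @param dprof A `diffusion_profile` tibble (`z`, `D`, `sigma_D`).
#' @param thermo A [thermo_state()].
#' @param z1,z2 Optional limits, nm; when supplied, undefined `W` or
#'   non-positive `D` anywhere inside `[z1, z2]` is an error naming the
#'   offending bins.
#' @return A `resistance_profile` tibble: `z` (nm), `r` (ps/nm^2),
#'   `sigma_r` (ps/nm^2). Multiply by 1e6 for s/m^2.
#' @export
resistance_profile <- function(pmf, dprof, thermo = thermo_state(),
                               z1 = NULL, z2 = NULL) {
  stopifnot(inherits(pmf, "pmf_profile"),
            is.data.frame(dprof), all(c("z", "D") %in% names(dprof)))
  thermo <- as_thermo(thermo)
  keep <- pmf$z >= min(dprof$z) & pmf$z <= max(dprof$z)
  z <- pmf$z[keep]
  W <- pmf$W[keep]
  sW <- pmf$sigma_W[keep]
  D <- approx(dprof$z, dprof$D, xout = z)$y
  sD <- if ("sigma_D" %in% names(dprof)) {
    approx(dprof$z, dprof$sigma_D, xout = z)$y
  } else rep(0, length(z))
  if (!is.null(z1) && !is.null(z2)) {
    inside <- z >= z1 & z <= z2
    bad <- inside & (!is.finite(W) | D <= 0)
    if (any(bad)) {
      abort(paste0("Resistance undefined inside [z1, z2] at z = ",
                   paste(signif(z[bad], 4), collapse = ", "),
                   " (undefined W or non-positive D)."))
    }
  }
  if (any(D <= 0, na.rm = TRUE)) {
    abort("Diffusion profile must be positive wherever used.")
  }
  r <- exp(W / thermo$RT) / D
  sW0 <- ifelse(is.finite(sW), sW, 0)
  sD0 <- ifelse(is.finite(sD), sD, 0)
  sigma_r <- r * sqrt((sW0 / thermo$RT)^2 + (sD0 / D)^2)
  tibble::new_tibble(
    tibble::tibble(z = z, r = r, sigma_r = sigma_r),
    class = c("resistance_profile", "tbl_df", "tbl", "data.frame"))
}

#' Total resistance and permeability from a resistance profile
#'
#' Trapezoidal integration of the local resistance over `[z1, z2]`
#' gives the total resistance; the permeability is its exact
#' reciprocal:
#' \deqn{P = 1 \Big/ \int_{z_1}^{z_2} r(z)\, dz.}
#' The default limits of +/-2.3 nm sit in the water phase where the
#' local resistance is negligible, so the result is insensitive to
#' their exact choice. Uncertainties propagate with independent bins:
#' \eqn{\sigma_R^2 = \sum_b (w_b \sigma_{r,b})^2} with trapezoid
#' weights \eqn{w_b}, and \eqn{\sigma_P = \sigma_R / R^2}.
#'
#' @param rprof A `resistance_profile` tibble (internal units
#'   ps/nm^2).
#' @param z1,z2 Integration limits, nm; the profile must cover them.
#' @return A `permeability_result` tibble (one row): `R_total` (s/m),
#'   `P` (m/s), `sigma_R` (s/m), `sigma_P` (m/s), `z1`, `z2`.
#' @export
integrate_permeability <- function(rprof, z1 = -2.3, z2 = 2.3) {
  stopifnot(inherits(rprof, "resistance_profile") ||
              (is.data.frame(rprof) && all(c("z", "r") %in% names(rprof))))
  if (!(z1 < z2)) abort("`z1` must be smaller than `z2`.")
  ok <- is.finite(rprof$r)
  z <- rprof$z[ok]; r <- rprof$r[ok]
  sr <- if ("sigma_r" %in% names(rprof)) rprof$sigma_r[ok] else
    rep(0, length(z))
  if (any(sr < 0, na.rm = TRUE)) abort("Negative `sigma_r` supplied.")
  step <- if (length(z) > 1) max(diff(z)) else Inf
  if (min(z) > z1 + step || max(z) < z2 - step) {
    abort(sprintf("Resistance profile covers [%g, %g] but limits are [%g, %g].",
                  min(z), max(z), z1, z2))
  }
  keep <- z >= z1 - 1e-9 & z <= z2 + 1e-9
  z <- z[keep]; r <- r[keep]; sr <- sr[keep]
  if (length(z) < 2) abort("Fewer than two bins inside the limits.")
  if (any(diff(z) > 2 * step)) {
    abort("Coverage gap (undefined bins) inside the integration limits.")
  }
  R_int <- pracma::trapz(z, r) # ps/nm
  dz <- diff(z)
  w <- c(dz / 2, 0) + c(0, dz / 2) # trapezoid weights
  sigma_R_int <- sqrt(sum((w * sr)^2))
  R_total <- R_int * 1e-3       # ps/nm -> s/m
  sigma_R <- sigma_R_int * 1e-3
  P <- 1 / R_total
  tibble::new_tibble(
    tibble::tibble(R_total = R_total, P = P, sigma_R = sigma_R,
                   sigma_P = sigma_R / R_total^2, z1 = z1, z2 = z2),
    class = c("permeability_result", "tbl_df", "tbl", "data.frame"))
}

#' Propagated uncertainties of resistance and permeability
#'
#' Convenience wrapper running [resistance_profile()] and
#' [integrate_permeability()] and returning only the propagated
#' uncertainty pieces: per-bin `sigma_r`, and scalar `sigma_R`,
#' `sigma_P`.
#'
#' @inheritParams resistance_profile
#' @param z1,z2 Integration limits, nm.
#' @return A list: `sigma_r` tibble (`z`, `sigma_r` in ps/nm^2),
#'   `sigma_R` (s/m), `sigma_P` (m/s).
#' @export
propagate_errors <- function(pmf, dprof, thermo = thermo_state(),
                             z1 = -2.3, z2 = 2.3) {
  if (any(pmf$sigma_W < 0, na.rm = TRUE) ||
      ("sigma_D" %in% names(dprof) && any(dprof$sigma_D < 0,
                                          na.rm = TRUE))) {
    abort("Input sigmas must be non-negative.")
  }
  rp <- resistance_profile(pmf, dprof, thermo, z1 = z1, z2 = z2)
  res <- integrate_permeability(rp, z1 = z1, z2 = z2)
  list(sigma_r = tibble::tibble(z = rp$z, sigma_r = rp$sigma_r),
       sigma_R = res$sigma_R, sigma_P = res$sigma_P)
}

#' Full permeability pipeline from umbrella windows
#'
#' Composition of the three analysis stages: PMF by WHAM with
#' histogram-bootstrap errors ([pmf_wham()]), diffusion profile from
#' force autocorrelations with block errors ([diffusion_profile()]),
#' and resistance integration with error propagation
#' ([resistance_profile()], [integrate_permeability()]). Deterministic
#' for a fixed `seed`.
#'
#' @param windows A `window_set` tibble spanning the integration
#'   limits.
#' @inheritParams pmf_wham
#' @inheritParams diffusion_profile
#' @param z1,z2 Integration limits, nm.
#' @return A `perm_fit` object: list with `pmf`, `dprof`, `rprof`,
#'   `result` and `settings`. `tidy()` returns the result row,
#'   `glance()` a run summary, `autoplot()` the profiles.
#' @export
compute_permeability <- function(windows, thermo = thermo_state(),
                                 bin_width = 0.02,
                                 reference_region = c(2.0, 2.3),
                                 mode = c("replicate-average", "pooled"),
                                 n_boot = 400, seed = NULL,
                                 n_blocks = 4, max_lag = 20,
                                 z1 = -2.3, z2 = 2.3,
                                 tol = 1e-6, max_iter = 1e5) {
  mode <- match.arg(mode)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  pmf <- stage("wham", pmf_wham(windows, thermo, bin_width = bin_width,
                                reference_region = reference_region,
                                mode = mode, n_boot = n_boot,
                                seed = seed, tol = tol,
                                max_iter = max_iter))
  dprof <- stage("diffusion",
                 diffusion_profile(windows, thermo, n_blocks = n_blocks,
                                   max_lag = max_lag))
  rprof <- stage("resistance",
                 resistance_profile(pmf, dprof, thermo, z1 = z1, z2 = z2))
  result <- stage("integration",
                  integrate_permeability(rprof, z1 = z1, z2 = z2))
  settings <- list(temperature = as_thermo(thermo)$temperature,
                   bin_width = bin_width,
                   reference_region = reference_region, mode = mode,
                   n_boot = n_boot, seed = seed, n_blocks = n_blocks,
                   max_lag = max_lag, z1 = z1, z2 = z2, tol = tol)
  structure(list(pmf = pmf, dprof = dprof, rprof = rprof,
                 result = result, settings = settings),
            class = "perm_fit")
}

#' @export
print.perm_fit <- function(x, ...) {
  cat("<perm_fit>\n")
  cat(sprintf("  R_total = %.3g +/- %.2g s/m\n", x$result$R_total,
              x$result$sigma_R))
  cat(sprintf("  P       = %.3g +/- %.2g m/s  (limits %g..%g nm)\n",
              x$result$P, x$result$sigma_P, x$result$z1, x$result$z2))
  invisible(x)
}

#' @export
tidy.perm_fit <- function(x, ...) x$result

#' @export
glance.perm_fit <- function(x, ...) {
  tibble::tibble(
    P = x$result$P, R_total = x$result$R_total,
    sigma_P = x$result$sigma_P,
    barrier = max(x$pmf$W, na.rm = TRUE),
    D_min = min(x$dprof$D), D_max = max(x$dprof$D),
    n_windows = dplyr::n_distinct(x$dprof$z),
    temperature = x$settings$temperature)
}
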