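#' Fit first-order uptake kinetics
#'
#' Least-squares fit of the saturating exponential
#' \eqn{C(t) = C_\infty (1 - e^{-kt})} to an uptake time series
#' (optionally with a free baseline offset). This is the conventional
#' reduction of time-resolved intracellular drug accumulation to a
#' single effective rate constant.
#'
#' @param uptake A data frame with columns `time` (s) and `value`
#'   (e.g. an `uptake_series` from [simulate_uptake()]).
#' @param offset Fit a free additive baseline as well (default FALSE).
#' @return A `first_order_fit`: list with `k` (1/s), `C_inf`,
#'   `residual_rms` and the underlying `nls` fit. `tidy()` and
#'   `glance()` methods are provided.
#' @examples
#' fit_first_order(simulate_uptake(1e-4, seq(60, 3.6e4, by = 600)))
#' @export
fit_first_order <- function(uptake, offset = FALSE) {
  stopifnot(is.data.frame(uptake),
            all(c("time", "value") %in% names(uptake)))
  t <- uptake$time; v <- uptake$value
  if (length(t) < 3) abort("Need at least 3 points to fit.")
  if (sd(v) == 0) abort("Uptake values are all equal; nothing to fit.")
  C0 <- max(v)
  slope <- (v[2] - v[1]) / (t[2] - t[1])
  k0 <- max(slope / C0, 1 / max(t))
  fit <- tryCatch(
    if (offset) {
      minpack.lm::nlsLM(v ~ c0 + Cinf * (1 - exp(-k * t)),
                        start = list(Cinf = C0, k = k0, c0 = 0))
    } else {
      minpack.lm::nlsLM(v ~ Cinf * (1 - exp(-k * t)),
                        start = list(Cinf = C0, k = k0),
                        lower = c(Cinf = 0, k = 0))
    },
    error = function(e) {
      abort(paste0("First-order fit failed to converge: ",
                   conditionMessage(e)))
    })
  cf <- coef(fit)
  structure(
    list(k = cf[["k"]], C_inf = cf[["Cinf"]],
         offset = if (offset) cf[["c0"]] else 0,
         residual_rms = sqrt(mean(stats::residuals(fit)^2)),
         fit = fit),
    class = "first_order_fit")
}

#' @export
print.first_order_fit <- function(x, ...) {
  cat(sprintf("<first_order_fit> k = %.4g 1/s, plateau = %.4g (rms %.2g)\n",
              x$k, x$C_inf, x$residual_rms))
  invisible(x)
}

#' @export
tidy.first_order_fit <- function(x, ...) {
  tibble::tibble(term = c("k", "C_inf"),
                 estimate = c(x$k, x$C_inf))
}

#' @export
glance.first_order_fit <- function(x, ...) {
  tibble::tibble(k = x$k, C_inf = x$C_inf, offset = x$offset,
                 residual_rms = x$residual_rms)
}

#' Sphere radius from cell volume
#'
#' @param volume Cell volume.
#' @param unit `"m3"` (default) or `"pL"` (1 pL = 1e-15 m^3).
#' @return Radius in metres: \eqn{r = (3V/4\pi)^{1/3}}.
#' @examples
#' radius_from_volume(2, "pL") # ~7.816e-6 m
#' @export
radius_from_volume <- function(volume, unit = c("m3", "pL")) {
  unit <- match.arg(unit)
  if (any(volume <= 0)) abort("`volume` must be positive.")
  v <- if (unit == "pL") volume * 1e-15 else volume
  (3 * v / (4 * pi))^(1 / 3)
}

#' Spherical-cell conversion between uptake rate and permeability
#'
#' For a spherical cell of radius \eqn{r}, a first-order uptake rate
#' constant \eqn{k} corresponds to the membrane permeability
#' \deqn{P = k r / 3,} and conversely \eqn{k = 3P/r}. The two
#' functions are exact inverses.
#'
#' @param k First-order rate constant, 1/s.
#' @param radius Cell radius, m.
#' @param P Permeability, m/s.
#' @return Permeability in m/s, or rate constant in 1/s.
#' @examples
#' permeability_from_kinetics(2.52e-5, radius_from_volume(2, "pL"))
#' @export
permeability_from_kinetics <- function(k, radius) {
  if (any(k <= 0) || any(radius <= 0)) {
    abort("`k` and `radius` must be positive.")
  }
  k * radius / 3
}

#' @rdname permeability_from_kinetics
#' @export
kinetic_constant <- function(P, radius) {
  if (any(P <= 0) || any(radius <= 0)) {
    abort("`P` and `radius` must be positive.")
  }
  3 * P / radius
}

#' Literature resistances and permeabilities of cisplatin
#'
#' Reported total permeation resistances and permeabilities of
#' cisplatin for five model membranes (a pure DOPC bilayer, asymmetric
#' normal plasma-membrane models at 0/15/33% cholesterol, and a
#' symmetric cancer-membrane model at 33% cholesterol), with their
#' quoted uncertainties. Used as worked-example input for consistency
#' checks: the printed permeability equals the reciprocal of the
#' printed resistance.
#'
#' @return A tibble with columns `system`, `cholesterol_pct`,
#'   `R_total` (s/m), `sigma_R`, `P` (m/s), `sigma_P`.
#' @export
cisplatin_resistance_table <- function() {
  tibble::tibble(
    system = c("DOPC", "Normal", "Normal", "Normal", "Cancer"),
    cholesterol_pct = c(0, 0, 15, 33, 33),
    R_total = c(4.5e6, 1.15e11, 2.08e11, 5.75e11, 6.3e12),
    sigma_R = c(0.1e6, 0.04e11, 0.04e11, 0.08e11, 0.2e12),
    P = c(2.2e-7, 8.7e-12, 4.8e-12, 1.74e-12, 1.59e-13),
    sigma_P = c(0.05e-7, 0.3e-12, 0.1e-12, 0.03e-12, 0.06e-13)
  )
}
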