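#' @export
autoplot.pmf_profile <- function(object, ...) {
  df <- dplyr::filter(object, is.finite(.data$W))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$W)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$W - .data$sigma_W,
                                      ymax = .data$W + .data$sigma_W),
                         alpha = 0.25, na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (nm)", y = "W(z) (kJ/mol)",
                  title = "Potential of mean force") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.diffusion_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$D)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$D - .data$sigma_D,
                                      ymax = .data$D + .data$sigma_D),
                         alpha = 0.25, na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (nm)", y = expression(D(z) ~ (nm^2 / ps)),
                  title = "Local diffusion coefficient") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.resistance_profile <- function(object, ...) {
  df <- dplyr::filter(object, is.finite(.data$r), .data$r > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$r)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "z (nm)", y = expression(R(z) ~ (ps / nm^2)),
                  title = "Local permeation resistance") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.perm_fit <- function(object,
                              which = c("pmf", "diffusion",
                                        "resistance"), ...) {
  which <- match.arg(which)
  switch(which,
         pmf = autoplot(object$pmf),
         diffusion = autoplot(object$dprof),
         resistance = autoplot(object$rprof))
}

#' @export
autoplot.uptake_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (s)", y = "uptake (fraction of plateau)") +
    ggplot2::theme_minimal()
}
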