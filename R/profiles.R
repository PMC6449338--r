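#' Number-density profile along the membrane normal
#'
#' Histograms per-particle z positions over frames and converts counts
#' to number densities: mean count per frame per bin divided by the
#' bin volume (`bin_width` times the lateral cross-section area). The
#' density integrates back to the mean particle count per frame.
#'
#' @param frames A data frame with columns `frame`, `species`,
#'   `leaflet`, `z` (nm), e.g. from [simulate_membrane_frames()] or
#'   [read_particle_frames()].
#' @param species Optional character vector of species labels to keep;
#'   unknown labels are an error.
#' @param bin_width Bin width along z, nm.
#' @param area Lateral cross-section area of the patch, nm^2; taken
#'   from the `area` attribute of `frames` if absent.
#' @return A tibble with columns `species`, `z` (bin centre) and
#'   `density` (nm^-3).
#' @export
density_profile <- function(frames, species = NULL, bin_width = 0.05,
                            area = NULL) {
  stopifnot(is.data.frame(frames),
            all(c("frame", "species", "z") %in% names(frames)))
  area <- area %||% attr(frames, "area")
  if (is.null(area) || area <= 0) {
    abort("Provide a positive `area` (nm^2), or frames with an `area` attribute.")
  }
  if (!is.null(species)) {
    unknown <- setdiff(species, unique(frames$species))
    if (length(unknown)) {
      abort(paste0("Unknown species label(s): ",
                   paste(unknown, collapse = ", ")))
    }
    frames <- dplyr::filter(frames, .data$species %in% !!species)
  }
  n_frames <- dplyr::n_distinct(frames$frame)
  r <- range(frames$z)
  lo <- floor(r[1] / bin_width) * bin_width
  n <- ceiling((r[2] - lo) / bin_width + 1e-9)
  edges <- lo + bin_width * (0:n)
  mids <- (head(edges, -1) + tail(edges, -1)) / 2
  frames |>
    dplyr::group_by(.data$species) |>
    dplyr::group_modify(function(d, key) {
      idx <- findInterval(d$z, edges, rightmost.closed = TRUE)
      tibble::tibble(
        z = mids,
        density = tabulate(idx, nbins = length(mids)) /
          (n_frames * bin_width * area))
    }) |>
    dplyr::ungroup()
}

#' Head-group peak position of a density profile
#'
#' Returns the absolute distance from the membrane centre to the
#' maximum of the density profile on the requested side, refined by a
#' three-point parabolic fit around the top bin.
#'
#' @param profile A tibble with columns `z` and `density` (one
#'   species).
#' @param leaflet `"outer"` (z > 0) or `"inner"` (z < 0).
#' @return Peak position |z|, nm.
#' @export
headgroup_peak <- function(profile, leaflet = c("outer", "inner")) {
  leaflet <- match.arg(leaflet)
  stopifnot(all(c("z", "density") %in% names(profile)))
  side <- if (leaflet == "outer") profile$z > 0 else profile$z < 0
  d <- profile[side, ]
  d <- d[order(d$z), ]
  if (nrow(d) < 3) abort("Too few bins on the requested side.")
  i <- which.max(d$density)
  if (i == 1 || i == nrow(d)) {
    abort(sprintf("No interior density maximum on the %s side.", leaflet))
  }
  y1 <- d$density[i - 1]; y2 <- d$density[i]; y3 <- d$density[i + 1]
  dz <- d$z[i + 1] - d$z[i]
  denom <- y1 - 2 * y2 + y3
  delta <- if (denom == 0) 0 else 0.5 * (y1 - y3) / denom * dz
  abs(d$z[i] + delta)
}

#' Linear regression of membrane thickness on cholesterol content
#'
#' Ordinary least squares of the head-group peak distance on
#' cholesterol mole percentage, with the Pearson correlation of the
#' fit. Membrane thickening with cholesterol (the condensing effect)
#' shows up as a positive slope with near-unit correlation.
#'
#' @param points A data frame with columns `cholesterol_pct` (0-100)
#'   and `thickness` (|z| of the head-group peak, nm); at least 3 rows.
#' @return A one-row tibble: `slope` (nm per mol%), `intercept` (nm),
#'   `correlation`.
#' @export
thickness_regression <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("cholesterol_pct", "thickness") %in% names(points)))
  if (nrow(points) < 3) abort("Need at least 3 points.")
  if (any(points$cholesterol_pct < 0 | points$cholesterol_pct > 100)) {
    abort("`cholesterol_pct` must lie in [0, 100].")
  }
  if (sd(points$cholesterol_pct) == 0) {
    abort("Degenerate regression: cholesterol content has no variance.")
  }
  fit <- lm(thickness ~ cholesterol_pct, data = points)
  tibble::tibble(
    slope = coef(fit)[["cholesterol_pct"]],
    intercept = coef(fit)[["(Intercept)"]],
    correlation = cor(points$cholesterol_pct, points$thickness))
}

#' Acyl-chain order parameter per carbon
#'
#' Second-Legendre order parameter
#' \eqn{S = \langle 3\cos^2\theta - 1 \rangle / 2} of bond orientations
#' relative to the bilayer normal, per chain carbon. Bounded in
#' [-0.5, 1]; no sign negation is applied.
#'
#' @param samples A data frame with columns `carbon` (index) and
#'   `cos_theta` (in [-1, 1]).
#' @return A tibble with columns `carbon`, `S`, `n`.
#' @export
order_parameter <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("carbon", "cos_theta") %in% names(samples)))
  if (any(abs(samples$cos_theta) > 1)) {
    abort("`cos_theta` values must lie in [-1, 1].")
  }
  samples |>
    dplyr::group_by(.data$carbon) |>
    dplyr::summarise(S = mean((3 * .data$cos_theta^2 - 1) / 2),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$carbon)
}

#' Synthetic bilayer particle frames
#'
#' Places head-group, tail and cholesterol z positions from declared
#' Gaussian mixtures, one draw per frame, so the structural observables
#' (density profiles, head-group peaks, order parameters) are testable
#' without MD trajectories. Head groups sit at the declared +/- peak
#' positions, tails near the centre, cholesterol in between.
#'
#' @param n_frames Number of frames.
#' @param n_lipids Lipids per leaflet per frame.
#' @param peak_outer,peak_inner Head-group peak distances, nm.
#' @param head_sd,tail_sd,chol_sd Spread of each Gaussian, nm.
#' @param cholesterol_fraction Cholesterol molecules per lipid.
#' @param area Lateral cross-section area, nm^2 (stored as attribute).
#' @param seed Optional integer seed.
#' @return A tibble with columns `frame`, `species` (`"headgroup"`,
#'   `"tail"`, `"cholesterol"`), `leaflet` (`"outer"`/`"inner"`) and
#'   `z` (nm), with attribute `area`.
#' @export
simulate_membrane_frames <- function(n_frames = 20, n_lipids = 100,
                                     peak_outer = 2.27,
                                     peak_inner = 2.05,
                                     head_sd = 0.18, tail_sd = 0.45,
                                     chol_sd = 0.35,
                                     cholesterol_fraction = 0.33,
                                     area = 36, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  one_frame <- function(fr) {
    n_chol <- round(n_lipids * cholesterol_fraction)
    mk <- function(species, leaflet, mu, s, n) {
      tibble::tibble(frame = fr, species = species, leaflet = leaflet,
                     z = rnorm(n, mu, s))
    }
    dplyr::bind_rows(
      mk("headgroup", "outer", peak_outer, head_sd, n_lipids),
      mk("headgroup", "inner", -peak_inner, head_sd, n_lipids),
      mk("tail", "outer", 0.9, tail_sd, n_lipids),
      mk("tail", "inner", -0.9, tail_sd, n_lipids),
      mk("cholesterol", "outer", 1.2, chol_sd, n_chol),
      mk("cholesterol", "inner", -1.2, chol_sd, n_chol))
  }
  out <- purrr::map_dfr(seq_len(n_frames), one_frame)
  attr(out, "area") <- area
  out
}

#' Read particle frames from CSV
#'
#' Reads a plain CSV with columns `frame`, `species`, `leaflet`, `z`
#' as produced by trajectory post-processing tools.
#'
#' @param path CSV file path.
#' @param area Lateral cross-section area, nm^2 (stored as attribute).
#' @return A tibble of frames suitable for [density_profile()].
#' @export
read_particle_frames <- function(path, area = NULL) {
  df <- tibble::as_tibble(read.table(path, header = TRUE, sep = ",",
                                     stringsAsFactors = FALSE))
  need <- c("frame", "species", "leaflet", "z")
  if (!all(need %in% names(df))) {
    abort(paste0("CSV must contain columns ",
                 paste(need, collapse = ", "), "."))
  }
  if (!is.null(area)) attr(df, "area") <- area
  df
}
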