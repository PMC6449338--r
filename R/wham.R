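#' Bin umbrella windows into histograms on a common grid
#'
#' Converts a `window_set` into per-window position histograms sharing
#' one uniform set of bin edges, the form consumed by [solve_wham()]
#' and [bootstrap_pmf()]. One histogram is produced per
#' (centre, replicate) pair.
#'
#' @param windows A `window_set` tibble (see [simulate_window()] or
#'   [read_pull_xvg()]).
#' @param bin_width Bin width, nm. The 0.02 nm default resolves a
#'   0.1 nm window ladder with five bins per spacing without starving
#'   counts.
#' @param edges Optional explicit uniform bin edges, nm. When given,
#'   samples outside the edges are an error unless `clip = TRUE`.
#' @param clip Drop samples outside `edges` instead of failing.
#' @return A `window_histograms` tibble with one row per
#'   (centre, replicate, bin): columns `center`, `spring`, `replicate`,
#'   `z` (bin centre), `count`; attributes `edges` and `bin_width`.
#' @export
histogram_windows <- function(windows, bin_width = 0.02, edges = NULL,
                              clip = FALSE) {
  check_window_set(windows)
  if (is.null(edges)) {
    r <- range(windows$position)
    lo <- floor(r[1] / bin_width) * bin_width
    n <- ceiling((r[2] - lo) / bin_width + 1e-9)
    edges <- lo + bin_width * (0:n)
  } else {
    dz <- diff(edges)
    if (length(edges) < 2 || any(dz <= 0) ||
        max(abs(dz - dz[1])) > 1e-9 * dz[1]) {
      abort("`edges` must be strictly increasing and uniform.")
    }
    bin_width <- dz[1]
  }
  mids <- (head(edges, -1) + tail(edges, -1)) / 2
  out <- windows |>
    dplyr::group_by(.data$center, .data$spring, .data$replicate) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 1) abort("Empty umbrella window.")
      idx <- findInterval(d$position, edges, rightmost.closed = TRUE)
      outside <- idx < 1 | idx > length(mids)
      if (any(outside)) {
        if (!clip) {
          abort(sprintf(
            "Window (center %g, replicate %s) has %d samples outside the bin edges; pass clip = TRUE or widen `edges`.",
            key$center, key$replicate, sum(outside)))
        }
        idx <- idx[!outside]
      }
      tibble::tibble(z = mids,
                     count = tabulate(idx, nbins = length(mids)))
    }) |>
    dplyr::ungroup()
  tibble::new_tibble(out, edges = edges, bin_width = bin_width,
                     class = c("window_histograms", "tbl_df", "tbl",
                               "data.frame"))
}

subset_histograms <- function(histograms, rows) {
  df <- as.data.frame(histograms)[rows, , drop = FALSE]
  rownames(df) <- NULL
  tibble::new_tibble(
    df,
    edges = attr(histograms, "edges"),
    bin_width = attr(histograms, "bin_width"),
    class = c("window_histograms", "tbl_df", "tbl", "data.frame"))
}

check_window_set <- function(windows) {
  need <- c("center", "spring", "replicate", "position")
  if (!is.data.frame(windows) || !all(need %in% names(windows))) {
    abort(paste0("`windows` must contain columns ",
                 paste(need, collapse = ", "), "."))
  }
  invisible(windows)
}

# Internal matrix view of a window_histograms tibble:
# counts [H x B], N [H], bias energies u [H x B] (kJ/mol), meta per row.
hist_matrices <- function(histograms) {
  edges <- attr(histograms, "edges")
  mids <- (head(edges, -1) + tail(edges, -1)) / 2
  meta <- dplyr::distinct(histograms, .data$center, .data$spring,
                          .data$replicate)
  wide <- histograms |>
    dplyr::arrange(match(paste(.data$center, .data$replicate),
                         paste(meta$center, meta$replicate)), .data$z)
  counts <- matrix(wide$count, nrow = nrow(meta), ncol = length(mids),
                   byrow = TRUE)
  u <- matrix(0, nrow = nrow(meta), ncol = length(mids))
  for (i in seq_len(nrow(meta))) {
    u[i, ] <- meta$spring[i] / 2 * (mids - meta$center[i])^2
  }
  list(counts = counts, N = rowSums(counts), u = u, z = mids, meta = meta)
}

# Self-consistent WHAM iteration on matrices. `rho` is kept normalised;
# the per-window free energies are gauge-fixed to f[1] = 0.
wham_core <- function(counts, N, u, RT, tol, max_iter, f_init = NULL) {
  H <- nrow(counts); B <- ncol(counts)
  expb <- exp(-u / RT)
  tot <- colSums(counts)
  f <- f_init %||% numeric(H)
  f <- f - f[1]
  iter <- 0L
  repeat {
    wf <- N * exp(f / RT)
    denom <- as.numeric(crossprod(expb, wf))
    rho <- ifelse(denom > 0, tot / denom, 0)
    s <- sum(rho)
    if (s <= 0) abort("WHAM: all bins empty.")
    rho <- rho / s
    f_new <- -RT * log(as.numeric(expb %*% rho))
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f))
    f <- f_new
    iter <- iter + 1L
    if (resid <= tol) break
    if (iter >= max_iter) {
      abort(sprintf(
        "WHAM did not converge in %d iterations (residual %.3g kJ/mol).",
        max_iter, resid))
    }
  }
  W <- ifelse(tot > 0, -RT * log(rho), NA_real_)
  list(rho = rho, W = W, f = f, iterations = iter, residual = resid)
}

new_pmf <- function(z, W, sigma_W = rep(NA_real_, length(z)),
                    reference = "none") {
  tibble::new_tibble(
    tibble::tibble(z = z, W = W, sigma_W = sigma_W),
    reference = reference,
    class = c("pmf_profile", "tbl_df", "tbl", "data.frame"))
}

#' Solve the WHAM equations for a set of biased histograms
#'
#' Finds the self-consistent solution of the weighted histogram
#' analysis method,
#' \deqn{\rho(z_b) = \frac{\sum_i n_i(z_b)}
#'       {\sum_i N_i e^{(f_i - u_i(z_b))/RT}}, \qquad
#'       f_i = -RT \ln \sum_b \rho(z_b) e^{-u_i(z_b)/RT},}
#' with harmonic biases \eqn{u_i(z) = k_{u,i}(z - z_{0,i})^2/2}, and
#' returns the unbiased potential of mean force
#' \eqn{W(z_b) = -RT \ln \rho(z_b)}. Iteration stops when the largest
#' change of any \eqn{f_i} falls below `tol`. Bins with zero aggregate
#' counts are reported as `NA`, never interpolated. The gauge is fixed
#' by \eqn{f_1 = 0}; the returned PMF is unreferenced (see
#' [reference_pmf()]).
#'
#' @param histograms A `window_histograms` tibble from
#'   [histogram_windows()] (all sharing the same edges by
#'   construction).
#' @param thermo A [thermo_state()].
#' @param tol Convergence tolerance on the window free energies,
#'   kJ/mol.
#' @param max_iter Iteration cap; reaching it is an error that carries
#'   the residual.
#' @param f_init Optional warm-start vector of window free energies.
#' @return A `wham_fit`: list with elements `pmf` (a `pmf_profile`
#'   tibble: `z`, `W`, `sigma_W`), `f` (tibble of per-window free
#'   energies), `iterations`, `residual`.
#' @export
solve_wham <- function(histograms, thermo = thermo_state(), tol = 1e-6,
                       max_iter = 1e5, f_init = NULL) {
  stopifnot(inherits(histograms, "window_histograms"))
  thermo <- as_thermo(thermo)
  m <- hist_matrices(histograms)
  sol <- wham_core(m$counts, m$N, m$u, thermo$RT, tol, max_iter, f_init)
  structure(
    list(pmf = new_pmf(m$z, sol$W),
         f = tibble::tibble(center = m$meta$center,
                            replicate = m$meta$replicate,
                            spring = m$meta$spring, f = sol$f),
         iterations = sol$iterations, residual = sol$residual,
         temperature = thermo$temperature),
    class = "wham_fit")
}

#' @export
print.wham_fit <- function(x, ...) {
  cat(sprintf(
    "<wham_fit> %d windows, %d bins, %d iterations (residual %.2g kJ/mol)\n",
    nrow(x$f), nrow(x$pmf), x$iterations, x$residual))
  invisible(x)
}

#' @export
tidy.wham_fit <- function(x, ...) x$pmf

#' @export
glance.wham_fit <- function(x, ...) {
  tibble::tibble(n_windows = nrow(x$f), n_bins = nrow(x$pmf),
                 iterations = x$iterations, residual = x$residual,
                 temperature = x$temperature)
}

#' Anchor a PMF to a reference region
#'
#' Shifts the profile so that the mean of \eqn{W} over the given region
#' is zero — conventionally a stretch of bulk water where the free
#' energy of the permeant is flat. Uncertainties are unchanged, and the
#' operation is idempotent.
#'
#' @param pmf A `pmf_profile` tibble.
#' @param region Length-2 numeric interval in nm; must overlap at least
#'   two bins with defined `W`.
#' @return The shifted `pmf_profile`.
#' @export
reference_pmf <- function(pmf, region = c(2.0, 2.3)) {
  stopifnot(inherits(pmf, "pmf_profile"))
  if (length(region) != 2 || !(region[1] < region[2])) {
    abort("`region` must be an increasing length-2 interval (nm).")
  }
  idx <- pmf$z >= region[1] & pmf$z <= region[2] & is.finite(pmf$W)
  if (sum(idx) < 2) {
    abort("Reference region overlaps fewer than two defined bins.")
  }
  new_pmf(pmf$z, pmf$W - mean(pmf$W[idx]), pmf$sigma_W,
          reference = paste0("mean-zero [", region[1], ", ", region[2],
                             "] nm"))
}

#' Average per-replicate PMFs
#'
#' Pointwise mean of several PMFs on the same grid and reference
#' convention (one per ligand/replicate). The combined uncertainty adds
#' the pointwise standard deviation across replicates in quadrature
#' with the mean of the per-profile variances.
#'
#' @param pmfs A list of `pmf_profile` tibbles.
#' @return A single `pmf_profile`.
#' @export
average_pmfs <- function(pmfs) {
  stopifnot(length(pmfs) >= 1,
            all(vapply(pmfs, inherits, TRUE, "pmf_profile")))
  z <- pmfs[[1]]$z
  refc <- attr(pmfs[[1]], "reference")
  for (p in pmfs[-1]) {
    if (length(p$z) != length(z) || max(abs(p$z - z)) > 1e-9) {
      abort("All PMFs must share the same grid.")
    }
    if (!identical(attr(p, "reference"), refc)) {
      abort("All PMFs must share the same reference convention.")
    }
  }
  Wm <- vapply(pmfs, function(p) p$W, numeric(length(z)))
  Sm <- vapply(pmfs, function(p) p$sigma_W, numeric(length(z)))
  Wm <- matrix(Wm, nrow = length(z)); Sm <- matrix(Sm, nrow = length(z))
  scatter <- if (ncol(Wm) > 1) apply(Wm, 1, sd) else rep(0, length(z))
  Sm[is.na(Sm)] <- 0
  sigma <- sqrt(scatter^2 + rowMeans(Sm^2))
  new_pmf(z, rowMeans(Wm), sigma, reference = refc)
}

#' Histogram-level bootstrap uncertainty of the PMF
#'
#' Treats complete window histograms as independent data points: each
#' bootstrap draw selects, at every window centre, one whole histogram
#' with replacement from the replicates at that centre, re-solves WHAM
#' and re-references the profile. The per-bin standard deviation over
#' the draws is the bootstrap uncertainty. Centres with a single
#' replicate fall back to multinomial resampling of that histogram's
#' counts (with a warning), so every centre stays covered in every
#' draw.
#'
#' @inheritParams solve_wham
#' @param n_boot Number of bootstrap draws (default 400).
#' @param seed Optional integer seed.
#' @param reference_region Passed to [reference_pmf()] for each draw.
#' @return A tibble with columns `z` and `sigma_W` (kJ/mol); attribute
#'   `n_boot`.
#' @export
bootstrap_pmf <- function(histograms, thermo = thermo_state(),
                          n_boot = 400, seed = NULL,
                          reference_region = c(2.0, 2.3), tol = 1e-6,
                          max_iter = 1e5) {
  stopifnot(inherits(histograms, "window_histograms"))
  thermo <- as_thermo(thermo)
  if (n_boot < 2) abort("`n_boot` must be at least 2.")
  if (!is.null(seed)) set.seed(seed)
  m <- hist_matrices(histograms)
  centers <- sort(unique(m$meta$center))
  by_center <- lapply(centers, function(c0) which(m$meta$center == c0))
  if (any(lengths(by_center) < 2)) {
    warn(paste0("Some window centres have a single replicate; falling ",
                "back to multinomial resampling of their counts."))
  }
  # Bias matrix of a one-histogram-per-centre draw is fixed: take the
  # first replicate's bias at each centre (replicates share biases).
  rows1 <- vapply(by_center, `[`, integer(1), 1)
  u_draw <- m$u[rows1, , drop = FALSE]
  W_draws <- matrix(NA_real_, nrow = length(m$z), ncol = n_boot)
  f_prev <- NULL
  for (b in seq_len(n_boot)) {
    counts <- matrix(0, nrow = length(centers), ncol = length(m$z))
    for (ci in seq_along(centers)) {
      rows <- by_center[[ci]]
      if (length(rows) >= 2) {
        counts[ci, ] <- m$counts[sample(rows, 1), ]
      } else {
        n_i <- m$N[rows]
        p <- m$counts[rows, ] / n_i
        counts[ci, ] <- as.numeric(stats::rmultinom(1, n_i, p))
      }
    }
    sol <- wham_core(counts, rowSums(counts), u_draw, thermo$RT, tol,
                     max_iter, f_init = f_prev)
    f_prev <- sol$f
    prof <- reference_pmf(new_pmf(m$z, sol$W), reference_region)
    W_draws[, b] <- prof$W
  }
  sigma <- apply(W_draws, 1, function(w) {
    w <- w[is.finite(w)]
    if (length(w) >= 2) sd(w) else NA_real_
  })
  out <- tibble::tibble(z = m$z, sigma_W = sigma)
  attr(out, "n_boot") <- n_boot
  out
}

#' Potential of mean force from umbrella windows
#'
#' End-to-end PMF reconstruction: histograms the windows on a common
#' grid, solves WHAM, references the profile to a bulk-water region and
#' attaches histogram-bootstrap uncertainties. By default each
#' replicate (ligand) is solved separately and the per-replicate
#' profiles are averaged; `mode = "pooled"` solves a single WHAM over
#' all histograms instead.
#'
#' @inheritParams histogram_windows
#' @inheritParams bootstrap_pmf
#' @param mode `"replicate-average"` (default) or `"pooled"`.
#' @param bootstrap Attach bootstrap `sigma_W` (default TRUE; when
#'   FALSE the sigma from replicate scatter is kept).
#' @return A referenced `pmf_profile` tibble (`z`, `W`, `sigma_W`).
#' @examples
#' \donttest{
#' w <- simulate_windows(membrane_model(), -0.5, 0.5, n_replicates = 2,
#'                       config = langevin_config(n_steps = 5000))
#' pmf_wham(w, n_boot = 20, reference_region = c(0.3, 0.5))
#' }
#' @export
pmf_wham <- function(windows, thermo = thermo_state(), bin_width = 0.02,
                     reference_region = c(2.0, 2.3),
                     mode = c("replicate-average", "pooled"),
                     bootstrap = TRUE, n_boot = 400, seed = NULL,
                     tol = 1e-6, max_iter = 1e5) {
  mode <- match.arg(mode)
  hist <- histogram_windows(windows, bin_width = bin_width)
  if (mode == "replicate-average") {
    reps <- sort(unique(hist$replicate))
    profs <- lapply(reps, function(r) {
      h <- subset_histograms(hist, hist$replicate == r)
      reference_pmf(solve_wham(h, thermo, tol, max_iter)$pmf,
                    reference_region)
    })
    pmf <- average_pmfs(profs)
  } else {
    pmf <- reference_pmf(solve_wham(hist, thermo, tol, max_iter)$pmf,
                         reference_region)
  }
  if (bootstrap) {
    bs <- bootstrap_pmf(hist, thermo, n_boot = n_boot, seed = seed,
                        reference_region = reference_region, tol = tol,
                        max_iter = max_iter)
    pmf$sigma_W <- bs$sigma_W
  }
  pmf
}
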