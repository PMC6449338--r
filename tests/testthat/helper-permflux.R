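# Shared fixtures and independent oracles for the test suite.

# A window_set built directly from vectors (bypasses the simulator).
make_window <- function(position, force = NULL, center = 0, spring = 1000,
                        replicate = 1L, dt = 0.1) {
  n <- length(position)
  tibble::new_tibble(
    tibble::tibble(
      center = rep(center, n), spring = rep(spring, n),
      replicate = rep(as.integer(replicate), n),
      time = dt * seq_len(n), position = position,
      force = if (is.null(force)) rep(NA_real_, n) else force),
    class = c("window_set", "tbl_df", "tbl", "data.frame"))
}

# window_histograms from an explicit counts matrix (H x B).
make_histograms <- function(counts, centers, springs, edges) {
  mids <- (head(edges, -1) + tail(edges, -1)) / 2
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    tibble::tibble(center = centers[i], spring = springs[i],
                   replicate = i, z = mids, count = counts[i, ])
  })
  tibble::new_tibble(
    dplyr::bind_rows(rows),
    edges = edges, bin_width = diff(edges)[1],
    class = c("window_histograms", "tbl_df", "tbl", "data.frame"))
}

# Independent WHAM oracle: direct BFGS minimisation of the negative
# log-likelihood over per-bin log-densities (never touches the
# package's fixed-point iteration).
oracle_wham_w <- function(counts, centers, springs, edges, RT) {
  mids <- (head(edges, -1) + tail(edges, -1)) / 2
  u <- t(vapply(seq_along(centers),
                function(i) springs[i] / 2 * (mids - centers[i])^2,
                numeric(length(mids))))
  tot <- colSums(counts)
  N <- rowSums(counts)
  keep <- tot > 0
  nll <- function(g) {
    gg <- rep(-Inf, length(mids)); gg[keep] <- g
    Z <- rowSums(exp(sweep(-u / RT, 2, gg, "+")))
    -sum(tot[keep] * g) + sum(N * log(Z))
  }
  g0 <- log(tot[keep] / sum(tot))
  opt <- stats::optim(g0, nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  W <- rep(NA_real_, length(mids))
  W[keep] <- -RT * opt$par
  W - mean(W[keep])
}
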