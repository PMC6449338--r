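test_that("histograms conserve samples and carry bias parameters", {
  w <- make_window(c(rep(0.05, 60), rep(0.11, 40)), center = 0.1)
  h <- histogram_windows(w, bin_width = 0.02)
  expect_equal(sum(h$count), 100)
  expect_identical(unique(h$center), 0.1)
  expect_identical(unique(h$spring), 1000)
  one <- make_window(rep(0.05, 30))
  h1 <- histogram_windows(one, bin_width = 0.5)
  expect_equal(sort(h1$count, decreasing = TRUE)[1], 30L)
  expect_equal(sum(h1$count > 0), 1)
})

test_that("samples outside explicit edges fail loudly unless clipped", {
  w <- make_window(c(-0.5, 0, 0.5), center = 0)
  edges <- seq(-0.2, 0.2, by = 0.1)
  expect_error(histogram_windows(w, edges = edges),
               "outside the bin edges")
  expect_error(histogram_windows(w, edges = edges), "center 0")
  h <- histogram_windows(w, edges = edges, clip = TRUE)
  expect_equal(sum(h$count), 1)
  expect_error(histogram_windows(w, edges = c(0, 0.1, 0.15)), "uniform")
})

test_that("WHAM degenerates to Boltzmann inversion for a single unbiased window", {
  th <- thermo_state()
  set.seed(31)
  pos <- rnorm(20000, 0, 0.2)
  w <- make_window(pos, center = 0, spring = 1e-9)
  h <- histogram_windows(w, bin_width = 0.05)
  sol <- solve_wham(h, th)
  counts <- h$count
  direct <- ifelse(counts > 0, -th$RT * log(counts / sum(counts)),
                   NA_real_)
  keep <- is.finite(sol$pmf$W)
  expect_equal(sol$pmf$W[keep] - mean(sol$pmf$W[keep]),
               direct[keep] - mean(direct[keep]), tolerance = 1e-6)
})

test_that("WHAM is invariant under histogram replication and bias offsets", {
  th <- thermo_state()
  edges <- seq(-0.3, 0.3, by = 0.04)
  set.seed(7)
  counts <- matrix(rpois(3 * 15, 40), nrow = 3)
  centers <- c(-0.1, 0, 0.1)
  springs <- rep(500, 3)
  h1 <- make_histograms(counts, centers, springs, edges)
  h2 <- make_histograms(rbind(counts, counts), rep(centers, 2),
                        rep(springs, 2), edges)
  W1 <- reference_pmf(solve_wham(h1, th)$pmf, c(-0.1, 0.1))
  W2 <- reference_pmf(solve_wham(h2, th)$pmf, c(-0.1, 0.1))
  expect_equal(W1$W, W2$W, tolerance = 1e-6)
  # adding a common constant to every bias shifts f but not W
  m <- permflux:::hist_matrices(h1)
  s0 <- permflux:::wham_core(m$counts, m$N, m$u, th$RT, 1e-10, 1e5)
  s1 <- permflux:::wham_core(m$counts, m$N, m$u + 3.7, th$RT, 1e-10, 1e5)
  k0 <- is.finite(s0$W)
  expect_equal(s0$W[k0] - mean(s0$W[k0]), s1$W[k0] - mean(s1$W[k0]),
               tolerance = 1e-6)
})

test_that("fixed point agrees with direct likelihood-minimisation oracle", {
  th <- thermo_state()
  edges <- seq(-0.35, 0.35, length.out = 15)
  centers <- c(-0.15, 0, 0.15)
  springs <- rep(400, 3)
  mids <- (head(edges, -1) + tail(edges, -1)) / 2
  set.seed(11)
  counts <- t(vapply(seq_along(centers), function(i) {
    p <- exp(-(8 * mids^2 + springs[i] / 2 * (mids - centers[i])^2) /
               th$RT)
    as.numeric(rmultinom(1, 500, p / sum(p)))
  }, numeric(length(mids))))
  h <- make_histograms(counts, centers, springs, edges)
  sol <- solve_wham(h, th, tol = 1e-10)
  W_oracle <- oracle_wham_w(counts, centers, springs, edges, th$RT)
  keep <- is.finite(sol$pmf$W)
  expect_equal(sol$pmf$W[keep] - mean(sol$pmf$W[keep]),
               W_oracle[keep], tolerance = 1e-4)
  expect_lte(sol$residual, 1e-10)
})

test_that("empty bins are NA and convergence failure is reported", {
  th <- thermo_state()
  edges <- seq(-0.2, 0.2, by = 0.05)
  counts <- matrix(c(0, 5, 20, 5, 0, 0, 0, 0), nrow = 1)
  h <- make_histograms(counts, 0, 200, edges)
  sol <- solve_wham(h, th)
  expect_true(all(is.na(sol$pmf$W[counts[1, ] == 0])))
  expect_true(all(is.finite(sol$pmf$W[counts[1, ] > 0])))
  counts2 <- matrix(rpois(2 * 8, 30), nrow = 2)
  h2 <- make_histograms(counts2, c(-0.1, 0.1), c(500, 500), edges)
  expect_error(solve_wham(h2, th, max_iter = 2), "converge")
})

test_that("referencing zeroes the declared region, idempotently", {
  p <- permflux:::new_pmf(seq(0, 2.3, by = 0.1),
                          W = rep(5, 24))
  r <- reference_pmf(p, c(2.0, 2.3))
  expect_equal(r$W, rep(0, 24))
  expect_equal(reference_pmf(r, c(2.0, 2.3))$W, r$W)
  asym <- permflux:::new_pmf(seq(0, 2.3, by = 0.1), W = seq(0, 2.3, by = 0.1))
  ra <- reference_pmf(asym, c(2.0, 2.3))
  idx <- asym$z >= 2.0 & asym$z <= 2.3
  expect_equal(ra$W, asym$W - mean(asym$W[idx]))
  expect_error(reference_pmf(p, c(5, 6)), "fewer than two")
})

test_that("averaging PMFs pools means and scatter correctly", {
  z <- seq(-1, 1, by = 0.1)
  p1 <- permflux:::new_pmf(z, W = z^2, sigma_W = rep(0.1, length(z)))
  p2 <- permflux:::new_pmf(z, W = z^2, sigma_W = rep(0.1, length(z)))
  avg <- average_pmfs(list(p1, p2))
  expect_equal(avg$W, z^2)
  expect_equal(avg$sigma_W, rep(0.1, length(z))) # scatter term zero
  pneg <- permflux:::new_pmf(z, W = -z^2, sigma_W = rep(0, length(z)))
  ppos <- permflux:::new_pmf(z, W = z^2, sigma_W = rep(0, length(z)))
  expect_equal(average_pmfs(list(ppos, pneg))$W, rep(0, length(z)))
  pbad <- permflux:::new_pmf(z + 0.01, W = z^2)
  expect_error(average_pmfs(list(p1, pbad)), "same grid")
})

test_that("bootstrap over identical replicates collapses to zero sigma", {
  th <- thermo_state()
  edges <- seq(-0.3, 0.3, by = 0.05)
  set.seed(3)
  base <- matrix(rpois(2 * 12, 50), nrow = 2)
  counts <- rbind(base, base) # two identical replicates per centre
  h <- make_histograms(counts, c(-0.1, 0.1, -0.1, 0.1), rep(300, 4),
                       edges)
  bs <- bootstrap_pmf(h, th, n_boot = 8, seed = 1,
                      reference_region = c(-0.1, 0.1))
  # identical draws agree to the solver tolerance scale
  expect_true(all(bs$sigma_W[is.finite(bs$sigma_W)] < 1e-4))
  expect_error(bootstrap_pmf(h, th, n_boot = 1), "at least 2")
  expect_equal(eval(formals(bootstrap_pmf)$n_boot), 400)
})

test_that("single-replicate centres trigger the multinomial fallback", {
  th <- thermo_state()
  edges <- seq(-0.3, 0.3, by = 0.05)
  set.seed(4)
  counts <- matrix(rpois(2 * 12, 50), nrow = 2)
  h <- make_histograms(counts, c(-0.1, 0.1), rep(300, 2), edges)
  expect_warning(bs <- bootstrap_pmf(h, th, n_boot = 5, seed = 2,
                                     reference_region = c(-0.1, 0.1)),
                 "multinomial")
  expect_true(any(is.finite(bs$sigma_W)))
})

test_that("flat-landscape windows recover a null PMF (reduced run)", {
  th <- thermo_state()
  flat <- membrane_model(bulk_diffusivity = 5e-3,
                         core_diffusivity = 5e-3)
  w <- simulate_windows(flat, -1, 1, spacing = 0.1, n_replicates = 3,
                        config = langevin_config(n_steps = 5e4,
                                                 seed = 17))
  pmf <- pmf_wham(w, th, reference_region = c(0.6, 1), n_boot = 50,
                  seed = 18)
  # judge only the window-covered span; bins beyond the outermost
  # centres are sampled by bias tails alone
  keep <- is.finite(pmf$W) & is.finite(pmf$sigma_W) & pmf$sigma_W > 0 &
    abs(pmf$z) <= 1
  # the true W = 0 should sit inside the +/-2 sigma band for most bins
  covered <- abs(pmf$W[keep]) < 2 * pmf$sigma_W[keep]
  expect_gte(mean(covered), 0.8)
  expect_lt(max(abs(pmf$W[keep])), 1.5) # kJ/mol, sanity scale
})
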