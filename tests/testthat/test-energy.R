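test_that("Fisher-Tippett nll: stationary point, normalization, convexity", {
  for (sigma in c(0.3, 0.5, 1.2)) {
    opt <- stats::optimize(fisher_tippett_nll, c(-10, 10), sigma = sigma,
                           tol = 1e-9)
    expect_equal(opt$minimum, log(2 * sigma^2) / 2, tolerance = 1e-6)
    dens <- function(r) 2 * exp((2 * r - log(2 * sigma^2)) -
                                  exp(2 * r - log(2 * sigma^2)))
    expect_equal(stats::integrate(dens, -30, 10)$value, 1, tolerance = 1e-6)
  }
  r <- seq(-3, 3, by = 0.05)
  nll <- fisher_tippett_nll(r, 0.5)
  expect_true(all(diff(diff(nll)) > 0))     # strictly convex
  expect_error(fisher_tippett_nll(0, 0), "sigma")
  expect_warning(fisher_tippett_nll(400, 0.5), "clipped")
})

test_that("unary energy honours the uncertainty layer and the alpha weight", {
  set.seed(1)
  v <- matrix(stats::rnorm(36), 6)
  none <- observed_envelope(matrix(0, 6, 6), matrix(0L, 6, 6), 0.5)
  up <- unary_params(sigma = 0.5, alpha = 1)
  expect_equal(unary_energy(v, none, up), 0)
  obs <- obs_full(v, 0.5)
  e1 <- unary_energy(v * 0, obs, up)
  up2 <- unary_params(sigma = 0.5, alpha = 2)
  expect_equal(unary_energy(v * 0, obs, up2), 2 * e1)
  # identity H: the per-voxel minimizer is obs - ln(2 sigma^2)/2
  fstar <- obs$values - log(2 * 0.5^2) / 2
  e_min <- unary_energy(fstar, obs, up)
  for (k in 1:5) {
    pert <- fstar + matrix(stats::rnorm(36, sd = 0.1), 6)
    expect_gt(unary_energy(pert, obs, up), e_min)
  }
})

test_that("pair weights follow first-power exponential decay", {
  expect_equal(w_spatial(c(1, 1), c(1, 1), 2), 1)
  # value halves when distance grows by 2 sigma^2 ln 2
  s <- 1.7
  d0 <- 1.3
  w0 <- exp(-d0 / (2 * s^2))
  expect_equal(rcrecon:::w_spatial_dist(d0 + 2 * s^2 * log(2), s), w0 / 2)
  expect_gt(rcrecon:::w_spatial_dist(100, s), 0)
  expect_equal(w_fov(2.2, 2.2, 0.4), 1)
  expect_equal(w_fov(1, 3, 0.4), w_fov(3, 1, 0.4))
  # big observed jump -> damped smoothing across the edge
  expect_lt(w_fov(0, 3, 0.4), 0.01)
  expect_error(w_fov(1, 2, -0.1), "sigma_fov")
})

test_that("pairwise energy matches a hand-rolled double loop", {
  set.seed(3)
  g <- matrix(stats::runif(9), 3)
  F0 <- matrix(stats::rnorm(9), 3)
  s <- sampler_full(g)
  pp <- pairwise_params(beta = 0.7, sigma_sp = 2, sigma_fov = 0.5,
                        epsilon_abs = 1e-3)
  got <- pairwise_energy(F0, g, s, pp)
  hand <- 0
  for (k in seq_along(s$i)) {
    i <- s$i[k]; j <- s$j[k]
    d <- F0[i] - F0[j]
    sm <- sqrt(d^2 + 1e-6) - 1e-3
    hand <- hand + 0.7 * sm * exp(-s$dist[k] / (2 * 4)) *
      exp(-abs(g[i] - g[j]) / (2 * 0.25))
  }
  expect_equal(got, hand, tolerance = 1e-12)
  expect_equal(pairwise_energy(matrix(2, 3, 3), g, s, pp), 0)
  expect_equal(pairwise_energy(F0, g, s, pairwise_params(beta = 0)), 0)
})

test_that("total energy: breakdown identity, vanishing cases, pair-order invariance", {
  set.seed(4)
  v <- matrix(stats::rnorm(16), 4)
  obs <- obs_full(v, 0.5)
  s <- sampler_full(v)
  up <- unary_params(0.5, 1)
  pp <- pairwise_params(beta = 1, sigma_sp = 2, sigma_fov = 0.4)
  e <- total_energy(v, obs, s, up, pp)
  expect_equal(e$total, e$unary_total + e$pairwise_total)
  # permuting the stored pair list leaves the energy unchanged
  perm <- sample(seq_along(s$i))
  s2 <- s; s2$i <- s$i[perm]; s2$j <- s$j[perm]; s2$dist <- s$dist[perm]
  expect_equal(total_energy(v, obs, s2, up, pp)$total, e$total)
  none <- observed_envelope(matrix(0, 4, 4), matrix(0L, 4, 4), 0.5)
  attr(none, "reference") <- matrix(1, 4, 4)
  expect_equal(total_energy(matrix(1, 4, 4), none, sampler_full(matrix(1, 4, 4)),
                            up, pp)$total, 0)
})

test_that("total energy equals a brute-force oracle on all slices up to 4x4", {
  set.seed(5)
  for (n in 2:4) {
    v <- matrix(stats::rnorm(n * n), n)
    F0 <- matrix(stats::rnorm(n * n), n)
    mask <- matrix(rbinom(n * n, 1, 0.7), n)
    if (sum(mask) < 2) mask[1:2] <- 1L
    obs <- obs_masked(v, mask, 0.6)
    ref <- interpolate_to_lattice(obs)
    attr(obs, "reference") <- ref
    s <- sampler_full(ref)
    up <- unary_params(0.6, 1.3)
    pp <- pairwise_params(beta = 0.8, sigma_sp = 3, sigma_fov = 0.5,
                          epsilon_abs = 1e-3)
    # oracle: explicit sums straight from the definitions
    u <- 0
    for (k in seq_len(n * n)) if (mask[k] == 1L) {
      r <- obs$values[k] - F0[k]
      t <- 2 * r - log(2 * 0.6^2)
      u <- u + 1.3 * (-(log(2) + t - exp(t)))
    }
    p <- 0
    for (k in seq_along(s$i)) {
      d <- F0[s$i[k]] - F0[s$j[k]]
      p <- p + 0.8 * (sqrt(d^2 + 1e-6) - 1e-3) *
        exp(-s$dist[k] / 18) * exp(-abs(ref[s$i[k]] - ref[s$j[k]]) / 0.5)
    }
    e <- total_energy(F0, obs, s, up, pp)
    expect_equal(e$unary_total, u, tolerance = 1e-10)
    expect_equal(e$pairwise_total, p, tolerance = 1e-10)
  }
})

test_that("analytic gradient matches central finite differences", {
  set.seed(6)
  for (domain in c("log", "linear")) {
    v <- matrix(stats::rnorm(36, sd = 0.5), 6)
    mask <- matrix(rbinom(36, 1, 0.8), 6)
    obs <- obs_masked(v, mask, 0.5)
    ref <- interpolate_to_lattice(obs)
    attr(obs, "reference") <- ref
    s <- build_sampler(ref, edge_map(ref),
                       indicator_params(window_radius = 3L, gamma = 0.01))
    bank <- build_psf_bank("parametric", 3,
                           list(sigma_lat = 0.3, sigma_ax = 0.3,
                                pitch = c(1, 1)))
    up <- unary_params(0.5, 1, psf_bank = bank, psf_domain = domain)
    pp <- pairwise_params(beta = 0.6, sigma_sp = 2, sigma_fov = 0.4)
    F0 <- ref + matrix(stats::rnorm(36, sd = 0.1), 6)
    gr <- energy_gradient(F0, obs, s, up, pp)
    h <- 1e-6
    fd <- matrix(0, 6, 6)
    for (k in 1:36) {
      Fp <- F0; Fp[k] <- Fp[k] + h
      Fm <- F0; Fm[k] <- Fm[k] - h
      fd[k] <- (total_energy(Fp, obs, s, up, pp)$total -
                  total_energy(Fm, obs, s, up, pp)$total) / (2 * h)
    }
    expect_lt(max(abs(gr - fd)) / max(abs(fd)), 1e-5)
  }
})

test_that("gradient vanishes where the energy is flat", {
  v <- matrix(stats::rnorm(25), 5)
  obs <- obs_full(v, 0.5)
  s <- sampler_full(v)
  up0 <- unary_params(0.5, alpha = 0)
  pp <- pairwise_params(beta = 0.5, sigma_fov = 0.4)
  # constant F: pairwise gradient is exactly 0 (s'(0) = 0)
  g <- energy_gradient(matrix(1, 5, 5), obs, s, up0, pp)
  expect_true(all(g == 0))
  # no observations and beta = 0: energy constant, gradient identically 0
  none <- observed_envelope(matrix(0, 5, 5), matrix(0L, 5, 5), 0.5)
  g2 <- energy_gradient(v, none, s, unary_params(0.5, 1),
                        pairwise_params(beta = 0))
  expect_true(all(g2 == 0))
})

test_that("voxels outside the beams never touch the unary term", {
  set.seed(7)
  v <- matrix(stats::rnorm(25), 5)
  mask <- matrix(1L, 5, 5); mask[2, 3] <- 0L; mask[4, 1] <- 0L
  obs <- obs_masked(v, mask, 0.5)
  ref <- interpolate_to_lattice(obs)
  attr(obs, "reference") <- ref
  s <- sampler_full(ref)
  up <- unary_params(0.5, 1)
  pp0 <- pairwise_params(beta = 0)
  F0 <- ref
  e0 <- total_energy(F0, obs, s, up, pp0)$total
  F1 <- F0; F1[2, 3] <- 99; F1[4, 1] <- -99
  expect_equal(total_energy(F1, obs, s, up, pp0)$total, e0)
})
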