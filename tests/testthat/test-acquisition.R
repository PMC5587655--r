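make_grid <- function(d_mm, c0 = 1540, span = c(0.97, 1.12), fs_mult = 24) {
  seq(d_mm * 1e-3 / c0 * span[1], d_mm * 1e-3 / c0 * span[2] * 1.25,
      by = 1 / (fs_mult * 6e6))
}

test_that("one-way impulse response honours arrival times and symmetry", {
  ap <- aperture_spec(element_length = 5, element_width = 0.5,
                      long_axis = "y")
  d <- 20
  tg <- make_grid(d)
  h <- one_way_sir(ap, c(0, 0, d), tg)
  first <- tg[min(which(h$response > 0))]
  expect_lt(abs(first - d * 1e-3 / 1540), 2 * (tg[2] - tg[1]))
  # mirror symmetry about the element's long axis
  h1 <- one_way_sir(ap, c(1.2, 0.8, d), tg)
  h2 <- one_way_sir(ap, c(-1.2, 0.8, d), tg)
  expect_equal(h1$response, h2$response, tolerance = 1e-12)
})

test_that("far on-axis time integral approaches S / (2 pi d)", {
  ap <- aperture_spec(element_length = 5, element_width = 1.25,
                      long_axis = "y")
  d <- 60
  tg <- make_grid(d)
  h <- suppressWarnings(one_way_sir(ap, c(0, 0, d), tg))
  S <- 5e-3 * 1.25e-3
  expect_equal(sum(h$response) * (tg[2] - tg[1]), S / (2 * pi * d * 1e-3),
               tolerance = 0.01)
})

test_that("coarse time grids warn, and error in strict mode", {
  ap <- aperture_spec(element_length = 5, element_width = 0.5,
                      long_axis = "y")
  # off-end point has a wide arrival spread; a very coarse grid violates
  # the spread/8 rule
  tg <- seq(6e-6, 9e-6, by = 4e-7)
  expect_warning(one_way_sir(ap, c(0, 4, 10), tg), "coarser")
  expect_error(one_way_sir(ap, c(0, 4, 10), tg, strict = TRUE), "coarser")
})

test_that("pulse-echo support and edge-wave arrival clusters", {
  tx <- aperture_spec(long_axis = "y")
  rx <- aperture_spec(long_axis = "x")
  tg <- make_grid(10, fs_mult = 32)
  pe <- suppressWarnings(pulse_echo_psf(tx, rx, c(0, 0, 10), tg))
  exc <- gauss_pulse(6e6, 0.6, tg[2] - tg[1])
  expect_length(pe$rf, 2 * length(tg) - 1 + length(exc) - 1)
  # off-axis scatterer: direct wave plus edge-wave ghosts give >= 2
  # distinct arrival clusters
  fp <- c(1.5, 2, 10)
  rmax <- sqrt((1.5 + 2.5)^2 + (2 + 2.5)^2 + 100) * 1e-3
  tg2 <- seq(10e-3 / 1540 * 0.97, rmax / 1540 * 1.05, by = 1 / (32 * 6e6))
  pe2 <- suppressWarnings(pulse_echo_psf(tx, rx, fp, tg2))
  expect_gte(arrival_clusters(pe2$envelope, threshold_db = 40), 2L)
  # on-axis point: one dominant cluster at a tight threshold
  expect_gte(arrival_clusters(pe$envelope, threshold_db = 6), 1L)
})

test_that("parametric PSF bank: normalization, degenerate depths, ghosts", {
  p <- list(sigma_lat = c(0.5, 0.5, 0.5), sigma_ax = 0.2,
            pitch = c(0.25, 0.25))
  b <- build_psf_bank("parametric", c(10, 20, 30), p)
  expect_true(all(vapply(b$kernels, function(k) abs(sum(k) - 1), 0) < 1e-9))
  expect_identical(b$kernels[[1]], b$kernels[[2]])
  expect_identical(b$kernels[[2]], b$kernels[[3]])
  expect_error(
    build_psf_bank("parametric", c(10, 20),
                   list(sigma_lat = c(0.6, 0.4), sigma_ax = 0.2,
                        pitch = c(0.25, 0.25))),
    "non-decreasing")
  gb <- build_psf_bank("parametric", c(10, 20),
                       list(sigma_lat = c(0.4, 0.5), sigma_ax = 0.2,
                            pitch = c(0.25, 0.25)),
                       ghost_spec = list(list(1.0, 0.1)))
  # ghost replica adds 10% of the kernel mass, shifted deeper
  expect_equal(vapply(gb$kernels, sum, 0), c(1.1, 1.1), tolerance = 1e-9)
  expect_gt(nrow(gb$kernels[[1]]), nrow(b$kernels[[1]]))
})

test_that("apply_psf is the identity for a delta bank, linear, with exact adjoint", {
  f <- matrix(stats::runif(32 * 32), 32)
  expect_equal(apply_psf(f, psf_bank_identity()), f, tolerance = 1e-12)
  bank <- build_psf_bank("parametric", c(3, 6),
                         list(sigma_lat = c(0.4, 0.8), sigma_ax = 0.3,
                              pitch = c(0.25, 0.25)),
                         ghost_spec = list(list(0.75, 0.1)))
  g <- matrix(stats::rnorm(32 * 32), 32)
  a <- 1.3; bvl <- -0.7
  lhs <- apply_psf(a * f + bvl * g, bank, pitch_z = 0.25)
  rhs <- a * apply_psf(f, bank, pitch_z = 0.25) +
    bvl * apply_psf(g, bank, pitch_z = 0.25)
  expect_lt(max(abs(lhs - rhs)), 1e-10)
  dot1 <- sum(apply_psf(f, bank, pitch_z = 0.25) * g)
  dot2 <- sum(f * apply_psf(g, bank, adjoint = TRUE, pitch_z = 0.25))
  expect_lt(abs(dot1 - dot2) / abs(dot1), 1e-8)
  expect_error(apply_psf(matrix(1, 2, 2), bank), "larger than image")
})

test_that("log-speckle noise follows the Fisher-Tippett law", {
  eps <- rcrecon:::speckle_noise(1e6, 0.7, seed = 11)
  expect_equal(var(eps), pi^2 / 24, tolerance = 0.01)
  # sigma-independence of the log-domain variance
  eps2 <- rcrecon:::speckle_noise(1e6, 0.05, seed = 12)
  expect_equal(var(eps2), pi^2 / 24, tolerance = 0.01)
  # standardized draws match the Gumbel-minimum CDF
  y <- 2 * rcrecon:::speckle_noise(1e5, 0.7, seed = 13) - log(2 * 0.7^2)
  ks <- max(abs(pgumbel_min(sort(y)) - (seq_along(y) - 0.5) / length(y)))
  expect_lt(ks, 0.01)
  expect_identical(apply_speckle(matrix(2, 4, 4), 0.5, seed = 3),
                   apply_speckle(matrix(2, 4, 4), 0.5, seed = 3))
  expect_error(apply_speckle(matrix(1, 2, 2), -1), "sigma")
})

test_that("fan-beam mask saturates, complements, and thins with fewer beams", {
  dense <- make_fanbeam_mask(c(32L, 32L), c(1, 1), origin = c(4, -16),
                             apex = c(0, 0), n_beams = 600L,
                             angular_span = c(-80, 80),
                             samples_per_beam = 4000L)
  expect_true(all(dense$mask == 1L))
  expect_true(all(dense$cr == 0L))
  m64 <- make_fanbeam_mask(c(128L, 128L), c(1, 1), origin = c(4, -64),
                           apex = c(0, 0), n_beams = 64L,
                           angular_span = c(-30, 30))
  m32 <- make_fanbeam_mask(c(128L, 128L), c(1, 1), origin = c(4, -64),
                           apex = c(0, 0), n_beams = 32L,
                           angular_span = c(-30, 30))
  expect_identical(m64$cr, 1L - m64$mask)
  expect_lt(sum(m32$mask), sum(m64$mask))
  expect_error(
    make_fanbeam_mask(c(32L, 32L), c(1, 1), origin = c(0, -16),
                      apex = c(10, 0)),
    "apex")
})

test_that("forward_observe composes blur, mask and seeded speckle", {
  f <- matrix(stats::runif(20 * 20, 0.5, 2), 20)
  m <- full_sampling_mask(c(20L, 20L))
  obs <- forward_observe(f, psf_bank_identity(), m, sigma = 0.5, seed = 5)
  eps <- matrix(rcrecon:::speckle_noise(400, 0.5, seed = 5), 20)
  # deterministic part of the forward model is exactly log f
  expect_equal(obs$values - eps, log(f), tolerance = 1e-12)
  obs2 <- forward_observe(f, psf_bank_identity(), m, sigma = 0.5, seed = 5)
  expect_identical(obs$values, obs2$values)
  # masked voxels carry no value and are flagged by the uncertainty layer
  mask <- matrix(rbinom(400, 1, 0.6), 20)
  obs3 <- forward_observe(f, psf_bank_identity(), mask, 0.5, seed = 5)
  expect_true(all(obs3$values[mask == 0L] == 0))
  expect_identical(obs3$cr, 1L - mask)
})

test_that("lattice interpolation fills gaps linearly and leaves samples alone", {
  v <- matrix(0, 5, 5)
  m <- matrix(1L, 5, 5)
  obs <- obs_masked(v, m)
  expect_identical(interpolate_to_lattice(obs), v)
  # gap midway between two samples along one beam axis -> arithmetic mean
  v2 <- matrix(0, 5, 3)
  v2[1, 2] <- 2; v2[5, 2] <- 4
  m2 <- matrix(0L, 5, 3); m2[1, ] <- 1L; m2[5, ] <- 1L
  v2[1, c(1, 3)] <- 2; v2[5, c(1, 3)] <- 4
  out <- interpolate_to_lattice(obs_masked(v2, m2))
  expect_equal(out[3, 2], 3)
  expect_false(anyNA(out))
  expect_true(all(out[m2 == 1L] == v2[m2 == 1L]))
  # fewer than 2 samples in a slice is an error
  m3 <- matrix(0L, 4, 4); m3[2, 2] <- 1L
  expect_error(interpolate_to_lattice(obs_masked(matrix(1, 4, 4), m3)),
               "fewer than 2")
})
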