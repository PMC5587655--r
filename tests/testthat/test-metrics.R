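test_that("PSNR matches hand arithmetic and flags identical images", {
  f_p <- matrix(1, 2, 2)
  f_r <- matrix(c(1, 1, 1, 0), 2)
  expect_equal(mse(f_p, f_r), 0.25)
  expect_equal(psnr(f_p, f_r), 10 * log10(1 / 0.25), tolerance = 1e-12)
  expect_equal(psnr(f_p, f_r), 6.0206, tolerance = 1e-4)
  expect_identical(psnr(f_p, f_p), Inf)
  # a common offset leaves the MSE untouched
  a <- matrix(stats::runif(16), 4); b <- matrix(stats::runif(16), 4)
  expect_equal(mse(a + 3, b + 3), mse(a, b))
  expect_error(psnr(matrix(1, 2, 2), matrix(1, 3, 3)), "shapes")
})

test_that("CoC: identical 1, negated -1, symmetric, affine-equivariant", {
  set.seed(20)
  f <- matrix(stats::rnorm(64), 8)
  g <- matrix(stats::rnorm(64), 8)
  expect_equal(coc(f, f), 1, tolerance = 1e-12)
  expect_equal(coc(f, -f), -1, tolerance = 1e-12)
  expect_equal(coc(f, g), coc(g, f), tolerance = 1e-12)
  expect_equal(coc(f, 2.5 * g + 7), coc(f, g), tolerance = 1e-12)
  expect_equal(coc(f, -0.3 * g + 2), -coc(f, g), tolerance = 1e-12)
  expect_warning(res <- coc(matrix(1, 8, 8), g), "zero-variance")
  expect_true(is.na(res))
})

test_that("CoC equals an independent correlation-of-Laplacians oracle", {
  set.seed(21)
  lap_oracle <- function(img) {
    n <- nrow(img); m <- ncol(img)
    out <- matrix(0, n, m)
    at <- function(i, j) img[min(max(i, 1), n), min(max(j, 1), m)]
    for (i in 1:n) for (j in 1:m)
      out[i, j] <- at(i - 1, j) + at(i + 1, j) + at(i, j - 1) +
        at(i, j + 1) - 4 * img[i, j]
    out
  }
  for (rep in 1:3) {
    f <- matrix(stats::rnorm(256), 16)
    g <- matrix(stats::rnorm(256), 16)
    expect_equal(coc(f, g),
                 stats::cor(as.vector(lap_oracle(f)),
                            as.vector(lap_oracle(g))),
                 tolerance = 1e-12)
  }
})

test_that("ENL: two-point value, infinity on constants, scale invariance", {
  img <- matrix(c(1, 3, 5, 5), 2)
  expect_equal(enl(img, c(1L, 2L)), 4)          # mu 2, pop var 1
  expect_identical(enl(img, c(3L, 4L)), Inf)
  set.seed(22)
  img2 <- matrix(stats::runif(36, 1, 2), 6)
  region <- img2 > 1.3
  expect_equal(enl(3.7 * img2, region), enl(img2, region), tolerance = 1e-12)
  expect_error(enl(img2, 5L), ">= 2")
})

test_that("CNR follows the printed expression, with the corrected variant", {
  img <- matrix(0, 4, 4)
  img[1:2, 1] <- c(2, 4)        # feature: mean 3, pop var 1
  img[3:4, 1] <- 2              # background: mean 2, sd 0
  feat <- matrix(FALSE, 4, 4); feat[1:2, 1] <- TRUE
  bg <- matrix(FALSE, 4, 4); bg[3:4, 1] <- TRUE
  expect_equal(cnr(img, feat, bg), 1)            # (3-2)/sqrt(1+0)
  expect_equal(cnr(img, feat, feat), 0)          # zero numerator
  # numerator is linear in the feature-background gap
  img2 <- img; img2[1:2, 1] <- c(4, 6)
  expect_equal(cnr(img2, feat, bg), 3)
  # printed form uses sd_b unsquared; corrected squares it
  set.seed(23)
  img3 <- matrix(stats::runif(64, 1, 4), 8)
  feat3 <- matrix(FALSE, 8, 8); feat3[2:4, 2:4] <- TRUE
  bg3 <- matrix(FALSE, 8, 8); bg3[6:8, 6:8] <- TRUE
  vb <- img3[bg3]; vf <- img3[feat3]
  sdb <- sqrt(mean((vb - mean(vb))^2))
  vr <- mean((vf - mean(vf))^2)
  expect_equal(cnr(img3, feat3, bg3),
               (mean(vf) - mean(vb)) / sqrt(vr + sdb), tolerance = 1e-12)
  expect_equal(cnr(img3, feat3, bg3, corrected = TRUE),
               (mean(vf) - mean(vb)) / sqrt(vr + sdb^2), tolerance = 1e-12)
})

test_that("FWHM: Gaussian closed form, triangle, monotone flag", {
  x <- seq(-6, 6, by = 0.05)
  prof <- exp(-x^2 / 2)                          # sigma_g = 1 mm
  expect_equal(fwhm(prof, pitch = 0.05), 2 * sqrt(2 * log(2)),
               tolerance = 0.05)
  tri <- c(seq(0, 1, by = 0.1), seq(0.9, 0, by = -0.1))  # base 2 mm
  expect_equal(fwhm(tri, pitch = 0.1), 1, tolerance = 1e-9)
  expect_warning(res <- fwhm(seq(0, 1, by = 0.1), pitch = 0.1), "undefined")
  expect_true(is.na(res))
})

test_that("half-max peak counting separates and merges as documented", {
  prof <- c(0, 0, 5, 0, 0, 0, 4, 0, 0)
  expect_equal(count_halfmax_peaks(prof), 2L)
  # one-sample dip is merged when min_gap > 1
  prof2 <- c(0, 5, 1, 5, 0)
  expect_equal(count_halfmax_peaks(prof2), 2L)
  expect_equal(count_halfmax_peaks(prof2, min_gap = 2L), 1L)
  expect_equal(count_halfmax_peaks(rep(1, 5)), 1L)
})

test_that("all metrics agree with naive double-loop references on random 8x8", {
  set.seed(24)
  for (rep in 1:3) {
    f <- matrix(stats::runif(64, 0, 5), 8)
    g <- matrix(stats::runif(64, 0, 5), 8)
    # psnr/mse
    sse <- 0
    for (i in 1:8) for (j in 1:8) sse <- sse + (f[i, j] - g[i, j])^2
    expect_equal(mse(f, g), sse / 64, tolerance = 1e-10)
    expect_equal(psnr(f, g), 10 * log10(max(f)^2 / (sse / 64)),
                 tolerance = 1e-10)
    # enl
    region <- matrix(FALSE, 8, 8); region[2:6, 3:7] <- TRUE
    v <- c()
    for (i in 1:8) for (j in 1:8) if (region[i, j]) v <- c(v, g[i, j])
    expect_equal(enl(g, region), mean(v)^2 / mean((v - mean(v))^2),
                 tolerance = 1e-10)
  }
})

test_that("psnr decreases as independent noise grows (median over 10 seeds)", {
  set.seed(25)
  f <- matrix(stats::runif(256, 1, 3), 16)
  med <- vapply(c(0.05, 0.2, 0.8), function(sd) {
    stats::median(vapply(1:10, function(s) {
      set.seed(s)
      psnr(f, f + matrix(stats::rnorm(256, sd = sd), 16))
    }, 0))
  }, 0)
  expect_true(all(diff(med) < 0))
})
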