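#' Peak signal-to-noise ratio
#'
#' `10 log10(max(f_p)^2 / MSE)` with the mean squared error taken over all
#' voxels; `f_p` is the ideal (reference) image. Identical images are
#' flagged infinite rather than raising.
#'
#' @param f_p ideal image (matrix).
#' @param f_r reconstructed image (same shape).
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(f_p, f_r) {
  if (!all(dim(f_p) == dim(f_r))) stop_arg("image shapes differ")
  m <- mse(f_p, f_r)
  if (m == 0) return(Inf)
  10 * log10(max(f_p)^2 / m)
}

#' @rdname psnr
#' @export
mse <- function(f_p, f_r) mean((f_p - f_r)^2)

laplacian4 <- function(img) {
  nz <- nrow(img); nx <- ncol(img)
  p <- img[c(1L, seq_len(nz), nz), c(1L, seq_len(nx), nx)]  # reflect border
  p[2L:(nz + 1L), 2L:(nx + 1L)] * (-4) +
    p[1L:nz, 2L:(nx + 1L)] + p[3L:(nz + 2L), 2L:(nx + 1L)] +
    p[2L:(nz + 1L), 1L:nx] + p[2L:(nz + 1L), 3L:(nx + 2L)]
}

#' Coefficient of correlation of image Laplacians
#'
#' Pearson correlation between the discrete Laplacians (4-neighbour kernel,
#' reflected border) of the ideal and reconstructed images: an
#' edge-preservation score in `[-1, 1]`, 1 for identical images.
#'
#' @inheritParams psnr
#' @return dimensionless value in `[-1, 1]`, or `NA` with a warning when a
#'   Laplacian has zero variance.
#' @export
coc <- function(f_p, f_r) {
  if (!all(dim(f_p) == dim(f_r))) stop_arg("image shapes differ")
  lp <- laplacian4(f_p); lr <- laplacian4(f_r)
  a <- lp - mean(lp); b <- lr - mean(lr)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) {
    warning("zero-variance Laplacian; CoC undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(a * b) / den
}

region_values <- function(image, region) {
  if (is.logical(region)) image[region]
  else image[as.integer(region)]
}

#' Effective number of looks of a region
#'
#' `mu^2 / sigma^2` (population variance) over a homogeneous region of
#' interest; higher means smoother. A perfectly constant region is flagged
#' infinite.
#'
#' @param image matrix.
#' @param region logical mask (same shape) or integer voxel indices, with at
#'   least 2 voxels.
#' @export
enl <- function(image, region) {
  v <- region_values(image, region)
  if (length(v) < 2L) stop_arg("region must contain >= 2 voxels")
  s2 <- mean((v - mean(v))^2)
  if (s2 == 0) return(Inf)
  mean(v)^2 / s2
}

#' Contrast-to-noise ratio of feature regions against background
#'
#' Averages `(mu_r - mu_b) / sqrt(sigma_r^2 + sigma_b)` over the feature
#' regions, exactly as the defining expression prints it (the background
#' standard deviation enters unsquared); `corrected = TRUE` uses
#' `sigma_r^2 + sigma_b^2` instead.
#'
#' @param image matrix.
#' @param features list of regions (masks or index vectors).
#' @param background background region.
#' @param corrected use the squared background deviation in the denominator.
#' @return dB-like real, or `NA` with a warning for a non-positive
#'   denominator.
#' @export
cnr <- function(image, features, background, corrected = FALSE) {
  if (is.logical(features) || is.numeric(features)) features <- list(features)
  if (length(features) < 1L) stop_arg("need at least one feature region")
  vb <- region_values(image, background)
  mu_b <- mean(vb)
  sd_b <- sqrt(mean((vb - mu_b)^2))
  vals <- vapply(features, function(rg) {
    v <- region_values(image, rg)
    mu_r <- mean(v)
    var_r <- mean((v - mu_r)^2)
    den <- var_r + if (corrected) sd_b^2 else sd_b
    if (den <= 0) return(NA_real_)
    (mu_r - mu_b) / sqrt(den)
  }, 0)
  if (anyNA(vals)) {
    warning("non-positive CNR denominator; undefined", call. = FALSE)
    return(NA_real_)
  }
  mean(vals)
}

#' Full width at half maximum of a 1-D profile
#'
#' Width (in mm) at half of `max - baseline` (baseline = profile minimum),
#' with linear interpolation of the crossings on either side of the unique
#' global maximum.
#'
#' @param profile numeric samples.
#' @param pitch mm between samples.
#' @return width in mm, or `NA` with a warning when the half level is never
#'   crossed on one side.
#' @export
fwhm <- function(profile, pitch = 1) {
  x <- (seq_along(profile) - 1) * pitch
  base <- min(profile)
  half <- base + (max(profile) - base) / 2
  w <- width_6db(x, profile - base)   # half of (max - base): same crossing
  if (!is.finite(w)) {
    warning("half-maximum level never crossed; FWHM undefined",
            call. = FALSE)
    return(NA_real_)
  }
  w
}

#' Count distinct axial half-maximum peaks in a profile
#'
#' Connected runs of samples at or above half of the profile maximum (above
#' the baseline minimum), separated by a below-half dip of at least
#' `min_gap` samples. Dips narrower than the axial PSF support cannot
#' indicate genuinely separate targets, so resolution counts should set
#' `min_gap` to roughly the PSF's axial half-width in samples.
#'
#' @param profile numeric samples.
#' @param min_gap minimum below-half dip width (samples) splitting peaks.
#' @return integer count.
#' @export
count_halfmax_peaks <- function(profile, min_gap = 1L) {
  base <- min(profile)
  half <- base + (max(profile) - base) / 2
  above <- profile >= half
  r <- rle(above)
  if (min_gap > 1L && length(r$values) > 2L) {
    short <- !r$values & r$lengths < min_gap
    short[c(1L, length(short))] <- FALSE
    r$values[short] <- TRUE
    r <- rle(inverse.rle(r))
  }
  sum(r$values)
}

#' Bundle of the standard quality metrics
#'
#' @param f_p,f_r ideal and reconstructed image (display domain by
#'   convention).
#' @param enl_region optional homogeneous region for ENL.
#' @param features,background optional CNR regions.
#' @return list with `psnr`, `mse`, `coc` and, when regions are given,
#'   `enl` / `cnr`.
#' @export
metrics_report <- function(f_p, f_r, enl_region = NULL, features = NULL,
                           background = NULL) {
  out <- list(psnr = psnr(f_p, f_r), mse = mse(f_p, f_r),
              coc = coc(f_p, f_r))
  if (!is.null(enl_region)) out$enl <- enl(f_r, enl_region)
  if (!is.null(features) && !is.null(background))
    out$cnr <- cnr(f_r, features, background)
  out
}
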