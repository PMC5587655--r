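#' Aperture geometry for a row-column line element
#'
#' Row-column arrays address an N x N 2-D aperture through N long row
#' elements and N orthogonal long column elements. A line element is modelled
#' as a flat rectangle in the z = 0 plane; `long_axis` says whether the long
#' dimension runs along y (a transmit column) or x (a receive row).
#'
#' @param element_length mm, long dimension of the line element.
#' @param element_width mm, short dimension (width of one element, or of the
#'   active sub-aperture when several adjacent elements fire together).
#' @param element_count elements per side of the array.
#' @param pitch mm element pitch.
#' @param center_frequency Hz.
#' @param sound_speed m/s.
#' @param long_axis `"y"` or `"x"`.
#' @return An `aperture_spec`.
#' @export
aperture_spec <- function(element_length = 5, element_width = 0.15625,
                          element_count = 32L, pitch = 0.15625,
                          center_frequency = 6e6, sound_speed = 1540,
                          long_axis = c("y", "x")) {
  long_axis <- match.arg(long_axis)
  vals <- c(element_length, element_width, element_count, pitch,
            center_frequency, sound_speed)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_arg("all aperture parameters must be positive")
  if (element_length <= 2 * element_width)
    stop_arg("row-column line elements require element_length >> element_width")
  structure(list(element_length = element_length,
                 element_width = element_width,
                 element_count = as.integer(element_count), pitch = pitch,
                 center_frequency = center_frequency,
                 sound_speed = sound_speed, long_axis = long_axis),
            class = "aperture_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

#' One-way spatial impulse response of a flat rectangular element
#'
#' Discretizes the Rayleigh surface integral of
#' delta(t - |r1 - r2| / c) / (2 pi |r1 - r2|) over the element surface by
#' sub-element summation into uniform time bins. The result is a time density
#' (1/s scaled by area/m), so its time-integral approaches S / (2 pi d) for a
#' far on-axis field point.
#'
#' @param aperture an `aperture_spec`.
#' @param field_point mm triple `c(x, y, z)`, z > 0 (off the aperture plane).
#' @param time_grid strictly increasing uniform vector of bin centres, in
#'   seconds; must span the arrival-time window.
#' @param n_sub sub-elements along the long axis (short axis scales by the
#'   aspect ratio); default resolves the arrival spread to ~dt/4.
#' @param strict escalate the coarse-time-grid warning to an error.
#' @return list with `time` (s) and `response`.
#' @export
one_way_sir <- function(aperture, field_point, time_grid, n_sub = NULL,
                        strict = FALSE) {
  fp <- as.numeric(field_point) * 1e-3                # mm -> m
  if (length(fp) != 3L || fp[3] == 0)
    stop_arg("field_point must be c(x, y, z) mm with z off the aperture plane")
  dt <- diff(time_grid)
  if (length(dt) < 1L || any(abs(dt - dt[1]) > 1e-6 * abs(dt[1])))
    stop_arg("time_grid must be uniform with >= 2 points")
  dt <- dt[1]
  L <- aperture$element_length * 1e-3
  W <- aperture$element_width * 1e-3
  c0 <- aperture$sound_speed
  # element-local axes: u along the long axis, v along the short one
  if (aperture$long_axis == "y") { pu <- fp[2]; pv <- fp[1] }
  else                           { pu <- fp[1]; pv <- fp[2] }
  # arrival spread across the element bounds the needed quadrature density
  corner_r <- sqrt(outer((c(-1, 1) * L / 2 - pu)^2,
                         (c(-1, 1) * W / 2 - pv)^2 + fp[3]^2, `+`))
  rmin_geo <- sqrt((max(min(pu, L / 2), -L / 2) - pu)^2 +
                   (max(min(pv, W / 2), -W / 2) - pv)^2 + fp[3]^2)
  spread <- (max(corner_r) - rmin_geo) / c0
  if (dt > max(spread, .Machine$double.eps) / 8) {
    msg <- paste0("time_grid bin (", signif(dt, 3),
                  " s) coarser than arrival spread/8 (",
                  signif(spread / 8, 3), " s)")
    if (strict) stop_arg(msg) else warning(msg, call. = FALSE)
  }
  if (is.null(n_sub)) {
    # sub-element small enough that its own arrival spread < dt/4
    du_max <- c0 * dt / 4
    n_sub <- max(32L, ceiling(L / du_max))
  }
  nu <- as.integer(n_sub)
  nv <- max(4L, ceiling(nu * W / L))
  du <- L / nu; dv <- W / nv
  us <- seq(-L / 2 + du / 2, L / 2 - du / 2, length.out = nu)
  vs <- seq(-W / 2 + dv / 2, W / 2 - dv / 2, length.out = nv)
  r <- sqrt(outer((us - pu)^2, (vs - pv)^2 + fp[3]^2, `+`))
  tt <- r / c0
  if (min(tt) < time_grid[1] - dt / 2 || max(tt) > time_grid[length(time_grid)] + dt / 2)
    stop_arg("time_grid does not span the arrival window [",
             signif(min(tt), 6), ", ", signif(max(tt), 6), "] s")
  bin <- as.integer(round((tt - time_grid[1]) / dt)) + 1L
  h <- scatter_add(length(time_grid), as.vector(bin),
                   as.vector(du * dv / (2 * pi * r))) / dt
  list(time = time_grid, response = h)
}

#' Gaussian-modulated sinusoidal excitation pulse
#'
#' @param center_frequency Hz.
#' @param fractional_bandwidth -6 dB fractional bandwidth (default 0.6).
#' @param dt sample interval, s.
#' @return numeric vector (odd length, peak at centre).
#' @export
gauss_pulse <- function(center_frequency, fractional_bandwidth = 0.6, dt) {
  sigma_f <- fractional_bandwidth * center_frequency / (2 * sqrt(2 * log(2)))
  sigma_t <- 1 / (2 * pi * sigma_f)
  half <- ceiling(3.5 * sigma_t / dt)
  t <- seq(-half, half) * dt
  exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * center_frequency * t)
}

#' Pulse-echo response of a transmit/receive aperture pair
#'
#' The two-way response is the time-domain convolution of the transmit and
#' receive one-way spatial impulse responses, convolved with a
#' Gaussian-modulated sinusoid excitation (the impulse-response model alone
#' carries no finite carrier). For the long orthogonal line elements of a
#' row-column array, an off-axis scatterer produces several distinct arrival
#' clusters: the direct wave plus edge waves from the element ends, the
#' origin of the method's ghost artifacts.
#'
#' @param transmit,receive `aperture_spec`s (orthogonal line elements for
#'   row-column, identical for a fully addressed array).
#' @param field_point mm triple.
#' @param time_grid uniform time grid (s) spanning each one-way arrival
#'   window.
#' @param excitation optional pulse sampled at the grid interval; default
#'   `gauss_pulse` at the transmit centre frequency.
#' @param fractional_bandwidth passed to `gauss_pulse`.
#' @return list with `time` (s, of the convolved support), `rf`, `envelope`.
#' @export
pulse_echo_psf <- function(transmit, receive, field_point, time_grid,
                           excitation = NULL, fractional_bandwidth = 0.6) {
  dt <- time_grid[2] - time_grid[1]
  ht <- one_way_sir(transmit, field_point, time_grid)
  hr <- one_way_sir(receive, field_point, time_grid)
  if (is.null(excitation))
    excitation <- gauss_pulse(transmit$center_frequency,
                              fractional_bandwidth, dt)
  rf <- conv1_full(conv1_full(ht$response, hr$response) * dt, excitation) * dt
  t0 <- 2 * time_grid[1] - dt * ((length(excitation) - 1) / 2)
  tt <- t0 + dt * (seq_along(rf) - 1L)
  list(time = tt, rf = rf, envelope = envelope_hilbert(rf))
}

#' Count distinct arrival clusters in a pulse-echo envelope
#'
#' Clusters are connected runs of samples above `threshold_db` relative to
#' the envelope maximum, separated by at least one below-threshold gap longer
#' than `min_gap` samples.
#'
#' @param envelope numeric vector.
#' @param threshold_db dB below peak (positive number, default 40).
#' @param min_gap minimum below-threshold gap (samples) splitting clusters.
#' @export
arrival_clusters <- function(envelope, threshold_db = 40, min_gap = 3L) {
  thr <- max(envelope) * 10^(-threshold_db / 20)
  above <- envelope >= thr
  r <- rle(above)
  # absorb short gaps
  short_gap <- !r$values & r$lengths < min_gap
  short_gap[c(1L, length(r$values))] <- FALSE
  r$values[short_gap] <- TRUE
  r <- rle(inverse.rle(r))
  sum(r$values)
}

lateral_beam_profile <- function(transmit, receive, depth_mm, offsets_mm,
                                 dt = NULL) {
  c0 <- transmit$sound_speed
  if (is.null(dt)) dt <- 1 / (16 * transmit$center_frequency)
  vapply(offsets_mm, function(x0) {
    fp <- c(x0, 0, depth_mm)
    rmax <- sqrt((abs(x0) + max(transmit$element_length,
                                transmit$element_width) / 2)^2 +
                 (max(transmit$element_length, transmit$element_width) / 2)^2 +
                 depth_mm^2) * 1e-3
    rmin <- depth_mm * 1e-3
    tg <- seq(rmin / c0 * 0.98, rmax / c0 * 1.05, by = dt)
    pe <- suppressWarnings(pulse_echo_psf(transmit, receive, fp, tg))
    max(pe$envelope)
  }, 0)
}

# -6 dB (half-amplitude) width of a sampled profile, linear interpolation.
width_6db <- function(offsets, profile) {
  half <- max(profile) / 2
  ip <- which.max(profile)
  left <- right <- NA_real_
  i <- ip
  while (i > 1L) {
    if (profile[i - 1L] < half) {
      left <- offsets[i - 1L] + (offsets[i] - offsets[i - 1L]) *
        (half - profile[i - 1L]) / (profile[i] - profile[i - 1L])
      break
    }
    i <- i - 1L
  }
  i <- ip
  while (i < length(profile)) {
    if (profile[i + 1L] < half) {
      right <- offsets[i] + (offsets[i + 1L] - offsets[i]) *
        (half - profile[i]) / (profile[i + 1L] - profile[i])
      break
    }
    i <- i + 1L
  }
  right - left
}

#' Depth-indexed PSF kernel bank
#'
#' Packages the spatially varying point spread function as one 2-D kernel
#' (rows axial, columns lateral, unit sum before ghost replicas) per depth.
#' `"parametric"` mode uses anisotropic Gaussians with a non-decreasing
#' lateral -6 dB width; `"sir"` mode extracts kernels from the simplified
#' spatial-impulse-response pulse-echo model with a small unfocused active
#' sub-aperture (so that both depths lie in its far field and the lateral
#' width grows with depth, as no per-depth transmit focusing is modelled).
#' Ghost replicas (`ghost_spec`) append axially shifted, attenuated copies of
#' each kernel emulating the edge-wave ghost echoes.
#'
#' @param mode `"parametric"` or `"sir"`.
#' @param depths strictly increasing depths, mm.
#' @param params named list. Parametric mode: `sigma_lat` (mm per depth,
#'   non-decreasing), `sigma_ax` (mm), `pitch` (`c(dz, dx)` mm). SIR mode:
#'   `transmit`, `receive` aperture specs, `pitch`, optional `lateral_span`
#'   (mm, default 4) and `dt`.
#' @param ghost_spec optional list of `list(offset_mm, rel_amplitude)` ghost
#'   replica descriptors (amplitude relative to the main lobe, linear scale).
#' @return A `psf_bank`.
#' @export
build_psf_bank <- function(mode = c("parametric", "sir"), depths, params,
                           ghost_spec = NULL) {
  mode <- match.arg(mode)
  depths <- as.numeric(depths)
  if (is.unsorted(depths, strictly = TRUE))
    stop_arg("depths must be strictly increasing")
  pitch <- params$pitch
  if (is.null(pitch) || length(pitch) != 2L || any(pitch <= 0))
    stop_arg("params$pitch must be c(dz, dx) mm")
  kernels <- if (mode == "parametric") {
    sl <- rep_len(as.numeric(params$sigma_lat), length(depths))
    if (is.unsorted(sl))
      stop_arg("invariant violation: sigma_lat(z) must be non-decreasing")
    sa <- params$sigma_ax %||% (min(sl) / 2)
    lapply(sl, function(s) gaussian_kernel(sa, s, pitch))
  } else {
    span <- params$lateral_span %||% 4
    lapply(depths, function(d)
      sir_kernel(params$transmit, params$receive, d, span, pitch,
                 dt = params$dt))
  }
  widths <- vapply(kernels, kernel_lateral_width_6db, 0, dx = pitch[2])
  # a half level never crossed inside the kernel means width >= kernel span
  full <- vapply(kernels, function(k) ncol(k) * pitch[2], 0)
  widths[is.na(widths)] <- full[is.na(widths)]
  if (is.unsorted(widths))
    stop_arg("invariant violation: -6 dB lateral width must be ",
             "non-decreasing with depth (got ",
             paste(signif(widths, 4), collapse = ", "), " mm)")
  sums <- vapply(kernels, sum, 0)
  stopifnot(all(abs(sums - 1) < 1e-9))
  if (!is.null(ghost_spec))
    kernels <- lapply(kernels, add_ghosts, ghost_spec = ghost_spec,
                      dz = pitch[1])
  structure(list(mode = mode, depths = depths, kernels = kernels,
                 pitch = as.numeric(pitch), ghost_spec = ghost_spec),
            class = "psf_bank")
}

#' @rdname build_psf_bank
#' @export
psf_bank_identity <- function() {
  structure(list(mode = "identity", depths = 0,
                 kernels = list(matrix(1, 1, 1)), pitch = c(1, 1),
                 ghost_spec = NULL),
            class = "psf_bank")
}

gaussian_kernel <- function(sigma_ax, sigma_lat, pitch) {
  hz <- max(1L, ceiling(3 * sigma_ax / pitch[1]))
  hx <- max(1L, ceiling(3 * sigma_lat / pitch[2]))
  z <- seq(-hz, hz) * pitch[1]
  x <- seq(-hx, hx) * pitch[2]
  k <- outer(exp(-z^2 / (2 * sigma_ax^2)), exp(-x^2 / (2 * sigma_lat^2)))
  k / sum(k)
}

sir_kernel <- function(transmit, receive, depth, span, pitch, dt = NULL) {
  if (is.null(transmit) || is.null(receive))
    stop_arg("sir mode needs params$transmit and params$receive apertures")
  c0 <- transmit$sound_speed
  if (is.null(dt)) dt <- 1 / (16 * transmit$center_frequency)
  nx <- max(5L, 2L * ceiling(span / 2 / pitch[2]) + 1L)
  xs <- (seq_len(nx) - (nx + 1L) / 2) * pitch[2]
  hz_mm <- 1.5                                        # axial half-extent
  nzk <- 2L * ceiling(hz_mm / pitch[1]) + 1L
  zk <- (seq_len(nzk) - (nzk + 1L) / 2) * pitch[1]
  k <- matrix(0, nzk, nx)
  for (j in seq_len(nx)) {
    fp <- c(xs[j], 0, depth)
    rmax <- sqrt((abs(xs[j]) + max(transmit$element_length,
                                   receive$element_length) / 2)^2 +
                 (max(transmit$element_length, receive$element_length) / 2)^2 +
                 depth^2) * 1e-3
    tg <- seq(depth * 1e-3 / c0 * 0.98, rmax / c0 * 1.05, by = dt)
    pe <- suppressWarnings(pulse_echo_psf(transmit, receive, fp, tg))
    # two-way time maps to axial distance via c t / 2, centred on the peak
    ax_mm <- (pe$time - pe$time[which.max(pe$envelope)]) * c0 / 2 * 1e3
    k[, j] <- stats::approx(ax_mm, pe$envelope, xout = zk, rule = 2,
                            yleft = 0, yright = 0)$y
  }
  k[k < 0] <- 0
  k / sum(k)
}

kernel_lateral_width_6db <- function(k, dx) {
  prof <- k[(nrow(k) + 1L) %/% 2L, ]
  if (all(prof == 0)) prof <- colSums(k)
  width_6db(seq_along(prof) * dx, prof)
}

add_ghosts <- function(k, ghost_spec, dz) {
  shifts <- vapply(ghost_spec, function(g) as.integer(round(g[[1]] / dz)), 0L)
  amps <- vapply(ghost_spec, function(g) as.numeric(g[[2]]), 0)
  pad <- max(abs(shifts), 0L)
  n0 <- nrow(k)
  out <- matrix(0, n0 + 2L * pad, ncol(k))
  out[pad + seq_len(n0), ] <- k
  for (i in seq_along(shifts))
    out[pad + shifts[i] + seq_len(n0), ] <-
      out[pad + shifts[i] + seq_len(n0), ] + amps[i] * k
  out
}

#' Apply (or adjoint-apply) the depth-banded PSF operator H
#'
#' Each bank depth contributes a full 2-D convolution; per-voxel linear
#' blending weights over depth (hat functions anchored at the bank depths,
#' clamped at the ends) combine them, giving a linear operator whose exact
#' adjoint is correlation with the flipped kernels applied to the
#' weight-masked image.
#'
#' @param f matrix or `reflectivity_image`.
#' @param bank a `psf_bank`.
#' @param adjoint apply the transpose operator instead.
#' @param pitch_z,origin_z axial geometry (mm) when `f` is a bare matrix.
#' @return matrix of the same shape as `f`.
#' @export
apply_psf <- function(f, bank, adjoint = FALSE, pitch_z = NULL,
                      origin_z = NULL) {
  if (inherits(f, "reflectivity_image")) {
    pitch_z <- pitch_z %||% f$pitch[1]
    origin_z <- origin_z %||% f$origin[1]
    f <- f$values
  }
  pitch_z <- pitch_z %||% 1
  origin_z <- origin_z %||% 0
  K <- length(bank$kernels)
  if (K == 1L) {
    k <- bank$kernels[[1L]]
    if (adjoint) k <- rot180(k)
    return(conv2_same(f, k))
  }
  zrows <- origin_z + (seq_len(nrow(f)) - 1) * pitch_z
  out <- matrix(0, nrow(f), ncol(f))
  for (k in seq_len(K)) {
    w <- depth_blend_weight(zrows, bank$depths, k)
    if (all(w == 0)) next
    W <- matrix(w, nrow(f), ncol(f))
    if (adjoint) out <- out + conv2_same(W * f, rot180(bank$kernels[[k]]))
    else out <- out + W * conv2_same(f, bank$kernels[[k]])
  }
  out
}

depth_blend_weight <- function(z, depths, k) {
  K <- length(depths)
  w <- numeric(length(z))
  if (k == 1L) w[z <= depths[1]] <- 1
  if (k == K) w[z >= depths[K]] <- 1
  if (k > 1L) {
    sel <- z > depths[k - 1L] & z <= depths[k]
    w[sel] <- (z[sel] - depths[k - 1L]) / (depths[k] - depths[k - 1L])
  }
  if (k < K) {
    sel <- z > depths[k] & z < depths[k + 1L]
    w[sel] <- (depths[k + 1L] - z[sel]) / (depths[k + 1L] - depths[k])
  }
  w
}

#' Multiplicative speckle in the log-envelope domain
#'
#' Returns `log f + eps` where `eps = (y + log(2 sigma^2)) / 2` and `y`
#' follows the standard minimum-Gumbel density `exp(y - exp(y))`, so that the
#' log-domain noise follows the Fisher-Tippett density
#' `2 exp[(2I - ln 2 sigma^2) - exp(2I - ln 2 sigma^2)]` that governs
#' log-compressed fully developed speckle. The noise variance is
#' sigma-independent: pi^2/24.
#'
#' @param f image (matrix) of positive linear reflectivity, or log values if
#'   `input_log = TRUE`.
#' @param sigma Fisher-Tippett scale parameter (> 0).
#' @param seed RNG seed.
#' @param input_log `f` is already in the log domain.
#' @return matrix of noisy log-envelope values.
#' @export
apply_speckle <- function(f, sigma, seed = 1L, input_log = FALSE) {
  if (!is_scalar_num(sigma) || sigma <= 0) stop_arg("sigma must be > 0")
  vals <- if (inherits(f, "reflectivity_image")) f$values else f
  eps <- speckle_noise(length(vals), sigma, seed)
  base <- if (input_log) vals else log(vals)
  out <- base + eps
  if (is.matrix(vals)) matrix(out, nrow(vals), ncol(vals)) else out
}

speckle_noise <- function(n, sigma, seed) {
  u <- with_seed(seed, stats::runif(n))
  y <- log(-log(u))
  (y + log(2 * sigma^2)) / 2
}

#' Fan-beam sampling mask
#'
#' Rasterizes `n_beams` rays from an apex above the lattice across
#' `angular_span`, assigning each along-ray sample to its nearest voxel.
#' Voxels hit at least once are sampled (mask 1); the uncertainty layer is
#' the elementwise complement.
#'
#' @param grid_shape `c(nz, nx)`.
#' @param pitch,origin `c(z, x)` mm.
#' @param apex `c(z, x)` mm; must not lie in the grid interior.
#' @param n_beams number of beams (>= 1).
#' @param angular_span degrees from the axial direction, within (-90, 90).
#' @param samples_per_beam along-ray samples; default saturates the axial
#'   resolution (2 nz).
#' @return A `sampling_mask`: list with `mask` (0/1 matrix), `cr`
#'   (complement), plus geometry.
#' @export
make_fanbeam_mask <- function(grid_shape, pitch, origin = c(0, 0),
                              apex = NULL, n_beams = 64L,
                              angular_span = c(-25, 25),
                              samples_per_beam = NULL) {
  nz <- grid_shape[1]; nx <- grid_shape[2]
  if (is.null(apex)) apex <- c(origin[1] - 1, origin[2] + (nx - 1) * pitch[2] / 2)
  if (n_beams < 1L) stop_arg("n_beams must be >= 1")
  if (any(abs(angular_span) >= 90))
    stop_arg("angular_span must lie inside (-90, 90) degrees")
  zmax <- origin[1] + (nz - 1) * pitch[1]
  xmax <- origin[2] + (nx - 1) * pitch[2]
  inside <- apex[1] > origin[1] && apex[1] < zmax &&
    apex[2] > origin[2] && apex[2] < xmax
  if (inside) stop_arg("geometry error: apex lies inside the grid interior")
  if (is.null(samples_per_beam)) samples_per_beam <- 2L * nz
  angles <- if (n_beams == 1L) mean(angular_span) else
    seq(angular_span[1], angular_span[2], length.out = n_beams)
  maxdist <- sqrt((zmax - apex[1])^2 + (abs(apex[2]) + abs(xmax) +
                                          abs(origin[2]))^2)
  tvals <- seq(0, maxdist, length.out = samples_per_beam)
  mask <- matrix(0L, nz, nx)
  for (a in angles * pi / 180) {
    zs <- apex[1] + tvals * cos(a)
    xs <- apex[2] + tvals * sin(a)
    iz <- as.integer(round((zs - origin[1]) / pitch[1])) + 1L
    ix <- as.integer(round((xs - origin[2]) / pitch[2])) + 1L
    ok <- iz >= 1L & iz <= nz & ix >= 1L & ix <= nx
    mask[cbind(iz[ok], ix[ok])] <- 1L
  }
  structure(list(mask = mask, cr = 1L - mask, apex = apex,
                 n_beams = as.integer(n_beams), angular_span = angular_span,
                 pitch = as.numeric(pitch), origin = as.numeric(origin)),
            class = "sampling_mask")
}

#' @rdname make_fanbeam_mask
#' @param mask 0/1 matrix.
#' @export
full_sampling_mask <- function(grid_shape, pitch = c(1, 1),
                               origin = c(0, 0)) {
  m <- matrix(1L, grid_shape[1], grid_shape[2])
  structure(list(mask = m, cr = 1L - m, apex = NULL, n_beams = NA_integer_,
                 angular_span = NULL, pitch = as.numeric(pitch),
                 origin = as.numeric(origin)),
            class = "sampling_mask")
}

#' Forward observation of a reflectivity image
#'
#' Simulates the observed log-compressed envelope on the sampled voxels:
#' `values = mask * (log(H f) + eps)` with `H` the depth-banded PSF operator
#' and `eps` Fisher-Tippett log-speckle. Unsampled voxels carry 0 and are
#' flagged by the uncertainty layer `cr = 1 - mask`.
#'
#' @param f `reflectivity_image` or positive matrix.
#' @param bank `psf_bank`.
#' @param mask `sampling_mask` (or 0/1 matrix).
#' @param sigma speckle scale.
#' @param seed RNG seed.
#' @param log_floor sampled envelope values below this are clipped before the
#'   log, with a warning.
#' @return An `observed_envelope`: list with `values`, `mask`, `cr`,
#'   `noise_sigma`, `pitch`, `origin`.
#' @export
forward_observe <- function(f, bank, mask, sigma, seed = 1L,
                            log_floor = 1e-12) {
  pitch <- c(1, 1); origin <- c(0, 0)
  if (inherits(f, "reflectivity_image")) { pitch <- f$pitch; origin <- f$origin }
  m <- if (inherits(mask, "sampling_mask")) mask$mask else mask
  blurred <- apply_psf(f, bank)
  if (any(blurred[m == 1L] < log_floor)) {
    warning("sampled envelope at or below log floor; clipped", call. = FALSE)
  }
  blurred <- pmax(blurred, log_floor)
  gl <- matrix(apply_speckle(blurred, sigma, seed = seed), nrow(blurred))
  observed_envelope(m * gl, m, sigma, pitch, origin)
}

#' @rdname forward_observe
#' @param values log-envelope matrix (finite where sampled).
#' @export
observed_envelope <- function(values, mask, sigma, pitch = c(1, 1),
                              origin = c(0, 0)) {
  m <- if (inherits(mask, "sampling_mask")) mask$mask else mask
  if (!all(dim(values) == dim(m)))
    stop_arg("values and mask shapes differ")
  if (any(!is.finite(values[m == 1L])))
    stop_arg("observed values must be finite wherever mask = 1")
  structure(list(values = values, mask = m, cr = 1L - m,
                 noise_sigma = sigma, pitch = as.numeric(pitch),
                 origin = as.numeric(origin)),
            class = "observed_envelope")
}

#' Fill the unsampled lattice by linear interpolation
#'
#' Missing (cr = 1) voxels are filled by separable linear interpolation:
#' first along each beam-dominant (axial) column, then along rows, with
#' nearest-neighbour extension outside the sampled hull. Sampled voxels are
#' returned unchanged and the output contains no undefined values.
#'
#' @param obs an `observed_envelope` (single slice).
#' @return matrix of log-envelope values, fully defined.
#' @export
interpolate_to_lattice <- function(obs) {
  v <- obs$values
  m <- obs$mask
  if (sum(m) < 2L)
    stop_arg("slice has fewer than 2 sampled voxels; cannot interpolate")
  if (all(m == 1L)) return(v)
  out <- v
  out[m == 0L] <- NA_real_
  # pass 1: along columns (axial), the dominant direction of the fan beams
  for (j in seq_len(ncol(out))) {
    col <- out[, j]
    ok <- !is.na(col)
    if (sum(ok) >= 2L) {
      fill <- is.na(col)
      col[fill] <- stats::approx(which(ok), col[ok], xout = which(fill),
                                 rule = 1)$y
      out[, j] <- col
    }
  }
  # pass 2: along rows, nearest extension at the ends
  for (i in seq_len(nrow(out))) {
    row <- out[i, ]
    ok <- !is.na(row)
    if (sum(ok) >= 2L) {
      fill <- is.na(row)
      row[fill] <- stats::approx(which(ok), row[ok], xout = which(fill),
                                 rule = 2)$y
      out[i, ] <- row
    } else if (sum(ok) == 1L) {
      row[] <- row[ok]
      out[i, ] <- row
    }
  }
  # pass 3: any still-empty rows take the nearest defined row
  if (anyNA(out)) {
    defined <- which(apply(out, 1L, function(r) !anyNA(r)))
    for (i in which(apply(out, 1L, anyNA)))
      out[i, ] <- out[defined[which.min(abs(defined - i))], ]
  }
  out[m == 1L] <- v[m == 1L]
  out
}
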