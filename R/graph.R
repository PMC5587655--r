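# box smoothing with replicated borders; the edge map of a speckled slice is
# noise-dominated unless the speckle is knocked down first (5x5 box cuts the
# log-speckle sd ~5x while a 10x reflectivity step stays ~2.3 log units)
box_smooth <- function(image, radius = 2L) {
  nz <- nrow(image); nx <- ncol(image)
  out <- matrix(0, nz, nx)
  ridx <- pmin(pmax(outer(seq_len(nz), (-radius):radius, `+`), 1L), nz)
  cidx <- pmin(pmax(outer(seq_len(nx), (-radius):radius, `+`), 1L), nx)
  for (dr in seq_len(2L * radius + 1L)) for (dc in seq_len(2L * radius + 1L))
    out <- out + image[ridx[, dr], cidx[, dc]]
  out / (2L * radius + 1L)^2
}

#' Edge map of a slice
#'
#' Sobel gradient magnitude with replicated borders, normalized to `[0, 1]`
#' by its maximum; an all-constant image yields an all-zero map. This is the
#' edge value consumed by the edge-guided stochastic indicator.
#'
#' @param image 2-D numeric matrix.
#' @return matrix of edge strengths in `[0, 1]`.
#' @export
edge_map <- function(image) {
  if (!is.matrix(image)) stop_arg("image must be a 2-D matrix")
  nz <- nrow(image); nx <- ncol(image)
  p <- image[c(1L, seq_len(nz), nz), c(1L, seq_len(nx), nx)]  # replicate pad
  sh <- function(dr, dc) p[dr + seq_len(nz), dc + seq_len(nx)]
  gx <- (sh(0, 2) + 2 * sh(1, 2) + sh(2, 2)) -
        (sh(0, 0) + 2 * sh(1, 0) + sh(2, 0))
  gz <- (sh(2, 0) + 2 * sh(2, 1) + sh(2, 2)) -
        (sh(0, 0) + 2 * sh(0, 1) + sh(0, 2))
  g <- sqrt(gx^2 + gz^2)
  mx <- max(g)
  if (mx > 0) g / mx else g
}

#' Clique-sampling affinities
#'
#' The stochastic indicator couples three Gaussian affinities: spatial
#' (`P^s`, on the inter-node Euclidean distance in voxel units, taking node i
#' as the window centre so its own centre distance is zero), data (`Q^d`, on
#' the intensity gap) and edge (`R^e`, on the edge-value gap). All lie in
#' `(0, 1]`.
#'
#' @param i,j lattice coordinates, numeric length-2 `c(row, col)` (or equal-
#'   length matrices of coordinates).
#' @param sigma_p,sigma_q,sigma_r positive bandwidths.
#' @param I_i,I_j node intensities.
#' @param B_i,B_j node edge values.
#' @name affinities
NULL

#' @rdname affinities
#' @export
spatial_affinity <- function(i, j, sigma_p) {
  if (sigma_p <= 0) stop_arg("sigma_p must be > 0")
  d2 <- sum((as.numeric(i) - as.numeric(j))^2)
  exp(-d2 / (2 * sigma_p^2))
}

#' @rdname affinities
#' @export
data_affinity <- function(I_i, I_j, sigma_q) {
  if (sigma_q <= 0) stop_arg("sigma_q must be > 0")
  exp(-(I_i - I_j)^2 / (2 * sigma_q^2))
}

#' @rdname affinities
#' @export
edge_affinity <- function(B_i, B_j, sigma_r) {
  if (sigma_r <= 0) stop_arg("sigma_r must be > 0")
  exp(-(B_i - B_j)^2 / (2 * sigma_r^2))
}

#' Parameters of the stochastic clique structure
#'
#' @param sigma_p,sigma_q,sigma_r affinity bandwidths (`sigma_q = NULL`
#'   resolves to 0.1 x intensity range at build time).
#' @param gamma sparsity threshold (>= 0); 0 keeps every in-window pair.
#' @param window_radius truncation radius in voxels for the "fully
#'   connected" candidate set (the spatial affinity is negligible beyond a
#'   few `sigma_p`).
#' @param mode `"deterministic"` thresholds the affinity product at `gamma`;
#'   `"stochastic"` compares it against `gamma * u`, `u ~ U(0, 1)` per pair.
#' @param seed RNG seed for stochastic mode.
#' @export
indicator_params <- function(sigma_p = 3, sigma_q = NULL, sigma_r = 0.1,
                             gamma = 0.02, window_radius = 9L,
                             mode = c("deterministic", "stochastic"),
                             seed = 1L) {
  mode <- match.arg(mode)
  if (sigma_p <= 0 || sigma_r <= 0 || (!is.null(sigma_q) && sigma_q <= 0))
    stop_arg("affinity bandwidths must be > 0")
  if (gamma < 0) stop_arg("gamma must be >= 0")
  structure(list(sigma_p = sigma_p, sigma_q = sigma_q, sigma_r = sigma_r,
                 gamma = gamma, window_radius = as.integer(window_radius),
                 mode = mode, seed = as.integer(seed)),
            class = "indicator_params")
}

resolve_sigma_q <- function(params, image) {
  if (!is.null(params$sigma_q)) return(params$sigma_q)
  max(0.1 * diff(range(image)), 1e-8)
}

#' Stochastic indicator for a single node pair
#'
#' Evaluates whether nodes i and j form a pairwise clique: 1 iff
#' `P^s * Q^d * R^e >= gamma` (deterministic) or `>= gamma * u` with a
#' uniform draw per pair (stochastic; pass `u`, or leave `NULL` to draw from
#' the current RNG stream).
#'
#' @param i,j `c(row, col)` lattice coordinates.
#' @param image intensity matrix.
#' @param edges edge map matrix (same shape).
#' @param params `indicator_params`.
#' @param u optional uniform variate for stochastic mode.
#' @return 0 or 1.
#' @export
indicator <- function(i, j, image, edges, params, u = NULL) {
  sq <- resolve_sigma_q(params, image)
  p <- spatial_affinity(i, j, params$sigma_p) *
    data_affinity(image[i[1], i[2]], image[j[1], j[2]], sq) *
    edge_affinity(edges[i[1], i[2]], edges[j[1], j[2]], params$sigma_r)
  thr <- if (params$mode == "stochastic") {
    if (is.null(u)) u <- stats::runif(1L)
    params$gamma * u
  } else params$gamma
  as.integer(p >= thr)
}

#' Build the realized pairwise clique structure over a slice
#'
#' Sweeps every canonical in-window offset, evaluates the three-way affinity
#' product for all node pairs at that offset, and keeps the pairs whose
#' stochastic indicator fires. Pairs are stored once, canonically (i before
#' j in column-major order), and the structure is deterministic under a
#' fixed seed.
#'
#' @param image intensity matrix the data affinity reads (typically the
#'   interpolated initial estimate; the graph stays fixed afterwards).
#' @param edges matching edge map.
#' @param params `indicator_params`.
#' @return A `neighbor_sampler`: list with integer pair vectors `i`, `j`
#'   (column-major linear indices), `dist` (Euclidean voxel distance per
#'   pair), `shape`, `n` and the resolved parameters.
#' @export
build_sampler <- function(image, edges, params) {
  if (!all(dim(image) == dim(edges)))
    stop_arg("image and edges must share a shape")
  nz <- nrow(image); nx <- ncol(image)
  n <- nz * nx
  r <- params$window_radius
  sq <- resolve_sigma_q(params, image)
  offsets <- list()
  for (dz in 0:r) for (dx in (-r):r) {
    if (dz == 0L && dx <= 0L) next      # canonical half-window
    offsets[[length(offsets) + 1L]] <- c(dz, dx)
  }
  stochastic <- params$mode == "stochastic"
  if (stochastic) set.seed(params$seed)
  ii <- jj <- list(); dd <- numeric(0)
  for (o in offsets) {
    dz <- o[1]; dx <- o[2]
    if (dz >= nz || abs(dx) >= nx) next
    rows_i <- seq_len(nz - dz); rows_j <- rows_i + dz
    if (dx >= 0) { cols_i <- seq_len(nx - dx); cols_j <- cols_i + dx }
    else         { cols_i <- seq_len(nx + dx) - dx; cols_j <- cols_i + dx }
    P <- exp(-(dz^2 + dx^2) / (2 * params$sigma_p^2))
    I1 <- image[rows_i, cols_i, drop = FALSE]
    I2 <- image[rows_j, cols_j, drop = FALSE]
    B1 <- edges[rows_i, cols_i, drop = FALSE]
    B2 <- edges[rows_j, cols_j, drop = FALSE]
    prod <- P * exp(-(I1 - I2)^2 / (2 * sq^2)) *
      exp(-(B1 - B2)^2 / (2 * params$sigma_r^2))
    thr <- if (stochastic)
      params$gamma * matrix(stats::runif(length(prod)), nrow(prod))
    else params$gamma
    sel <- prod >= thr
    if (!any(sel)) next
    idx_i <- outer(rows_i, (cols_i - 1L) * nz, `+`)
    idx_j <- outer(rows_j, (cols_j - 1L) * nz, `+`)
    ii[[length(ii) + 1L]] <- idx_i[sel]
    jj[[length(jj) + 1L]] <- idx_j[sel]
    dd <- c(dd, rep(sqrt(dz^2 + dx^2), sum(sel)))
  }
  i <- as.integer(unlist(ii) %||% integer(0))
  j <- as.integer(unlist(jj) %||% integer(0))
  structure(list(i = i, j = j, dist = dd, n = n, shape = c(nz, nx),
                 sigma_q = sq, params = params),
            class = "neighbor_sampler")
}

#' @rdname build_sampler
#' @param x a `neighbor_sampler`.
#' @param ... unused.
#' @export
as.data.frame.neighbor_sampler <- function(x, ...) {
  data.frame(i = x$i, j = x$j, dist = x$dist)
}

#' Realized degree of every node
#'
#' @param sampler a `neighbor_sampler`.
#' @return integer vector of length `sampler$n`.
#' @export
sampler_degree <- function(sampler) {
  tabulate(c(sampler$i, sampler$j), nbins = sampler$n)
}
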