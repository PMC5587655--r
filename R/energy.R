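#' Fisher-Tippett negative log-likelihood of a log-domain residual
#'
#' The log-compressed speckle envelope residual `r = log g - log H(f)`
#' follows the density `p(r) = 2 exp[(2r - ln 2 sigma^2) -
#' exp(2r - ln 2 sigma^2)]`; this returns `-log p(r)`, which is smooth and
#' strictly convex in `r` with its minimum at `r* = ln(2 sigma^2) / 2`.
#'
#' @param r residual(s), log domain.
#' @param sigma scale parameter (> 0).
#' @return numeric of the same length as `r`.
#' @export
fisher_tippett_nll <- function(r, sigma) {
  if (!is_scalar_num(sigma) || sigma <= 0) stop_arg("sigma must be > 0")
  t <- 2 * r - log(2 * sigma^2)
  if (any(t > 700)) {
    warning("Fisher-Tippett exponent clipped at 700", call. = FALSE)
    t <- pmin(t, 700)
  }
  -(log(2) + t - exp(t))
}

# d/dr of fisher_tippett_nll
fisher_tippett_nll_grad <- function(r, sigma) {
  t <- pmin(2 * r - log(2 * sigma^2), 700)
  -2 + 2 * exp(t)
}

#' Unary (data) term parameters
#'
#' @param sigma Fisher-Tippett scale of the speckle model.
#' @param alpha weight of the observed data term (>= 0).
#' @param psf_bank `psf_bank` used as the system operator H; `NULL` means
#'   identity.
#' @param psf_domain `"log"` applies H directly to the log image (fast,
#'   approximate); `"linear"` exponentiates, blurs, and takes the log (the
#'   exact forward model).
#' @param log_floor clip level before logs in linear mode.
#' @export
unary_params <- function(sigma = 0.5, alpha = 1, psf_bank = NULL,
                         psf_domain = c("log", "linear"),
                         log_floor = 1e-12) {
  psf_domain <- match.arg(psf_domain)
  if (sigma <= 0) stop_arg("sigma must be > 0")
  if (alpha < 0) stop_arg("alpha must be >= 0")
  structure(list(sigma = sigma, alpha = alpha, psf_bank = psf_bank,
                 psf_domain = psf_domain, log_floor = log_floor),
            class = "unary_params")
}

#' Pairwise (smoothness) term parameters
#'
#' @param beta pairwise weight (>= 0).
#' @param sigma_sp spatial-proximity bandwidth (voxels; first-power distance
#'   decay).
#' @param sigma_fov first-order-variation bandwidth (`NULL`: 0.1 x range of
#'   the reference image at evaluation time; first-power intensity decay).
#' @param epsilon_abs Charbonnier smoothing of `|.|` (`NULL`: 1e-3 x range).
#' @param use_spatial include the spatial proximity factor in the pair
#'   weight (the printed penalty argument list only carries intensities;
#'   both terms are described in the text, so the default keeps both).
#' @export
pairwise_params <- function(beta = 0.5, sigma_sp = 3, sigma_fov = NULL,
                            epsilon_abs = NULL, use_spatial = TRUE) {
  if (beta < 0) stop_arg("beta must be >= 0")
  if (sigma_sp <= 0 || (!is.null(sigma_fov) && sigma_fov <= 0))
    stop_arg("bandwidths must be > 0")
  if (!is.null(epsilon_abs) && epsilon_abs <= 0)
    stop_arg("epsilon_abs must be > 0")
  structure(list(beta = beta, sigma_sp = sigma_sp, sigma_fov = sigma_fov,
                 epsilon_abs = epsilon_abs, use_spatial = use_spatial),
            class = "pairwise_params")
}

resolve_pairwise <- function(params, g) {
  rng <- diff(range(g))
  list(beta = params$beta, sigma_sp = params$sigma_sp,
       sigma_fov = params$sigma_fov %||% max(0.1 * rng, 1e-8),
       epsilon_abs = params$epsilon_abs %||% max(1e-3 * rng, 1e-8),
       use_spatial = params$use_spatial)
}

#' Pairwise penalty factors
#'
#' `w_spatial` decays with the first power of the Euclidean inter-node
#' distance (voxel units); `w_fov` decays with the first power of the
#' intensity gap between the observed (reference) values, damping the
#' smoothing penalty across tissue transitions so boundaries survive.
#'
#' @param i,j `c(row, col)` coordinates (or `d` a precomputed distance).
#' @param sigma_sp,sigma_fov positive bandwidths.
#' @param g_i,g_j reference intensities.
#' @name pair_weights
NULL

#' @rdname pair_weights
#' @export
w_spatial <- function(i, j, sigma_sp) {
  if (sigma_sp <= 0) stop_arg("sigma_sp must be > 0")
  d <- sqrt(sum((as.numeric(i) - as.numeric(j))^2))
  exp(-d / (2 * sigma_sp^2))
}

w_spatial_dist <- function(d, sigma_sp) exp(-d / (2 * sigma_sp^2))

#' @rdname pair_weights
#' @export
w_fov <- function(g_i, g_j, sigma_fov) {
  if (sigma_fov <= 0) stop_arg("sigma_fov must be > 0")
  exp(-abs(g_i - g_j) / (2 * sigma_fov^2))
}

# reference image the pair weights read: the filled lattice (cached on the
# observation by the optimizer via attr(obs, "reference"))
reference_image <- function(obs) {
  ref <- attr(obs, "reference")
  if (!is.null(ref)) return(ref)
  if (inherits(obs, "observed_envelope")) interpolate_to_lattice(obs) else obs
}

# H(F) in the log domain under the configured mode
psf_log_forward <- function(F_log, params, pitch_z = 1, origin_z = 0) {
  bank <- params$psf_bank
  if (is.null(bank) || identical(bank$mode, "identity")) return(F_log)
  if (params$psf_domain == "log")
    apply_psf(F_log, bank, pitch_z = pitch_z, origin_z = origin_z)
  else
    log(pmax(apply_psf(exp(F_log), bank, pitch_z = pitch_z,
                       origin_z = origin_z), params$log_floor))
}

#' Unary energy over a slice
#'
#' `alpha * sum over sampled voxels (cr = 0)` of the Fisher-Tippett negative
#' log-likelihood of `log g - log H(F)`; voxels under the uncertainty layer
#' (cr = 1) contribute exactly zero.
#'
#' @param F_log current estimate, log domain (matrix).
#' @param obs an `observed_envelope`.
#' @param params `unary_params`.
#' @return scalar energy.
#' @export
unary_energy <- function(F_log, obs, params) {
  sampled <- obs$mask == 1L
  if (!any(sampled)) return(0)
  HF <- psf_log_forward(F_log, params, obs$pitch[1], obs$origin[1])
  r <- obs$values[sampled] - HF[sampled]
  params$alpha * sum(fisher_tippett_nll(r, params$sigma))
}

#' Pairwise energy over the realized cliques
#'
#' `beta * sum over realized pairs of s(f_i - f_j) * w_sp * w_fov`, with
#' `s(x) = sqrt(x^2 + eps^2) - eps` the smoothed absolute value. The
#' penalty-weight product lets either spatial distance or an observed
#' intensity jump veto the smoothing of a pair.
#'
#' @param F_log current estimate, log domain.
#' @param obs `observed_envelope` (its filled lattice provides the reference
#'   intensities) or a plain reference matrix.
#' @param sampler `neighbor_sampler` built on the same lattice.
#' @param params `pairwise_params`.
#' @return scalar energy.
#' @export
pairwise_energy <- function(F_log, obs, sampler, params) {
  if (length(sampler$i) == 0L) return(0)
  g <- reference_image(obs)
  pp <- resolve_pairwise(params, g)
  d <- F_log[sampler$i] - F_log[sampler$j]
  s <- sqrt(d^2 + pp$epsilon_abs^2) - pp$epsilon_abs
  w <- w_fov(g[sampler$i], g[sampler$j], pp$sigma_fov)
  if (pp$use_spatial) w <- w * w_spatial_dist(sampler$dist, pp$sigma_sp)
  pp$beta * sum(s * w)
}

#' Total MAP energy and its breakdown
#'
#' @inheritParams pairwise_energy
#' @param unary_params,pairwise_params term parameters.
#' @return list with `unary_total`, `pairwise_total`, `total`.
#' @export
total_energy <- function(F_log, obs, sampler, unary_params, pairwise_params) {
  u <- unary_energy(F_log, obs, unary_params)
  p <- pairwise_energy(F_log, obs, sampler, pairwise_params)
  list(unary_total = u, pairwise_total = p, total = u + p)
}

#' Analytic gradient of the total energy with respect to the log estimate
#'
#' The unary part chains the Fisher-Tippett score through the PSF operator's
#' exact adjoint (and through the exponential in linear mode); the pairwise
#' part scatters `beta * s'(f_i - f_j) * w` to the two endpoints with
#' opposite signs.
#'
#' @inheritParams total_energy
#' @return gradient matrix, same shape as `F_log`.
#' @export
energy_gradient <- function(F_log, obs, sampler, unary_params,
                            pairwise_params) {
  up <- unary_params
  grad <- matrix(0, nrow(F_log), ncol(F_log))
  sampled <- obs$mask == 1L
  if (up$alpha > 0 && any(sampled)) {
    bank <- up$psf_bank
    identity_h <- is.null(bank) || identical(bank$mode, "identity")
    if (identity_h) {
      r <- matrix(0, nrow(F_log), ncol(F_log))
      r[sampled] <- obs$values[sampled] - F_log[sampled]
      sc <- matrix(0, nrow(F_log), ncol(F_log))
      sc[sampled] <- fisher_tippett_nll_grad(r[sampled], up$sigma)
      grad <- grad - up$alpha * sc
    } else if (up$psf_domain == "log") {
      HF <- apply_psf(F_log, bank, pitch_z = obs$pitch[1],
                      origin_z = obs$origin[1])
      sc <- matrix(0, nrow(F_log), ncol(F_log))
      sc[sampled] <- fisher_tippett_nll_grad(obs$values[sampled] - HF[sampled],
                                             up$sigma)
      grad <- grad - up$alpha *
        apply_psf(sc, bank, adjoint = TRUE, pitch_z = obs$pitch[1],
                  origin_z = obs$origin[1])
    } else {
      Fe <- exp(F_log)
      u <- pmax(apply_psf(Fe, bank, pitch_z = obs$pitch[1],
                          origin_z = obs$origin[1]), up$log_floor)
      sc <- matrix(0, nrow(F_log), ncol(F_log))
      sc[sampled] <- fisher_tippett_nll_grad(obs$values[sampled] -
                                               log(u)[sampled], up$sigma)
      grad <- grad - up$alpha * Fe *
        apply_psf(sc / u, bank, adjoint = TRUE, pitch_z = obs$pitch[1],
                  origin_z = obs$origin[1])
    }
  }
  if (pairwise_params$beta > 0 && length(sampler$i) > 0L) {
    g <- reference_image(obs)
    pp <- resolve_pairwise(pairwise_params, g)
    d <- F_log[sampler$i] - F_log[sampler$j]
    sprime <- d / sqrt(d^2 + pp$epsilon_abs^2)
    w <- w_fov(g[sampler$i], g[sampler$j], pp$sigma_fov)
    if (pp$use_spatial) w <- w * w_spatial_dist(sampler$dist, pp$sigma_sp)
    contrib <- pp$beta * sprime * w
    n <- length(F_log)
    grad <- grad + matrix(scatter_add(n, sampler$i, contrib) -
                            scatter_add(n, sampler$j, contrib),
                          nrow(F_log), ncol(F_log))
  }
  grad
}
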