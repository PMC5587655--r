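#' Reconstruction configuration
#'
#' Bundles every hyperparameter of the MAP reconstruction: unary and
#' pairwise term weights, stochastic clique parameters, and the gradient
#' descent controls. Defaults are implementation choices (the source model
#' family states none).
#'
#' @param unary `unary_params`.
#' @param pairwise `pairwise_params`.
#' @param indicator `indicator_params`.
#' @param step_size initial gradient-descent step (> 0).
#' @param max_iters iteration cap (>= 1).
#' @param rel_tol relative energy-change stopping threshold (> 0).
#' @param backtrack_factor step multiplier on an energy increase.
#' @param max_halvings backtracking attempts per iteration.
#' @param seed RNG seed (stochastic clique mode).
#' @export
recon_config <- function(unary = unary_params(),
                         pairwise = pairwise_params(),
                         indicator = indicator_params(),
                         step_size = 0.1, max_iters = 500L,
                         rel_tol = 1e-6, backtrack_factor = 0.5,
                         max_halvings = 30L, seed = 1L) {
  if (step_size <= 0) stop_arg("step_size must be > 0")
  if (max_iters < 1L) stop_arg("max_iters must be >= 1")
  if (rel_tol <= 0) stop_arg("rel_tol must be > 0")
  structure(list(unary = unary, pairwise = pairwise, indicator = indicator,
                 step_size = step_size, max_iters = as.integer(max_iters),
                 rel_tol = rel_tol, backtrack_factor = backtrack_factor,
                 max_halvings = as.integer(max_halvings),
                 seed = as.integer(seed)),
            class = "recon_config")
}

#' MAP reconstruction of a single slice
#'
#' Initializes from the linearly interpolated lattice, freezes the edge map
#' and the stochastic clique structure computed from that initial estimate,
#' and descends the total energy with backtracking step halving so that the
#' accepted energy trace is non-increasing. Stops when the relative energy
#' change falls below `rel_tol` or at `max_iters`.
#'
#' @param obs an `observed_envelope` slice.
#' @param bank optional `psf_bank` serving as the system operator H
#'   (overrides `config$unary$psf_bank`); `NULL` keeps the configured one.
#' @param config a `recon_config`.
#' @return A `reconstruction_result`: `estimate_log` (matrix),
#'   `estimate` (linear domain), `initial` (the interpolation
#'   initialization), `trace` (data.frame: iter, unary, pairwise, total,
#'   step), `iterations`, `converged`, `n_pairs`.
#' @export
reconstruct_slice <- function(obs, bank = NULL, config = recon_config()) {
  if (sum(obs$mask) < 2L)
    stop_arg("slice has fewer than 2 sampled voxels")
  up <- config$unary
  if (!is.null(bank)) up$psf_bank <- bank
  init <- interpolate_to_lattice(obs)
  attr(obs, "reference") <- init
  ip <- config$indicator
  ip$seed <- config$seed
  # edge values come from a lightly smoothed initialization: Sobel on raw
  # speckle measures noise, and the edge affinity can only guide the clique
  # structure if B reflects structure rather than speckle
  edges <- edge_map(box_smooth(init))
  sampler <- build_sampler(init, edges, ip)
  F_log <- init
  e <- total_energy(F_log, obs, sampler, up, config$pairwise)
  trace <- list(c(0, e$unary_total, e$pairwise_total, e$total, NA_real_))
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(config$max_iters)) {
    grad <- energy_gradient(F_log, obs, sampler, up, config$pairwise)
    if (any(!is.finite(grad)))
      stop_arg("non-finite gradient at iteration ", it)
    gmax <- max(abs(grad))
    if (gmax == 0) { converged <- TRUE; break }
    # step normalized to at most eta log-units per voxel: the Fisher-Tippett
    # score is exponentially stiff on one side, and a raw gradient step sized
    # for typical voxels overshoots badly on bright speckle spikes
    dirn <- grad / gmax
    eta <- config$step_size
    accepted <- FALSE
    for (h in 0:config$max_halvings) {
      F_try <- F_log - eta * dirn
      e_try <- total_energy(F_try, obs, sampler, up, config$pairwise)
      if (!is.finite(e_try$total))
        stop_arg("non-finite energy at iteration ", it)
      if (e_try$total <= e$total) { accepted <- TRUE; break }
      eta <- eta * config$backtrack_factor
    }
    if (!accepted) { converged <- TRUE; break }    # no descent direction step
    de <- e$total - e_try$total
    F_log <- F_try
    e <- e_try
    iters <- it
    trace[[length(trace) + 1L]] <-
      c(it, e$unary_total, e$pairwise_total, e$total, eta)
    if (de <= config$rel_tol * max(abs(e$total), .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  tr <- as.data.frame(do.call(rbind, trace))
  names(tr) <- c("iter", "unary", "pairwise", "total", "step")
  structure(list(estimate_log = F_log, estimate = exp(F_log), initial = init,
                 trace = tr, iterations = iters, converged = converged,
                 n_pairs = length(sampler$i)),
            class = "reconstruction_result")
}

#' Slice-independent volume reconstruction
#'
#' Applies `reconstruct_slice` to each slice of a volume; slices are
#' mutually independent, so any processing order yields the same stack.
#' Per-slice failures are collected and reported together with their slice
#' indices.
#'
#' @param obs_volume list of `observed_envelope` slices.
#' @param bank optional `psf_bank`.
#' @param config `recon_config`.
#' @return list with `slices` (per-slice `reconstruction_result`s) and
#'   `estimate` (3-D array, slice index last).
#' @export
reconstruct_volume <- function(obs_volume, bank = NULL,
                               config = recon_config()) {
  if (inherits(obs_volume, "observed_envelope"))
    obs_volume <- list(obs_volume)
  res <- vector("list", length(obs_volume))
  errs <- character(0)
  for (s in seq_along(obs_volume)) {
    r <- tryCatch(reconstruct_slice(obs_volume[[s]], bank, config),
                  error = function(e) e)
    if (inherits(r, "error"))
      errs <- c(errs, paste0("slice ", s, ": ", conditionMessage(r)))
    else res[[s]] <- r
  }
  if (length(errs))
    stop_arg("reconstruction failed for ", length(errs), " slice(s):\n  ",
             paste(errs, collapse = "\n  "))
  est <- vapply(res, function(r) r$estimate_log,
                res[[1L]]$estimate_log)
  list(slices = res,
       estimate = array(est, c(dim(res[[1L]]$estimate_log), length(res))))
}

#' Interpolation-only baseline
#'
#' The no-model comparator: the linearly interpolated lattice itself,
#' independent of every CRF hyperparameter. Stands in for the real-time
#' interpolation-based pipeline that the random-field reconstruction is
#' measured against.
#'
#' @param obs an `observed_envelope`.
#' @return matrix of log-envelope values.
#' @export
baseline_interpolation <- function(obs) interpolate_to_lattice(obs)
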