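# Shared fixture builders; everything is generated in code at test time.

# fully sampled observation over a given log-image
obs_full <- function(values_log, sigma = 0.5) {
  m <- matrix(1L, nrow(values_log), ncol(values_log))
  observed_envelope(values_log, m, sigma)
}

# observation with a given 0/1 mask (values zeroed where unsampled)
obs_masked <- function(values_log, mask, sigma = 0.5) {
  observed_envelope(values_log * mask, mask, sigma)
}

# full-window sampler keeping every pair (gamma = 0)
sampler_full <- function(image) {
  ip <- indicator_params(gamma = 0,
                         window_radius = max(dim(image)))
  build_sampler(image, edge_map(image), ip)
}

# brute-force pair enumeration via the scalar indicator (oracle)
oracle_pairs <- function(image, edges, params) {
  nz <- nrow(image); nx <- ncol(image)
  coords <- expand.grid(r = seq_len(nz), c = seq_len(nx))
  idx <- function(r, c) r + (c - 1L) * nz
  out <- list()
  for (a in seq_len(nrow(coords))) for (b in seq_len(nrow(coords))) {
    if (b <= a) next
    i <- c(coords$r[a], coords$c[a]); j <- c(coords$r[b], coords$c[b])
    if (max(abs(i - j)) > params$window_radius) next
    if (indicator(i, j, image, edges, params) == 1L)
      out[[length(out) + 1L]] <- c(idx(i[1], i[2]), idx(j[1], j[2]))
  }
  if (!length(out)) return(matrix(integer(0), 0, 2))
  do.call(rbind, out)
}

# canonical sorted pair matrix from a sampler
sampler_pairs <- function(s) {
  p <- cbind(pmin(s$i, s$j), pmax(s$i, s$j))
  p[order(p[, 1], p[, 2]), , drop = FALSE]
}

# Gumbel-minimum CDF (distribution of 2*eps - log(2 sigma^2))
pgumbel_min <- function(q) 1 - exp(-exp(q))

fast_scenario <- function(seed = 1L) {
  cfg <- scenario_lshape(seed)
  cfg$recon$max_iters <- 25L
  cfg
}
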