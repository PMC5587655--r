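# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

#' @noRd
rot180 <- function(k) k[nrow(k):1, ncol(k):1, drop = FALSE]

# Zero-padded linear 2-D convolution, "same" output, via FFT.
# Kernel dimensions must be odd so that the centre tap is well defined; the
# adjoint of this operator is then exactly correlation with the same kernel,
# i.e. conv2_same(x, rot180(k)).
conv2_same <- function(x, k) {
  if (nrow(k) %% 2 == 0L || ncol(k) %% 2 == 0L)
    stop_arg("convolution kernels must have odd dimensions")
  if (nrow(k) > nrow(x) || ncol(k) > ncol(x))
    stop_arg("kernel (", nrow(k), "x", ncol(k), ") larger than image (",
             nrow(x), "x", ncol(x), ")")
  nr <- nrow(x) + nrow(k) - 1L
  nc <- ncol(x) + ncol(k) - 1L
  px <- matrix(0, nr, nc); px[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  pk <- matrix(0, nr, nc); pk[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  full <- Re(stats::fft(stats::fft(px) * stats::fft(pk), inverse = TRUE)) / (nr * nc)
  r0 <- (nrow(k) - 1L) %/% 2L
  c0 <- (ncol(k) - 1L) %/% 2L
  full[r0 + seq_len(nrow(x)), c0 + seq_len(ncol(x)), drop = FALSE]
}

# 1-D linear convolution (full), via FFT; used by the impulse-response chain.
conv1_full <- function(a, b) {
  n <- length(a) + length(b) - 1L
  m <- stats::nextn(n, 2)
  pa <- c(a, numeric(m - length(a)))
  pb <- c(b, numeric(m - length(b)))
  Re(stats::fft(stats::fft(pa) * stats::fft(pb), inverse = TRUE))[seq_len(n)] / m
}

# Magnitude of the analytic signal (Hilbert envelope) of a real vector.
envelope_hilbert <- function(x) {
  n <- length(x)
  if (n < 2L) return(abs(x))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0L) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2L:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2L:((n + 1L) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Scatter-add val into a vector of length n at (possibly repeated) indices.
scatter_add <- function(n, idx, val) {
  out <- numeric(n)
  s <- rowsum(val, idx, reorder = FALSE)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

# FNV-1a hash of a character scalar, as 8 hex digits; used for config
# fingerprints in artifact sidecars (no cryptographic intent).
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # multiply mod 2^32 in two 16-bit halves (doubles stay exact)
    hi16 <- h %/% 65536
    lo16 <- h %% 65536
    h <- (((hi16 * m) %% 65536) * 65536 + lo16 * m) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Derive a per-stage 31-bit seed from a master seed and a label.
derive_seed <- function(seed, label) {
  bytes <- utf8ToInt(label)
  (as.numeric(seed) * 7919 + sum(bytes * seq_along(bytes))) %% 2147483647
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
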