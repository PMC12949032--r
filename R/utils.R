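# Internal helpers: seeding, hashing, convolution.

# Deterministic per-(spot, stage) seed stream so per-spot results are
# independent of delivery order.
derive_seed <- function(base_seed, spot_key, stage) {
  stage_code <- switch(stage, sample = 1L, transport = 2L, film = 3L,
                       output = 4L, stop("unknown stage"))
  as.integer((as.double(base_seed) * 100003 + spot_key * 7919 +
                stage_code * 131) %% 2147483587)
}

# Polynomial rolling hash (mod 2^31 - 1, exact in doubles) over the
# serialization of an R object; returned as a hex string. Used for
# config/manifest identity only, not cryptography.
config_hash <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b + 1) %% 2147483647
  sprintf("%08x", h)
}

# Discrete Gaussian kernel (sum 1); sigma in bins.
gauss_kernel <- function(sigma_bins) {
  hl <- max(1L, ceiling(4 * sigma_bins))
  k <- stats::dnorm(seq(-hl, hl), sd = sigma_bins)
  k / sum(k)
}

# Convolve each column of a matrix with a Gaussian (zero-padded edges).
# sigma in bins along the first dimension; below 0.25 bins the kernel is
# effectively a delta and the input is returned unchanged.
blur_columns <- function(m, sigma_bins) {
  if (sigma_bins < 0.25) return(m)
  k <- gauss_kernel(sigma_bins)
  hl <- (length(k) - 1L) / 2L
  n <- nrow(m)
  np <- stats::nextn(n + 2L * hl, c(2, 3, 5))
  pad <- matrix(0, np, ncol(m))
  pad[seq_len(n) + hl, ] <- m
  kf <- stats::fft(c(k, rep(0, np - length(k))))
  out <- Re(stats::mvfft(stats::mvfft(pad) * kf, inverse = TRUE)) / np
  out[seq_len(n) + 2L * hl, , drop = FALSE]
}

# Separable 2-D Gaussian blur of a (nx, ny) matrix; sigmas in bins.
blur_xy <- function(m, sigma_x_bins, sigma_y_bins) {
  m <- blur_columns(m, sigma_x_bins)
  t(blur_columns(t(m), sigma_y_bins))
}
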