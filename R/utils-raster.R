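# Small raster helpers shared by the generator and the measurement modules.
# Convention: matrices are [row = y, col = x], 1-based, pixel centers at
# integer coordinates.

coord_grids <- function(h, w) {
  list(
    y = matrix(rep(seq_len(h), times = w), h, w),
    x = matrix(rep(seq_len(w), each = h), h, w)
  )
}

# isotropic Gaussian blob, peak amplitude at (cy, cx)
gauss_blob <- function(g, cy, cx, sigma, peak) {
  peak * exp(-((g$y - cy)^2 + (g$x - cx)^2) / (2 * sigma^2))
}

# filled ellipse mask by pixel-center inclusion (angle in radians, measured
# from the +x axis towards +y)
ellipse_mask <- function(g, cy, cx, semi_major, semi_minor, angle_rad) {
  dy <- g$y - cy
  dx <- g$x - cx
  u <- dx * cos(angle_rad) + dy * sin(angle_rad)
  v <- -dx * sin(angle_rad) + dy * cos(angle_rad)
  (u / semi_major)^2 + (v / semi_minor)^2 <= 1
}

# separable Gaussian blur with edge replication; sigma = 0 returns the input
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_1d <- function(m) {
    # replicate-pad rows, convolve each column of the padded matrix
    padded <- m[c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r)), , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_len(ncol(m))) {
      out[, j] <- stats::filter(padded[, j], k, sides = 2)[(r + 1):(r + nrow(m))]
    }
    out
  }
  t(blur_1d(t(blur_1d(img))))
}

# deterministic sub-seed per (movie seed, stream index), kept below 2^31
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 131071 + stream * 7919) %% 2147483629)
}
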