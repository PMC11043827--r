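# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
# All generator functions funnel their randomness through this so that
# identical spec + seed gives bit-identical output regardless of call order.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Derive a child seed from a parent seed and an index, staying inside the
# 32-bit signed range R requires for set.seed().
child_seed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 1299709) %% 2147483629
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits.
# Used to stamp pipeline outputs with their configuration.  Arithmetic is done
# in doubles split into 16-bit halves to stay exact (no 32-bit ints in base R).
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    # xor the low byte
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # multiply modulo 2^32: h = hi*2^16 + lo
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  # h is a double <= 2^32 - 1; format as 8 hex digits via two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Zero-truncated Poisson draw (n values, mean of the *untruncated* parent
# lambda); used for nucleoid counts of cells that are not Rho-0 so a
# mtDNA-positive cell can never draw zero puncta.
rpois_positive <- function(n, lambda) {
  if (n == 0L) return(integer(0))
  lambda <- rep_len(lambda, n)
  x <- stats::rpois(n, lambda)
  while (any(x == 0L)) {
    i <- which(x == 0L)
    x[i] <- stats::rpois(length(i), lambda[i])
  }
  x
}

# Add a 2-D Gaussian blob to matrix `img` (modified copy returned).
# Centre in fractional pixel coordinates (row, col), sd in pixels, `peak` is
# the amplitude at the centre.
stamp_gaussian <- function(img, row, col, sd_r, sd_c, peak, extent = 4) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- max(1L, floor(row - extent * sd_r)); r1 <- min(nr, ceiling(row + extent * sd_r))
  c0 <- max(1L, floor(col - extent * sd_c)); c1 <- min(nc, ceiling(col + extent * sd_c))
  if (r0 > r1 || c0 > c1) return(img)
  rr <- r0:r1; cc <- c0:c1
  gr <- exp(-((rr - row)^2) / (2 * sd_r^2))
  gc <- exp(-((cc - col)^2) / (2 * sd_c^2))
  img[rr, cc] <- img[rr, cc] + peak * outer(gr, gc)
  img
}

# Bilinear "splat" of point masses onto a raster: each (row, col, mass)
# impulse is spread over its four neighbouring pixels.  A single Gaussian
# blur of the result then renders all points with sub-pixel accuracy.
splat_points <- function(img, row, col, mass) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  for (dr in 0:1) for (dc in 0:1) {
    w <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
    r <- r0 + dr; c <- c0 + dc
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc & w > 0
    if (any(ok)) {
      # accumulate via rowsum so coincident points add up instead of
      # overwriting each other
      lin <- (c[ok] - 1) * nr + r[ok]
      acc <- rowsum(mass[ok] * w[ok], lin)
      img[as.integer(rownames(acc))] <- img[as.integer(rownames(acc))] + acc[, 1]
    }
  }
  img
}

`%||%` <- function(a, b) if (is.null(a)) b else a
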