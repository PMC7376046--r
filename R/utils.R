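# Shared numeric helpers: seeded evaluation, bilinear sampling, Gaussian blur.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All stochastic operations in the package route through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_ctc <- function(class, fmt, ...) {
  stop(structure(class = c(class, "ctcscope_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

# Bilinear interpolation at continuous 0-based (r, c) with edge replication.
# r, c are equal-length vectors; returns a vector of sampled intensities.
bilinear_sample <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 0), nr - 1)
  c <- pmin(pmax(c, 0), nc - 1)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, nr - 1); c1 <- pmin(c0 + 1, nc - 1)
  fr <- r - r0; fc <- c - c0
  i00 <- img[cbind(r0 + 1, c0 + 1)]
  i01 <- img[cbind(r0 + 1, c1 + 1)]
  i10 <- img[cbind(r1 + 1, c0 + 1)]
  i11 <- img[cbind(r1 + 1, c1 + 1)]
  (1 - fr) * ((1 - fc) * i00 + fc * i01) + fr * ((1 - fc) * i10 + fc * i11)
}

# Gaussian smoothing; sigma = 0 is the identity. EBImage's gblur needs a
# kernel that fits the image, so tiny inputs fall back to a dense separable
# convolution with edge renormalization.
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  rad <- max(1L, as.integer(ceiling(3 * sigma)))
  if (2L * rad + 1L < min(dim(x)) ) {
    return(unclass(EBImage::gblur(x, sigma = sigma, radius = rad)))
  }
  k <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  smooth_axis <- function(m, klen) {
    n <- nrow(m)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      idx <- (i - rad):(i + rad)
      ok <- idx >= 1 & idx <= n
      K[i, idx[ok]] <- klen[ok] / sum(klen[ok])
    }
    K %*% m
  }
  t(smooth_axis(t(smooth_axis(x, k)), k))
}

# half-open bbox intersection area; boxes are c(r0, c0, r1, c1)
bbox_intersection <- function(a, b) {
  h <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  w <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  h * w
}
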