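# Independent brute-force oracles used by the tests. These are written as
# plain scalar/loop implementations, deliberately sharing no code with the
# package internals they check.

# Scalar textbook sRGB (D65, 2 deg) -> L*a*b*, one pixel at a time.
oracleLab <- function(r, g, b) {
  lin <- function(u) {
    u <- u / 255
    if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4
  }
  R <- lin(r); G <- lin(g); B <- lin(b)
  X <- 0.4124564 * R + 0.3575761 * G + 0.1804375 * B
  Y <- 0.2126729 * R + 0.7151522 * G + 0.0721750 * B
  Z <- 0.0193339 * R + 0.1191920 * G + 0.9503041 * B
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  fx <- f(X / 0.95047); fy <- f(Y / 1); fz <- f(Z / 1.08883)
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# Exhaustive queue-based flood fill for connected-component areas.
oracleComponentAreas <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  nbr <- if (connectivity == 4L)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  areas <- integer(0)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || seen[i, j]) next
    queue <- list(c(i, j)); seen[i, j] <- TRUE; area <- 0L
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      area <- area + 1L
      for (k in seq_len(nrow(nbr))) {
        ni <- p[1] + nbr[k, 1]; nj <- p[2] + nbr[k, 2]
        if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
            mask[ni, nj] && !seen[ni, nj]) {
          seen[ni, nj] <- TRUE
          queue <- c(queue, list(c(ni, nj)))
        }
      }
    }
    areas <- c(areas, area)
  }
  areas
}

# Minimum-norm least squares via an explicit SVD pseudoinverse.
oraclePinvSolve <- function(A, y, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% ((t(s$u[, pos, drop = FALSE]) %*% y) / s$d[pos])
}

# Uniform-color RGBImage of the given hue/sat/val (0-255 conversion by base R).
uniformHsvImage <- function(h, s, v, nrow = 8L, ncol = 8L) {
  rgb <- as.vector(grDevices::col2rgb(grDevices::hsv(h, s, v)))
  px <- array(0, dim = c(nrow, ncol, 3L))
  for (k in 1:3) px[, , k] <- rgb[k]
  RGBImage(px)
}

# Small generator config used throughout the unit tests (full-resolution
# images are exercised in the acceptance suite).
smallConfig <- function(...) {
  GeneratorConfig(imageShape = c(96, 160), ...)
}
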