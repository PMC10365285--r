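# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive definitional loops, never the package's
# internal code paths.

# 3D "same" convolution with mirror padding, straight from the definition.
oracle_conv3d <- function(x, W, b) {
  d <- dim(x); k <- dim(W)[1]; r <- k %/% 2
  cin <- dim(W)[4]; cout <- dim(W)[5]
  refl <- function(i, n) if (i < 1) 2 - i else if (i > n) 2 * n - i else i
  y <- array(0, dim = c(d[1:3], cout, d[5]))
  for (n in seq_len(d[5])) for (co in seq_len(cout)) {
    for (z in seq_len(d[3])) for (yy in seq_len(d[2])) for (xx in seq_len(d[1])) {
      s <- b[co]
      for (ci in seq_len(cin)) for (dz in 1:k) for (dy in 1:k) for (dx in 1:k) {
        s <- s + x[refl(xx + dx - 1 - r, d[1]), refl(yy + dy - 1 - r, d[2]),
                   refl(z + dz - 1 - r, d[3]), ci, n] * W[dx, dy, dz, ci, co]
      }
      y[xx, yy, z, co, n] <- s
    }
  }
  y
}

# Block mean by an explicit triple loop over output voxels.
oracle_block_mean <- function(a, f) {
  d <- dim(a); o <- d %/% f
  y <- array(0, dim = o)
  for (k in seq_len(o[3])) for (j in seq_len(o[2])) for (i in seq_len(o[1])) {
    y[i, j, k] <- mean(a[((i - 1) * f + 1):(i * f),
                         ((j - 1) * f + 1):(j * f),
                         ((k - 1) * f + 1):(k * f)])
  }
  y
}

# Definitional RMSE via an explicit accumulation loop.
oracle_rmse <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  sqrt(s / length(a))
}

# Definitional 3D SSIM: per voxel, a jointly normalized truncated Gaussian
# window, weighted moments, and the standard two-term SSIM formula.
oracle_ssim <- function(a, b, L = 1, win = 11L, sigma = 1.5) {
  d <- dim(a); half <- win %/% 2L
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  total <- 0
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    ix <- max(1, i - half):min(d[1], i + half)
    iy <- max(1, j - half):min(d[2], j + half)
    iz <- max(1, k - half):min(d[3], k + half)
    w <- outer(outer(g[ix - i + half + 1], g[iy - j + half + 1]),
               g[iz - k + half + 1])
    w <- w / sum(w)
    wa <- a[ix, iy, iz]; wb <- b[ix, iy, iz]
    mu_a <- sum(w * wa); mu_b <- sum(w * wb)
    va <- sum(w * wa^2) - mu_a^2; vb <- sum(w * wb^2) - mu_b^2
    cab <- sum(w * wa * wb) - mu_a * mu_b
    total <- total + ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
      ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  }
  total / prod(d)
}

# Textbook paired t statistic.
oracle_paired_t <- function(a, b) {
  d <- a - b
  mean(d) / (sd(d) / sqrt(length(d)))
}

# Textbook Welch ANOVA: F* and Welch-Satterthwaite df.
oracle_welch_anova <- function(groups) {
  ni <- vapply(groups, length, numeric(1))
  mi <- vapply(groups, mean, numeric(1))
  vi <- vapply(groups, var, numeric(1))
  wi <- ni / vi
  mw <- sum(wi * mi) / sum(wi)
  k <- length(groups)
  A <- sum(wi * (mi - mw)^2) / (k - 1)
  B <- 1 + (2 * (k - 2) / (k^2 - 1)) * sum((1 - wi / sum(wi))^2 / (ni - 1))
  Fstat <- A / B
  df2 <- (k^2 - 1) / (3 * sum((1 - wi / sum(wi))^2 / (ni - 1)))
  p <- stats::pf(Fstat, k - 1, df2, lower.tail = FALSE)
  list(statistic = Fstat, p = p)
}

# Periodic Gaussian blur of a 2D image (for resolution-estimator tests).
oracle_gauss_blur2d <- function(im, s) {
  if (s == 0) return(im)
  n1 <- nrow(im); n2 <- ncol(im)
  k1 <- function(n) {
    k <- exp(-(c(0:(n %/% 2), -((n - n %/% 2 - 1):1)))^2 / (2 * s^2))
    k / sum(k)
  }
  Re(fft(fft(im) * fft(outer(k1(n1), k1(n2))), inverse = TRUE)) / length(im)
}

# Small random volume helper.
rand_volume <- function(n = 8L, seed = 1L, voxel = 100) {
  set.seed(seed)
  volume(array(runif(n^3), dim = c(n, n, n)), voxel)
}
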