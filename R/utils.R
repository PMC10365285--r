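#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.  All stochastic operations in the
# package run through this so that results are reproducible end to end.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Multiply a matrix M (n_out x dim(a)[axis]) into a 3D array along one axis.
# Workhorse for separable operations (cubic interpolation, Gaussian windows).
#' @keywords internal
axis_apply <- function(a, M, axis) {
  d <- dim(a)
  perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                 `3` = c(3L, 1L, 2L))
  ap <- if (axis == 1L) a else aperm(a, perm)
  dp <- dim(ap)
  res <- M %*% matrix(ap, nrow = dp[1L])
  dim(res) <- c(nrow(M), dp[2L], dp[3L])
  if (axis == 1L) res else aperm(res, order(perm))
}

# Reflect (mirror about the edge sample, no duplication) an index vector
# into [1, n]; used for boundary handling of separable kernels.
#' @keywords internal
reflect_index <- function(i, n) {
  if (n == 1L) return(rep.int(1L, length(i)))
  # period of the reflected sequence is 2(n-1)
  j <- (i - 1L) %% (2L * (n - 1L))
  j <- ifelse(j >= n, 2L * (n - 1L) - j, j)
  j + 1L
}

#' @keywords internal
stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Gaussian smoothing of a 3D array by FFT with periodic wrap; used only for
# random-field synthesis where wrap-around is harmless (fields are
# stationary by construction).
#' @keywords internal
gauss_smooth_periodic <- function(a, sigma_vox) {
  if (sigma_vox <= 0) return(a)
  d <- dim(a)
  kern1 <- function(n) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * sigma_vox^2))
    k / sum(k)
  }
  K <- outer(outer(kern1(d[1]), kern1(d[2])), kern1(d[3]))
  dim(K) <- d
  out <- Re(fft(fft(a) * fft(K), inverse = TRUE)) / prod(d)
  out
}

# Standardize a numeric vector to zero mean / unit sd.
#' @keywords internal
standardize <- function(x) {
  s <- sd(x)
  if (s == 0) stopf("cannot standardize a constant field")
  (x - mean(x)) / s
}

# Residual of x after projecting out the (centered) directions in `basis`
# (a list of numeric vectors), via sequential Gram-Schmidt.
#' @keywords internal
orthogonalize <- function(x, basis) {
  x <- x - mean(x)
  for (b in basis) {
    b <- b - mean(b)
    nb <- sum(b * b)
    if (nb > 0) x <- x - b * (sum(x * b) / nb)
  }
  x
}
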