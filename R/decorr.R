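# Decorrelation-based, parameter-free effective resolution estimation.
#
# The estimator cross-correlates an image's Fourier transform with low-pass
# masked versions of its unit-modulus (phase-only) transform.  Each mask
# radius r (a normalized frequency in (0, 1]) yields a decorrelation value
#
#   d(r) = sum_{|f| <= r} |F(f)|  /  sqrt( sum |F|^2 * N(r) ),
#
# the normalized real cross-correlation between F and the masked F/|F|.
# Curves are recomputed under a bank of Gaussian high-pass pre-filters plus
# a refinement pass around the best peak; the cut-off frequency K is the
# highest frequency among all accepted local maxima, and
# effective resolution = voxel size / K.

# Cosine-taper (Tukey) edge apodization, removing hard-edge spectral leakage.
#' @keywords internal
apodize2d <- function(img, frac = 0.1) {
  taper1 <- function(n) {
    w <- rep(1, n)
    m <- max(2L, floor(frac * n))
    ramp <- 0.5 * (1 - cos(pi * (seq_len(m) - 1) / (m - 1)))
    w[seq_len(m)] <- ramp
    w[n + 1 - seq_len(m)] <- ramp
    w
  }
  img <- img - mean(img)
  img * outer(taper1(nrow(img)), taper1(ncol(img)))
}

# Decorrelation curve for one 2D spectrum.  `absF` and `radius` are the
# modulus and the normalized frequency radius of each Fourier sample.
#' @keywords internal
decorr_curve <- function(absF, radius, radii) {
  ord <- order(radius)
  r_sorted <- radius[ord]
  cum_abs <- cumsum(absF[ord])
  cum_n <- seq_along(r_sorted)
  total2 <- sum(absF^2)
  idx <- findInterval(radii, r_sorted)
  vapply(seq_along(radii), function(i) {
    k <- idx[i]
    if (k < 1L || total2 == 0) return(0)
    cum_abs[k] / sqrt(total2 * cum_n[k])
  }, numeric(1))
}

# Local maxima of a curve d(radii): a point qualifying as a peak must exceed
# the minimum of the later curve values by at least `drop` (so monotone
# growth up to the Nyquist edge registers as an endpoint peak); ties break
# toward higher frequency.
#' @keywords internal
find_peaks <- function(radii, d, drop = 1e-3) {
  n <- length(d)
  peaks <- list()
  for (i in seq_len(n)) {
    left_ok <- i == 1L || d[i] >= d[i - 1L]
    right_ok <- i == n || d[i] >= d[i + 1L]
    if (!(left_ok && right_ok)) next
    later_min <- if (i == n) d[n] - drop else min(d[i:n])
    if (i == n || d[i] - later_min >= drop) {
      peaks[[length(peaks) + 1L]] <- c(frequency = radii[i], amplitude = d[i])
    }
  }
  if (!length(peaks)) return(NULL)
  do.call(rbind, peaks)
}

#' @keywords internal
decorr_2d <- function(img, n_radii = 50L, n_highpass = 10L) {
  if (min(dim(img)) < 32L) stopf("image dimensions must be >= 32")
  if (sd(as.numeric(img)) == 0) stopf("constant image has no spectrum")
  a <- apodize2d(img)
  F <- fft(a)
  d <- dim(a)
  fr <- function(n) {
    f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n / 2)
    f[seq_len(n)]
  }
  radius <- sqrt(outer(fr(d[1])^2, fr(d[2])^2, `+`))
  keep <- radius <= 1 & radius > 0          # circular support, DC excluded
  absF0 <- abs(F)[keep]
  rad <- radius[keep]
  radii <- seq(1 / n_radii, 1, length.out = n_radii)
  sigmas <- exp(seq(log(0.15), log(1), length.out = n_highpass))
  curves <- list()
  maxima <- NULL
  add_curves <- function(radii_loc, sigma_set) {
    for (sg in c(NA, sigma_set)) {
      w <- if (is.na(sg)) 1 else 1 - exp(-rad^2 / (2 * sg^2))
      dcur <- decorr_curve(absF0 * w, rad, radii_loc)
      curves[[length(curves) + 1L]] <<- list(radii = radii_loc, d = dcur,
                                             highpass_sigma = sg)
      pk <- find_peaks(radii_loc, dcur)
      if (!is.null(pk)) maxima <<- rbind(maxima, pk)
    }
  }
  add_curves(radii, sigmas)
  # refinement pass around the current best peak frequency
  k0 <- max(maxima[, "frequency"])
  radii_ref <- seq(max(0.02, k0 - 0.1), min(1, k0 + 0.1),
                   length.out = max(10L, n_radii %/% 2L))
  add_curves(radii_ref, sigmas)
  K <- max(maxima[, "frequency"])
  list(curves = curves, maxima = maxima, K = K)
}

#' Estimate effective resolution by decorrelation analysis
#'
#' Parameter-free estimation of the highest spatial frequency carrying
#' correlated signal: the image spectrum is cross-correlated with low-pass
#' masked versions of its phase-normalized spectrum over `n_radii` mask
#' radii, repeated under `n_highpass` Gaussian high-pass pre-filters plus a
#' refinement pass; the cut-off frequency `K` (in (0, 1], units of the
#' Nyquist frequency) is the highest local-maximum frequency, and
#' effective resolution = voxel size / K.
#'
#' 3D volumes are analysed slice-wise (the median `K` over the central
#' slices is reported) unless `use_3d = TRUE`, which uses spherical masks on
#' the full 3D spectrum.
#'
#' @param image a `voxsr_volume` or a 2D matrix; every dimension >= 32.
#' @param voxel_size_um voxel size (taken from the volume when omitted).
#' @param n_radii number of mask radii per curve.
#' @param n_highpass number of Gaussian high-pass sigmas (geometrically
#'   spaced over normalized frequencies 0.15-1).
#' @param n_central_slices how many central slices enter the slice-wise
#'   median for 3D input.
#' @param use_3d analyse the full 3D spectrum with spherical masks instead
#'   of slice-wise.
#' @return A `voxsr_decorr` result: `radii`, `curves`, `maxima`, `K`,
#'   `effective_resolution_um`.
#' @export
effective_resolution <- function(image, voxel_size_um = NULL, n_radii = 50L,
                                 n_highpass = 10L, n_central_slices = 5L,
                                 use_3d = FALSE) {
  if (inherits(image, "voxsr_volume")) {
    voxel_size_um <- voxel_size_um %||% image$voxel_size_um
    arr <- image$data
  } else {
    arr <- image
  }
  voxel_size_um <- voxel_size_um %||% 1
  if (!all(is.finite(arr))) stopf("image intensities must be finite")
  if (is.matrix(arr)) {
    res <- decorr_2d(arr, n_radii, n_highpass)
    K <- res$K
  } else if (length(dim(arr)) == 3L) {
    if (min(dim(arr)) < 32L) stopf("volume dimensions must be >= 32")
    if (use_3d) {
      res <- decorr_3d(arr, n_radii, n_highpass)
      K <- res$K
    } else {
      nz <- dim(arr)[3]
      mid <- (nz + 1) %/% 2
      half <- min(n_central_slices %/% 2L, mid - 1L)
      slices <- (mid - half):(mid + half)
      per <- lapply(slices, function(k) decorr_2d(arr[, , k], n_radii,
                                                  n_highpass))
      Ks <- vapply(per, `[[`, numeric(1), "K")
      K <- median(Ks)
      res <- per[[which.min(abs(Ks - K))[1]]]
    }
  } else {
    stopf("`image` must be a 2D matrix or a 3D volume")
  }
  structure(list(radii = res$curves[[1]]$radii, curves = res$curves,
                 maxima = res$maxima, K = K,
                 effective_resolution_um = voxel_size_um / K),
            class = "voxsr_decorr")
}

#' @keywords internal
decorr_3d <- function(arr, n_radii = 50L, n_highpass = 10L) {
  if (sd(as.numeric(arr)) == 0) stopf("constant image has no spectrum")
  a <- arr - mean(arr)
  d <- dim(a)
  tap <- function(n, frac = 0.1) {
    w <- rep(1, n); m <- max(2L, floor(frac * n))
    ramp <- 0.5 * (1 - cos(pi * (seq_len(m) - 1) / (m - 1)))
    w[seq_len(m)] <- ramp; w[n + 1 - seq_len(m)] <- ramp; w
  }
  a <- a * outer(outer(tap(d[1]), tap(d[2])), tap(d[3]))
  dim(a) <- d
  F <- fft(a)
  fr <- function(n) c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n / 2)
  radius <- sqrt(outer(outer(fr(d[1])^2, fr(d[2])^2, `+`), fr(d[3])^2, `+`))
  keep <- radius <= 1 & radius > 0
  absF0 <- abs(F)[keep]; rad <- radius[keep]
  radii <- seq(1 / n_radii, 1, length.out = n_radii)
  sigmas <- exp(seq(log(0.15), log(1), length.out = n_highpass))
  curves <- list(); maxima <- NULL
  for (sg in c(NA, sigmas)) {
    w <- if (is.na(sg)) 1 else 1 - exp(-rad^2 / (2 * sg^2))
    dcur <- decorr_curve(absF0 * w, rad, radii)
    curves[[length(curves) + 1L]] <- list(radii = radii, d = dcur,
                                          highpass_sigma = sg)
    pk <- find_peaks(radii, dcur)
    if (!is.null(pk)) maxima <- rbind(maxima, pk)
  }
  list(curves = curves, maxima = maxima, K = max(maxima[, "frequency"]))
}

#' @export
print.voxsr_decorr <- function(x, ...) {
  cat(sprintf("<voxsr_decorr> K = %.3f, effective resolution = %.1f um (%d curves, %d maxima)\n",
              x$K, x$effective_resolution_um, length(x$curves),
              nrow(x$maxima)))
  invisible(x)
}
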