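#' Root mean square error between two volumes
#'
#' @param a,b `voxsr_volume`s (or 3D arrays) of identical shape.
#' @param mask optional logical array selecting the voxels to compare
#'   (default: whole grid).
#' @return The square root of the mean squared voxel difference.
#' @export
rmse <- function(a, b, mask = NULL) {
  xa <- if (inherits(a, "voxsr_volume")) a$data else a
  xb <- if (inherits(b, "voxsr_volume")) b$data else b
  if (!identical(dim(xa), dim(xb))) stopf("volumes have different shapes")
  d <- xa - xb
  if (!is.null(mask)) d <- d[mask]
  sqrt(mean(d^2))
}

# Truncated-Gaussian weighted local smoothing along every axis, with the
# window renormalized over the in-bounds support.  Because the truncation
# region is a cartesian product, per-axis renormalization is exactly the
# joint renormalized 3D window.
#' @keywords internal
gauss_window_matrix <- function(n, win, sigma) {
  half <- win %/% 2L
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - half):(i + half)
    ok <- j >= 1L & j <= n
    M[i, j[ok]] <- g[ok] / sum(g[ok])
  }
  M
}

#' @keywords internal
local_smooth3 <- function(a, win, sigma) {
  d <- dim(a)
  for (ax in 1:3) a <- axis_apply(a, gauss_window_matrix(d[ax], win, sigma), ax)
  a
}

#' Structural similarity index between two volumes (3D)
#'
#' Mean local SSIM with a Gaussian window (default 11-wide, sigma 1.5)
#' computed fully in 3D; near the borders (and on grids smaller than the
#' window) the window is truncated and renormalized.  Stabilizing constants
#' are `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` for dynamic range `L`.
#'
#' @param a,b `voxsr_volume`s (or 3D arrays) of identical shape, on a
#'   declared dynamic range (normalize to [0, 1] first for `L = 1`).
#' @param dynamic_range intensity range `L` (default 1).
#' @param window odd window width.
#' @param sigma Gaussian window sigma in voxels.
#' @return Mean SSIM over the grid, at most 1.
#' @export
ssim <- function(a, b, dynamic_range = 1, window = 11L, sigma = 1.5) {
  xa <- if (inherits(a, "voxsr_volume")) a$data else a
  xb <- if (inherits(b, "voxsr_volume")) b$data else b
  if (!identical(dim(xa), dim(xb))) stopf("volumes have different shapes")
  C1 <- (0.01 * dynamic_range)^2
  C2 <- (0.03 * dynamic_range)^2
  mu_a <- local_smooth3(xa, window, sigma)
  mu_b <- local_smooth3(xb, window, sigma)
  var_a <- local_smooth3(xa * xa, window, sigma) - mu_a^2
  var_b <- local_smooth3(xb * xb, window, sigma) - mu_b^2
  cov_ab <- local_smooth3(xa * xb, window, sigma) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + C1) * (2 * cov_ab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (var_a + var_b + C2)
  mean(num / den)
}

#' Voxel-wise Pearson correlation between two volumes
#'
#' @param a,b `voxsr_volume`s (or arrays) of identical shape.
#' @param mask optional logical array selecting at least 3 voxels.
#' @return `list(r, p)`: the correlation and its two-sided p-value.
#' @export
pearson_correlation <- function(a, b, mask = NULL) {
  xa <- if (inherits(a, "voxsr_volume")) a$data else a
  xb <- if (inherits(b, "voxsr_volume")) b$data else b
  if (!identical(dim(xa), dim(xb))) stopf("volumes have different shapes")
  va <- as.numeric(xa); vb <- as.numeric(xb)
  if (!is.null(mask)) { va <- va[mask]; vb <- vb[mask] }
  if (length(va) < 3L) stopf("mask must select at least 3 voxels")
  if (sd(va) == 0 || sd(vb) == 0) stopf("zero variance in one of the inputs")
  ct <- cor.test(va, vb, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Paired t-test on matched score lists
#'
#' Classical two-sided paired t-test (e.g. RMSE of two SR methods on the
#' same test volumes).  All-zero differences are reported as statistic 0,
#' p-value 1; any other zero-variance difference vector is rejected.
#'
#' @param scores_a,scores_b numeric vectors of equal length n >= 2.
#' @return A `voxsr_stat` report: `test_name`, `statistic`, `p_value`, `n`,
#'   `group_labels`.
#' @export
paired_ttest <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) stopf("score lists differ in length")
  n <- length(scores_a)
  if (n < 2L) stopf("need at least 2 pairs")
  d <- scores_a - scores_b
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(new_stat("paired t-test", 0, 1, n, c("a", "b")))
    }
    stopf("constant non-zero differences: t statistic undefined")
  }
  tt <- t.test(scores_a, scores_b, paired = TRUE)
  new_stat("paired t-test", unname(tt$statistic), tt$p.value, n, c("a", "b"))
}

#' Welch's ANOVA across groups
#'
#' Welch's heteroscedastic F test (Welch-Satterthwaite degrees of freedom)
#' for equality of several group means; groups need not share a variance.
#'
#' @param groups a (named) list of numeric vectors, each of length >= 2 with
#'   positive variance.
#' @return A `voxsr_stat` report with the Welch F statistic and p-value.
#' @export
welch_anova <- function(groups) {
  if (length(groups) < 2L) stopf("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stopf("every group needs n >= 2")
  }
  if (any(vapply(groups, sd, numeric(1)) == 0)) {
    stopf("a group has zero variance")
  }
  labels <- names(groups) %||% paste0("group", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labels, vapply(groups, length, integer(1))), levels = labels)
  ow <- oneway.test(y ~ g, var.equal = FALSE)
  new_stat("Welch's ANOVA", unname(ow$statistic), ow$p.value,
           length(y), labels)
}

#' @keywords internal
new_stat <- function(test_name, statistic, p_value, n, group_labels) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, n = as.integer(n),
                 group_labels = group_labels),
            class = "voxsr_stat")
}

#' @export
print.voxsr_stat <- function(x, ...) {
  cat(sprintf("<voxsr_stat> %s: statistic = %.4g, p = %.4g (n = %d)\n",
              x$test_name, x$statistic, x$p_value, x$n))
  invisible(x)
}
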