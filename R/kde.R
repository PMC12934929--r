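# Two-dimensional product-Gaussian kernel density estimation.
#
# The density at query q is (1/N) * sum_j K_h(q - p_j) with
# K_h(d) = exp(-d1^2/(2 h1^2) - d2^2/(2 h2^2)) / (2*pi*h1*h2),
# evaluated in log space (log-sum-exp) so that far-out-of-support queries
# underflow gracefully instead of hitting exact zeros early.

#' Fit a 2-D Gaussian kernel density estimator
#'
#' @param points two-column matrix or data frame of (rx, ry) training pairs;
#'   at least two rows, all coordinates finite.
#' @param bandwidth per-dimension kernel widths: a positive length-2 numeric
#'   vector, or `"silverman"` to use Silverman's rule of thumb per dimension
#'   (`0.9 * min(sd, IQR/1.34) * n^(-1/5)`), floored at `bw_floor`. The floor
#'   keeps near-degenerate dimensions (e.g. Ry of the homogametic-pair sex,
#'   which is a near-point-mass at 0) from collapsing the kernel.
#' @param bw_floor minimum bandwidth in each dimension.
#' @return Object of class `hostsex_kde`: list with `points` (matrix),
#'   `bandwidth` (length-2), `n`.
#' @export
fit_kde <- function(points, bandwidth = "silverman", bw_floor = 1e-4) {
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 2L)
    hs_error("KDE training points must have two columns (rx, ry)",
             "hostsex_kde_error")
  if (nrow(pts) < 2L || !all(is.finite(pts)))
    hs_error("KDE needs >= 2 training points with finite coordinates",
             "hostsex_kde_error")
  if (identical(bandwidth, "silverman")) {
    bandwidth <- c(bw_silverman(pts[, 1]), bw_silverman(pts[, 2]))
  }
  bandwidth <- pmax(as.numeric(bandwidth), bw_floor)
  if (length(bandwidth) != 2L || any(!is.finite(bandwidth) | bandwidth <= 0))
    hs_error("bandwidth must be two positive finite numbers",
             "hostsex_kde_error")
  structure(list(points = unname(pts), bandwidth = bandwidth, n = nrow(pts)),
            class = "hostsex_kde")
}

# Silverman's rule of thumb for one dimension; returns 0 for a degenerate
# dimension (caller applies the floor).
bw_silverman <- function(v) {
  n <- length(v)
  s <- stats::sd(v)
  iqr <- stats::IQR(v) / 1.34
  sigma <- if (iqr > 0) min(s, iqr) else s
  if (!is.finite(sigma)) sigma <- 0
  0.9 * sigma * n^(-1 / 5)
}

#' Evaluate the log density of a fitted KDE
#'
#' Computed with a per-query log-sum-exp over all kernels, chunked so that
#' large query sets never materialize the full query-by-training matrix.
#'
#' @param kde a [fit_kde()] object.
#' @param qx,qy query coordinates (equal-length numeric vectors).
#' @return Log density at each query; `-Inf` where the sum underflows.
#' @export
kde_logdensity <- function(kde, qx, qy) {
  stopifnot(inherits(kde, "hostsex_kde"), length(qx) == length(qy))
  h <- kde$bandwidth
  px <- kde$points[, 1] / h[1]
  py <- kde$points[, 2] / h[2]
  lognorm <- log(kde$n) + log(2 * pi) + log(h[1]) + log(h[2])
  out <- rep(NA_real_, length(qx))
  chunk <- max(1L, floor(4e6 / kde$n))
  for (s in seq(1L, length(qx), by = chunk)) {
    e <- min(s + chunk - 1L, length(qx))
    dx <- outer(qx[s:e] / h[1], px, "-")
    dy <- outer(qy[s:e] / h[2], py, "-")
    ll <- -0.5 * (dx * dx + dy * dy)
    m <- apply(ll, 1L, max)
    out[s:e] <- m + log(rowSums(exp(ll - m))) - lognorm
  }
  out[!is.finite(qx) | !is.finite(qy)] <- NA_real_
  out
}

#' Evaluate the density of a fitted KDE
#' @inheritParams kde_logdensity
#' @return Density at each query.
#' @export
kde_density <- function(kde, qx, qy) exp(kde_logdensity(kde, qx, qy))

#' @export
print.hostsex_kde <- function(x, ...) {
  cat(sprintf("<hostsex_kde> %d points, bandwidth (%.4g, %.4g)\n",
              x$n, x$bandwidth[1], x$bandwidth[2]))
  invisible(x)
}
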