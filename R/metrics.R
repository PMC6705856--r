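#' Mean and SD of T2 over a voxel set
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' valid-voxel T2 values pooled across all three slices of an ROI or
#' sub-region.  Invalid voxels (failed fits, truncated bright noise) are
#' excluded; with fewer than two valid voxels the SD is undefined and
#' returned as `NA`.
#'
#' @param map a `t2_map`.
#' @param voxels a [disc_roi()] or a data.frame with `slice`, `row`, `col`.
#' @return list with `mean`, `sd`, `n_valid`.
#' @export
roi_mean_sd <- function(map, voxels) {
  stop_if_not(inherits(map, "t2_map"), "map must be a t2_map")
  v <- if (inherits(voxels, "disc_roi")) voxels$voxels else voxels
  stop_if_not(is.data.frame(v) && nrow(v) > 0, "empty voxel set")
  vals <- roi_values(map, v)
  n <- length(vals)
  list(mean = if (n >= 1) mean(vals) else NA_real_,
       sd = if (n >= 2) stats::sd(vals) else NA_real_,
       n_valid = n)
}

# valid T2 values of a voxel set
roi_values <- function(map, v) {
  dshape <- dim(map$t2)
  if (any(v$slice < 1 | v$slice > dshape[1] | v$row < 1 | v$row > dshape[2] |
            v$col < 1 | v$col > dshape[3])) {
    stop("voxel set lies outside the map grid")
  }
  idx <- cbind(v$slice, v$row, v$col)
  ok <- map$valid[idx]
  map$t2[idx][ok]
}

#' Two-component Gaussian mixture fit of a T2 sample
#'
#' Expectation-maximisation fit of a two-component Gaussian mixture to the
#' empirical distribution of T2 values inside a disc.  The two components
#' capture the annulus fibrosus (low T2) and nucleus pulposus (high T2)
#' populations; their peak separation `delta_mu = mu2 - mu1` quantifies the
#' remaining distinction between the tissues and shrinks as the disc
#' degenerates.
#'
#' Initialisation is deterministic: means at the 25th and 75th percentiles,
#' equal weights, both SDs at half the sample SD.  The log-likelihood is
#' checked to be non-decreasing at every iteration (up to floating-point
#' slack from the variance floor that prevents component collapse on
#' near-degenerate samples).  Components are returned sorted by mean.
#'
#' @param values numeric sample, at least 10 finite values with nonzero
#'   variance.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter iteration cap; hitting it is flagged via `converged`.
#' @return object of class `gmm2_fit`: `mu` (sorted), `sigma`, `lambda`
#'   (mixing weights), `delta_mu`, `loglik`, `loglik_trace`, `converged`,
#'   `n_iter`.
#' @export
fit_two_gaussians <- function(values, tol = 1e-8, max_iter = 500) {
  x <- as.numeric(values)
  stop_if_not(all(is.finite(x)), "values must be finite")
  stop_if_not(length(x) >= 10, "at least 10 values are required")
  sx <- stats::sd(x)
  stop_if_not(sx > 0, "zero-variance sample: degenerate mixture")

  mu <- as.numeric(stats::quantile(x, c(0.25, 0.75), names = FALSE))
  if (mu[1] == mu[2]) mu <- mu + c(-sx, sx) / 2
  sg <- rep(sx / 2, 2)
  lam <- c(0.5, 0.5)
  floor_sg <- max(sx * 1e-3, .Machine$double.xmin^0.25)

  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    d1 <- lam[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- lam[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    if (ll < ll_old - 1e-6 * (1 + abs(ll))) {
      stop("internal error: EM log-likelihood decreased")
    }
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    g <- d1 / tot
    n1 <- sum(g); n2 <- length(x) - n1
    lam <- pmin(pmax(c(n1, n2) / length(x), 1e-8), 1 - 1e-8)
    lam <- lam / sum(lam)
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    sg <- sqrt(c(sum(g * (x - mu[1])^2) / n1,
                 sum((1 - g) * (x - mu[2])^2) / n2))
    sg <- pmax(sg, floor_sg)
  }
  ord <- order(mu)
  structure(list(mu = mu[ord], sigma = sg[ord], lambda = lam[ord],
                 delta_mu = abs(diff(mu)), loglik = trace[length(trace)],
                 loglik_trace = trace, converged = converged, n_iter = it),
            class = "gmm2_fit")
}

#' @export
print.gmm2_fit <- function(x, ...) {
  cat(sprintf("gmm2_fit: mu = (%.2f, %.2f), sigma = (%.2f, %.2f), lambda = (%.2f, %.2f)\n",
              x$mu[1], x$mu[2], x$sigma[1], x$sigma[2], x$lambda[1], x$lambda[2]))
  cat(sprintf("  delta_mu = %.2f ms, loglik = %.3f, %s after %d iterations\n",
              x$delta_mu, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Per-disc T2 metrics
#'
#' Assembles the whole-ROI mean T2, SD and Gaussian-mixture peak separation
#' (delta-mu), plus per-sub-region mean and SD, pooling the valid voxels of
#' all three slices.  Delta-mu is computed on the whole disc only: the
#' NP/AF separation it measures is a whole-disc concept.  Sub-regions with
#' no valid voxels yield `NA` (missing, not zero).
#'
#' @param map a `t2_map`.
#' @param roi a [disc_roi()].
#' @param partition a [partition_subregions()] result for `roi`; computed
#'   on the fly when `NULL`.
#' @param gmm_min_n minimum valid-voxel count for the mixture fit.
#' @return one-row data.frame with columns `mean_t2`, `sd_t2`, `delta_mu`,
#'   `n_valid`, `sr_mean_1..5`, `sr_sd_1..5`, `sr_n_1..5`.
#' @export
disc_metrics <- function(map, roi, partition = NULL, gmm_min_n = 10) {
  stop_if_not(inherits(map, "t2_map"), "map must be a t2_map")
  stop_if_not(inherits(roi, "disc_roi"), "roi must be a disc_roi")
  if (is.null(partition)) partition <- partition_subregions(roi)
  stop_if_not(length(partition$labels) == nrow(roi$voxels),
              "partition does not match the ROI")
  whole <- roi_mean_sd(map, roi)
  vals <- roi_values(map, roi$voxels)
  dmu <- NA_real_
  if (length(vals) >= gmm_min_n && stats::sd(vals) > 0) {
    dmu <- fit_two_gaussians(vals)$delta_mu
  }
  out <- data.frame(mean_t2 = whole$mean, sd_t2 = whole$sd,
                    delta_mu = dmu, n_valid = whole$n_valid)
  for (k in 1:5) {
    sub <- roi$voxels[partition$labels == k, , drop = FALSE]
    if (nrow(sub) == 0) {
      m <- list(mean = NA_real_, sd = NA_real_, n_valid = 0L)
    } else {
      m <- roi_mean_sd(map, sub)
    }
    out[[paste0("sr_mean_", k)]] <- m$mean
    out[[paste0("sr_sd_", k)]] <- m$sd
    out[[paste0("sr_n_", k)]] <- m$n_valid
  }
  out
}
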