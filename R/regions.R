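#' Partition a disc ROI into five anterior-posterior sub-regions
#'
#' The pooled (three-slice) ROI voxel centres are projected onto an
#' in-plane anterior-posterior axis and the projected range is split into
#' five intervals of equal length; sub-region 1 is the anterior extreme and
#' sub-region 5 the posterior extreme (where high-intensity zones live).
#'
#' When no axis is supplied it is estimated as the in-plane principal axis
#' of the pooled ROI (eigenvector of the second-moment matrix with the
#' largest eigenvalue), signed so that increasing projection means more
#' posterior (the sign is fixed by the geometry's posterior direction).
#' Projections falling exactly on an interval edge are assigned to the
#' lower-index interval.
#'
#' "Equally sized" means equal geometric width along the axis, not equal
#' voxel counts; per-band counts are returned so the alternative reading
#' can be audited.
#'
#' @param roi a [disc_roi()].
#' @param ap_axis optional in-plane unit vector (row, col components, mm
#'   space) pointing posteriorly; estimated from the ROI shape when absent.
#' @return object of class `subregion_partition`: list with `labels`
#'   (integer 1..5 per ROI voxel, in the order of `roi$voxels`), `axis`,
#'   `breaks` (the six interval edges in projection units), and `counts`
#'   (voxels per sub-region).
#' @export
partition_subregions <- function(roi, ap_axis = NULL) {
  stop_if_not(inherits(roi, "disc_roi"), "roi must be a disc_roi")
  mm <- voxel_centers_mm(roi$voxels, roi$geometry)
  if (is.null(ap_axis)) {
    ctr <- colMeans(mm)
    cov <- stats::cov(mm)
    eg <- eigen(cov, symmetric = TRUE)
    ap_axis <- eg$vectors[, 1]
  } else {
    nrm <- sqrt(sum(ap_axis^2))
    stop_if_not(length(ap_axis) == 2 && nrm > 0, "ap_axis must be a nonzero 2-vector")
    ap_axis <- ap_axis / nrm
  }
  dp <- sum(ap_axis * roi$geometry$posterior)
  if (dp < 0) ap_axis <- -ap_axis
  p <- drop(mm %*% ap_axis)
  rng <- range(p)
  stop_if_not(diff(rng) > 0, "ROI has zero in-plane extent along the axis")
  u <- (p - rng[1]) / diff(rng)
  lab <- pmax(1L, pmin(5L, as.integer(ceiling(u * 5 - 1e-9))))
  lab[u <= 0] <- 1L
  counts <- tabulate(lab, nbins = 5)
  structure(list(labels = lab, axis = ap_axis,
                 breaks = rng[1] + diff(rng) * (0:5) / 5,
                 counts = counts),
            class = "subregion_partition")
}

#' @export
print.subregion_partition <- function(x, ...) {
  cat("subregion_partition: counts", paste(x$counts, collapse = " "),
      sprintf("| axis (%.3f, %.3f)\n", x$axis[1], x$axis[2]))
  invisible(x)
}
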