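#' Scan geometry for a sagittal image stack
#'
#' Describes where the voxels of a parallel sagittal stack sit in patient
#' space: in-plane pixel spacing, the in-plane patient position of the first
#' voxel, per-slice positions along the slice normal, and the in-plane unit
#' vector pointing towards the patient's posterior.  This is the minimal
#' information needed to transfer a region of interest between two series
#' with different fields of view (the DICOM PixelSpacing /
#' ImagePositionPatient use case).
#'
#' @param spacing numeric length-2, in-plane spacing in mm (row, column).
#' @param slice_positions numeric vector of slice positions (mm) along the
#'   slice normal, one per slice, strictly monotone.
#' @param origin numeric length-2, patient-space in-plane coordinates (mm) of
#'   the centre of voxel (row 1, col 1).
#' @param posterior in-plane unit vector pointing posteriorly; the default
#'   `c(0, 1)` means increasing column index is more posterior.
#' @param slice_thickness slice thickness in mm (informational).
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(spacing, slice_positions, origin = c(0, 0),
                          posterior = c(0, 1), slice_thickness = NA_real_) {
  stop_if_not(length(spacing) == 2 && all(spacing > 0),
              "spacing must be two positive values (row, col) in mm")
  stop_if_not(length(slice_positions) >= 1 &&
                (length(slice_positions) == 1 ||
                   all(diff(slice_positions) > 0) ||
                   all(diff(slice_positions) < 0)),
              "slice_positions must be strictly monotone")
  stop_if_not(length(origin) == 2, "origin must be length 2 (mm)")
  nrm <- sqrt(sum(posterior^2))
  stop_if_not(length(posterior) == 2 && nrm > 0,
              "posterior must be a nonzero in-plane vector")
  structure(list(spacing = as.numeric(spacing),
                 slice_positions = as.numeric(slice_positions),
                 origin = as.numeric(origin),
                 posterior = as.numeric(posterior) / nrm,
                 slice_thickness = slice_thickness),
            class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("scan_geometry: %d slice(s), spacing %.3f x %.3f mm, origin (%.2f, %.2f) mm\n",
              length(x$slice_positions), x$spacing[1], x$spacing[2],
              x$origin[1], x$origin[2]))
  invisible(x)
}

# in-plane patient coordinates (mm) of voxel centres; voxels is a data.frame
# with columns slice, row, col
voxel_centers_mm <- function(voxels, geometry) {
  cbind(r = geometry$origin[1] + (voxels$row - 1) * geometry$spacing[1],
        c = geometry$origin[2] + (voxels$col - 1) * geometry$spacing[2])
}

geometries_parallel <- function(a, b, tol = 1e-6) {
  abs(sum(a$posterior * b$posterior) - 1) < tol
}
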