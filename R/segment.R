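#' Seeded region growing on one 2-D slice
#'
#' Returns the maximal 8-connected pixel set containing the seed within
#' which every pixel intensity lies within `tolerance * reference` of the
#' reference intensity.  The reference is the mean of the 3x3 neighbourhood
#' around the seed (clipped at the image border) unless supplied
#' explicitly.  Deterministic for fixed inputs and independent of the
#' traversal order.
#'
#' @param image numeric matrix (one sagittal slice).
#' @param seed integer pair (row, col), inside the grid.
#' @param tolerance positive fraction of the reference intensity.
#' @param reference optional explicit reference intensity; growing from any
#'   pixel of a previous result with the same reference reproduces that
#'   result.
#' @return logical matrix the size of `image` (the grown region); the
#'   reference used is attached as attribute `"reference"`.
#' @export
region_grow <- function(image, seed, tolerance = 0.25, reference = NULL) {
  stop_if_not(is.matrix(image), "image must be a matrix")
  nr <- nrow(image); nc <- ncol(image)
  stop_if_not(length(seed) == 2 && seed[1] >= 1 && seed[1] <= nr &&
                seed[2] >= 1 && seed[2] <= nc, "seed out of bounds")
  stop_if_not(tolerance > 0, "tolerance must be > 0")
  if (is.null(reference)) {
    rr <- max(1, seed[1] - 1):min(nr, seed[1] + 1)
    cc <- max(1, seed[2] - 1):min(nc, seed[2] + 1)
    reference <- mean(image[rr, cc])
  }
  qualify <- abs(image - reference) <= tolerance * abs(reference)
  region <- matrix(FALSE, nr, nc)
  if (!qualify[seed[1], seed[2]]) {
    attr(region, "reference") <- reference
    return(region)
  }
  region[seed[1], seed[2]] <- TRUE
  # flood fill: iterate 8-neighbour dilation restricted to qualifying pixels
  repeat {
    grown <- dilate8(region) & qualify
    if (sum(grown) == sum(region)) break
    region <- grown
  }
  attr(region, "reference") <- reference
  region
}

# one 8-connected dilation step (includes the input set)
dilate8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-nr, ]
  out[-nr, ] <- out[-nr, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -nc]
  out[, -nc] <- out[, -nc] | m[, -1]
  out[-1, -1] <- out[-1, -1] | m[-nr, -nc]
  out[-1, -nc] <- out[-1, -nc] | m[-nr, -1]
  out[-nr, -1] <- out[-nr, -1] | m[-1, -nc]
  out[-nr, -nc] <- out[-nr, -nc] | m[-1, -1]
  out
}

#' Contract a mask contour by morphological erosion
#'
#' Applies `steps` erosions with a 3x3 cross (4-connected) structuring
#' element.  Used to pull the segmented disc contour inwards so that tissue
#' of doubtful membership near the boundary is excluded.  Anti-extensive:
#' the result is always a subset of the input.
#'
#' @param mask logical matrix.
#' @param steps number of erosion steps (>= 0).
#' @return eroded logical matrix; attribute `"degenerate"` is TRUE when the
#'   result is empty.
#' @export
contract_contour <- function(mask, steps = 1) {
  stop_if_not(is.matrix(mask) && is.logical(mask), "mask must be a logical matrix")
  stop_if_not(steps >= 0, "steps must be >= 0")
  nr <- nrow(mask); nc <- ncol(mask)
  m <- mask
  for (i in seq_len(steps)) {
    up <- rbind(m[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, m[-nr, , drop = FALSE])
    lf <- cbind(m[, -1, drop = FALSE], FALSE)
    rt <- cbind(FALSE, m[, -nc, drop = FALSE])
    m <- m & up & dn & lf & rt
    if (!any(m)) break
  }
  attr(m, "degenerate") <- !any(m)
  m
}

#' Disc region of interest over three consecutive sagittal slices
#'
#' @param voxels data.frame with integer columns `slice`, `row`, `col`;
#'   must span exactly three consecutive slices, be nonempty on each, and
#'   form one 8-connected component per slice.
#' @param geometry the [scan_geometry()] the voxel indices refer to.
#' @param id list or character disc identifier (e.g. subject + level).
#' @param provenance optional list recording seed points, tolerance and
#'   contraction steps.
#' @param check_connected verify per-slice 8-connectivity (default TRUE;
#'   disabled for ROIs transferred to a finer grid, where nearest-neighbour
#'   mapping legitimately leaves pinholes).
#' @return object of class `disc_roi`.
#' @export
disc_roi <- function(voxels, geometry, id = "disc", provenance = list(),
                     check_connected = TRUE) {
  stop_if_not(is.data.frame(voxels) && all(c("slice", "row", "col") %in% names(voxels)),
              "voxels must be a data.frame with slice, row, col")
  stop_if_not(nrow(voxels) > 0, "empty ROI")
  sl <- sort(unique(voxels$slice))
  stop_if_not(length(sl) == 3 && all(diff(sl) == 1),
              "ROI must cover exactly three consecutive slices")
  for (s in sl) {
    sub <- voxels[voxels$slice == s, ]
    stop_if_not(nrow(sub) > 0, "ROI empty on one slice")
    if (check_connected) {
      stop_if_not(is_connected8(sub$row, sub$col),
                  "per-slice ROI component must be 8-connected")
    }
  }
  voxels <- voxels[order(voxels$slice, voxels$row, voxels$col), , drop = FALSE]
  rownames(voxels) <- NULL
  structure(list(voxels = voxels, geometry = geometry, id = id,
                 provenance = provenance),
            class = "disc_roi")
}

#' @export
print.disc_roi <- function(x, ...) {
  cat(sprintf("disc_roi '%s': %d voxels on slices %s\n",
              paste(unlist(x$id), collapse = "/"), nrow(x$voxels),
              paste(sort(unique(x$voxels$slice)), collapse = ",")))
  invisible(x)
}

is_connected8 <- function(rows, cols) {
  n <- length(rows)
  if (n <= 1) return(TRUE)
  rmin <- min(rows) - 1; cmin <- min(cols) - 1
  nr <- max(rows) - rmin; nc <- max(cols) - cmin
  m <- matrix(FALSE, nr, nc)
  m[cbind(rows - rmin, cols - cmin)] <- TRUE
  comp <- matrix(FALSE, nr, nc)
  comp[rows[1] - rmin, cols[1] - cmin] <- TRUE
  repeat {
    grown <- dilate8(comp) & m
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  sum(comp) == n
}

#' Transfer a disc ROI between scan geometries
#'
#' Maps each source voxel centre to patient coordinates (origin + index x
#' spacing; slice by its slice position), then to the nearest destination
#' voxel, emulating the automatic ROI repositioning between series with
#' different fields of view via DICOM position/spacing tags.  Duplicate
#' destination voxels are collapsed; slices are matched to the nearest
#' destination slice position.  Nearest-neighbour mapping is used because
#' masks are categorical.
#'
#' @param roi a [disc_roi()] defined on `src_geometry`.
#' @param src_geometry,dst_geometry [scan_geometry()] objects; must be
#'   parallel stacks (oblique resampling unsupported).
#' @param dst_shape integer (slices, rows, cols) of the destination grid;
#'   mapped voxels falling outside it are dropped.
#' @return a `disc_roi` on the destination geometry.
#' @export
transfer_roi <- function(roi, src_geometry = roi$geometry, dst_geometry,
                         dst_shape) {
  stop_if_not(inherits(roi, "disc_roi"), "roi must be a disc_roi")
  stop_if_not(geometries_parallel(src_geometry, dst_geometry),
              "geometries are not parallel; oblique resampling unsupported")
  v <- roi$voxels
  mm <- voxel_centers_mm(v, src_geometry)
  dst_row <- round((mm[, 1] - dst_geometry$origin[1]) / dst_geometry$spacing[1]) + 1
  dst_col <- round((mm[, 2] - dst_geometry$origin[2]) / dst_geometry$spacing[2]) + 1
  src_z <- src_geometry$slice_positions[v$slice]
  dst_slice <- vapply(src_z, function(z) {
    which.min(abs(dst_geometry$slice_positions - z))
  }, integer(1))
  out <- unique(data.frame(slice = dst_slice, row = dst_row, col = dst_col))
  inb <- out$slice >= 1 & out$slice <= dst_shape[1] &
    out$row >= 1 & out$row <= dst_shape[2] &
    out$col >= 1 & out$col <= dst_shape[3]
  out <- out[inb, , drop = FALSE]
  stop_if_not(nrow(out) > 0, "transferred ROI is empty on the destination grid")
  disc_roi(out, dst_geometry, id = roi$id,
           provenance = c(roi$provenance, list(transferred_from = src_geometry)),
           check_connected = FALSE)
}

#' Segment one disc on a structural stack
#'
#' Convenience wrapper running [region_grow()] on each of three consecutive
#' slices from one seed per slice, followed by [contract_contour()],
#' returning a [disc_roi()].
#'
#' @param image 3-D array (slice x row x col), the structural series.
#' @param geometry its [scan_geometry()].
#' @param seeds data.frame with columns `slice`, `row`, `col` (one seed per
#'   slice, three consecutive slices).
#' @param tolerance region-growing tolerance (fraction of reference).
#' @param contract_steps erosion steps applied per slice after growing.
#' @param id disc identifier.
#' @return a `disc_roi`, or `NULL` when any slice's region is degenerate
#'   (empty after contraction).
#' @export
segment_disc <- function(image, geometry, seeds, tolerance = 0.25,
                         contract_steps = 1, id = "disc") {
  stop_if_not(length(dim(image)) == 3, "image must be slice x row x col")
  vox <- list()
  for (k in seq_len(nrow(seeds))) {
    s <- seeds$slice[k]
    reg <- region_grow(image[s, , ], c(seeds$row[k], seeds$col[k]), tolerance)
    reg <- contract_contour(reg, contract_steps)
    if (!any(reg)) return(NULL)
    idx <- which(reg, arr.ind = TRUE)
    vox[[k]] <- data.frame(slice = s, row = idx[, 1], col = idx[, 2])
  }
  vox <- do.call(rbind, vox)
  disc_roi(vox, geometry, id = id,
           provenance = list(seeds = seeds, tolerance = tolerance,
                             contract_steps = contract_steps))
}
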