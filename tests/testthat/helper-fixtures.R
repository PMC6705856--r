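# shared fixtures: small, ideal phantoms built in code

TE8 <- c(11.1, 22.2, 33.3, 44.4, 55.5, 66.6, 77.7, 88.8)

# ideal hard-edged two-compartment disc: no blend, no jitter
ideal_spec <- function(grade = 2, hiz = FALSE, noise_sigma = 0, seed = 1,
                       np = NULL, af = NULL, ...) {
  tt <- default_t2_table()
  if (!is.null(np)) tt$np <- rep(np, 5)
  if (!is.null(af)) tt$af <- rep(af, 5)
  phantom_spec(discs = list(disc_descriptor("L4-L5", center_mm = c(20, 24),
                                            grade = grade, hiz = hiz)),
               t2_table = tt,
               blend_base = 0, blend_per_grade = 0,
               np_jitter_sd = 0, af_jitter_sd = 0,
               noise_sigma = noise_sigma, seed = seed, ...)
}

# disc_roi from a ground-truth label array
roi_from_truth <- function(ph, disc = 1) {
  idx <- which(ph$truth$disc_labels == disc, arr.ind = TRUE)
  disc_roi(data.frame(slice = idx[, 1], row = idx[, 2], col = idx[, 3]),
           ph$series$geometry, id = "gt", check_connected = FALSE)
}

voxel_key <- function(v) paste(v[, 1], v[, 2], v[, 3])

dice <- function(a_keys, b_keys) {
  2 * length(intersect(a_keys, b_keys)) / (length(a_keys) + length(b_keys))
}

# simple rectangular ROI helper on an identity-ish geometry
rect_roi <- function(rows, cols, slices = 1:3, spacing = c(1, 1)) {
  g <- scan_geometry(spacing = spacing, slice_positions = (slices - 1) * 4.2)
  v <- expand.grid(slice = slices, row = rows, col = cols)
  disc_roi(v, g, id = "rect")
}
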