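test_that("region growing: homogeneous and two-intensity limits", {
  img <- matrix(50, 20, 30)
  reg <- region_grow(img, c(10, 15), tolerance = 0.1)
  expect_true(all(reg))                                  # uniform -> whole slice
  img2 <- matrix(20, 40, 40)
  disc <- outer((1:40 - 20)^2 / 64, (1:40 - 20)^2 / 225, "+") <= 1
  img2[disc] <- 100
  reg2 <- region_grow(img2, c(20, 20), tolerance = 0.3)
  expect_identical(as.vector(reg2), as.vector(disc))     # exactly the disc
  expect_error(region_grow(img2, c(0, 5)), "out of bounds")
})

test_that("region growing reaches Dice >= 0.90 against phantom ground truth", {
  sp <- ideal_spec(seed = 2)
  ph <- build_phantom(sp)
  st <- ph$structural
  d <- sp$discs[[1]]
  # ground-truth ellipse rendered on the structural grid
  g <- st$geometry
  nr <- dim(st$image)[2]; nc <- dim(st$image)[3]
  Rm <- matrix(g$origin[1] + (seq_len(nr) - 1) * g$spacing[1], nr, nc)
  Cm <- matrix(g$origin[2] + (seq_len(nc) - 1) * g$spacing[2], nr, nc, byrow = TRUE)
  gt <- ((Rm - d$center_mm[1]) / d$semi_axes_mm[1])^2 +
    ((Cm - d$center_mm[2]) / d$semi_axes_mm[2])^2 <= 1
  seed_px <- c(round((d$center_mm[1] - g$origin[1]) / g$spacing[1]) + 1,
               round((d$center_mm[2] - g$origin[2]) / g$spacing[2]) + 1)
  reg <- region_grow(st$image[2, , ], seed_px, tolerance = 0.25)
  dc <- 2 * sum(reg & gt) / (sum(reg) + sum(gt))
  expect_gte(dc, 0.90)
})

test_that("region growing is idempotent and seed-order independent given the reference", {
  sp <- ideal_spec(seed = 8)
  ph <- build_phantom(sp)
  g <- ph$structural$geometry
  d <- sp$discs[[1]]
  img <- ph$structural$image[1, , ]
  seed_px <- c(round((d$center_mm[1] - g$origin[1]) / g$spacing[1]) + 1,
               round((d$center_mm[2] - g$origin[2]) / g$spacing[2]) + 1)
  reg <- region_grow(img, seed_px, tolerance = 0.25)
  expect_gt(sum(reg), 100)
  ref <- attr(reg, "reference")
  inside <- which(reg, arr.ind = TRUE)
  for (k in c(1, nrow(inside) %/% 2, nrow(inside))) {
    reg2 <- region_grow(img, inside[k, ], tolerance = 0.25, reference = ref)
    expect_identical(as.vector(reg2), as.vector(reg))
  }
})

test_that("contour contraction: identity, erosion arithmetic, exhaustion, monotonicity", {
  sq <- matrix(FALSE, 9, 9); sq[3:7, 3:7] <- TRUE
  expect_identical(as.vector(contract_contour(sq, 0)), as.vector(sq))
  e1 <- contract_contour(sq, 1)
  expect_equal(sum(e1), 9)                               # 5x5 -> 3x3
  expect_true(all(which(e1, arr.ind = TRUE) >= 4) &&
                all(which(e1, arr.ind = TRUE) <= 6))
  e9 <- contract_contour(sq, 9)
  expect_false(any(e9))
  expect_true(attr(e9, "degenerate"))
  # anti-extensive and decreasing in steps
  prev <- sq
  for (s in 1:3) {
    cur <- contract_contour(sq, s)
    expect_true(all(!cur | prev))
    expect_lte(sum(cur), sum(prev))
    prev <- cur
  }
})

test_that("ROI transfer: identity, half-spacing arithmetic, non-parallel error", {
  roi <- rect_roi(5:10, 8:20)
  same <- transfer_roi(roi, roi$geometry, roi$geometry, c(3, 30, 30))
  expect_equal(as.matrix(same$voxels) * 1, as.matrix(roi$voxels) * 1,
               ignore_attr = TRUE)
  # destination at half the source spacing, aligned origins
  fine <- scan_geometry(c(0.5, 0.5), roi$geometry$slice_positions)
  tr <- transfer_roi(roi, roi$geometry, fine, c(3, 60, 60))
  expect_setequal(tr$voxels$row, 2 * (5:10) - 1)         # even-index cover: 2i - 1
  expect_setequal(tr$voxels$col, 2 * (8:20) - 1)
  tilted <- scan_geometry(c(1, 1), roi$geometry$slice_positions,
                          posterior = c(1, 0))
  expect_error(transfer_roi(roi, roi$geometry, tilted, c(3, 30, 30)),
               "parallel")
})

test_that("offset field-of-view transfer recovers the mask (Dice >= 0.95)", {
  sp <- ideal_spec(seed = 4)
  ph <- build_phantom(sp)
  roi <- roi_from_truth(ph)
  src <- ph$series$geometry
  # equal-resolution destination grid with a non-integer origin shift
  dst <- scan_geometry(src$spacing, src$slice_positions,
                       origin = src$origin + c(-3.13, 2.41))
  shape <- dim(ph$series$data)[2:4] + c(0, 10, 10)
  tr <- transfer_roi(roi, src, dst, shape)
  # oracle: ground-truth ellipse re-rendered directly on the destination grid
  d <- sp$discs[[1]]
  vx <- tr$voxels
  gt_keys <- local({
    nr <- shape[2]; nc <- shape[3]
    Rm <- matrix(dst$origin[1] + (seq_len(nr) - 1) * dst$spacing[1], nr, nc)
    Cm <- matrix(dst$origin[2] + (seq_len(nc) - 1) * dst$spacing[2], nr, nc, byrow = TRUE)
    gt2d <- ((Rm - d$center_mm[1]) / d$semi_axes_mm[1])^2 +
      ((Cm - d$center_mm[2]) / d$semi_axes_mm[2])^2 <= 1
    idx <- which(gt2d, arr.ind = TRUE)
    unlist(lapply(1:3, function(s) paste(s, idx[, 1], idx[, 2])))
  })
  expect_gte(dice(voxel_key(as.matrix(vx)), gt_keys), 0.95)
  # round trip back to the source grid recovers >= 95% of the voxels
  back <- transfer_roi(tr, dst, src, dim(ph$series$data)[2:4])
  rec <- mean(voxel_key(as.matrix(roi$voxels)) %in% voxel_key(as.matrix(back$voxels)))
  expect_gte(rec, 0.95)
})

test_that("disc_roi validates slice span and per-slice connectivity", {
  g <- scan_geometry(c(1, 1), c(0, 4.2, 8.4))
  expect_error(disc_roi(data.frame(slice = c(1, 3), row = 1, col = 1), g),
               "three consecutive")
  split <- rbind(expand.grid(slice = 1:3, row = 1:2, col = 1:2),
                 expand.grid(slice = 1:3, row = 9:10, col = 9:10))
  expect_error(disc_roi(split, g), "8-connected")
  expect_s3_class(disc_roi(split, g, check_connected = FALSE), "disc_roi")
})
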