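test_that("spec validation rejects broken invariants with a named message", {
  expect_error(phantom_spec(echo_times = c(10, 20, 15)), "echo times")
  expect_error(phantom_spec(hiz_ap_position = 0.5), "posterior fifth")
  bad_tt <- default_t2_table()
  bad_tt$np <- c(40, 40, 40, 40, 40)   # NP below AF at grades 1-3
  expect_error(phantom_spec(t2_table = bad_tt), "NP T2")
  gap_tt <- default_t2_table()
  gap_tt$np <- c(80, 100, 80, 60, 50)  # NP/AF gap not converging
  expect_error(phantom_spec(t2_table = gap_tt), "converge")
  expect_error(disc_descriptor("L1-L2", c(10, 10), grade = 6), "grade")
})

test_that("noise-free NP voxels decay exactly as S0*exp(-t/T2)", {
  sp <- ideal_spec(noise_sigma = 0, np = 90, af = 45)  # NP T2 = 2 x AF T2
  ph <- build_phantom(sp)
  np_idx <- which(ph$truth$compartments == 1L, arr.ind = TRUE)
  expect_gt(nrow(np_idx), 0)
  t2_np <- ph$truth$discs$t2_np[1]
  expect_equal(t2_np, 2 * ph$truth$discs$t2_af[1])
  for (e in seq_along(sp$echo_times)) {
    sl <- ph$series$data[e, , , ]
    expect_equal(sl[np_idx], rep(sp$s0_np * exp(-sp$echo_times[e] / t2_np),
                                 nrow(np_idx)), tolerance = 1e-12)
  }
})

test_that("zero-noise signal is strictly decreasing across echoes", {
  ph <- build_phantom(ideal_spec(noise_sigma = 0))
  d <- ph$series$data
  inside <- ph$truth$disc_labels > 0
  for (e in 2:dim(d)[1]) {
    expect_true(all(d[e, , , ][inside] < d[e - 1, , , ][inside]))
  }
})

test_that("NP decays slower than AF (first-echo-normalised) for grades 1-3", {
  for (g in 1:3) {
    ph <- build_phantom(phantom_spec(
      discs = list(disc_descriptor("L4-L5", c(20, 24), grade = g)),
      np_jitter_sd = 0, af_jitter_sd = 0, noise_sigma = 0))
    d <- ph$series$data
    np <- ph$truth$compartments == 1L
    af <- ph$truth$compartments == 2L
    last <- dim(d)[1]
    np_ratio <- mean(d[last, , , ][np] / d[1, , , ][np])
    af_ratio <- mean(d[last, , , ][af] / d[1, , , ][af])
    expect_gt(np_ratio, af_ratio)
  }
})

test_that("HIZ mask is in the posterior fifth and lands in sub-region 5", {
  sp <- ideal_spec(grade = 3, hiz = TRUE)
  ph <- build_phantom(sp)
  hiz <- which(ph$truth$compartments == 3L, arr.ind = TRUE)
  expect_gt(nrow(hiz), 0)
  roi <- roi_from_truth(ph)
  part <- partition_subregions(roi)
  keys <- voxel_key(as.matrix(roi$voxels))
  expect_true(all(part$labels[keys %in% voxel_key(hiz)] == 5L))
  # masks disjoint subsets of the disc mask; HIZ empty when flag false
  expect_true(all(ph$truth$disc_labels[ph$truth$compartments > 0] > 0))
  ph0 <- build_phantom(ideal_spec(grade = 3, hiz = FALSE))
  expect_identical(sum(ph0$truth$compartments == 3L), 0L)
})

test_that("same seed gives bit-identical stacks, different seeds differ", {
  sp <- phantom_spec(seed = 11)
  a <- build_phantom(sp)
  b <- build_phantom(sp)
  expect_identical(a$series$data, b$series$data)
  c <- build_phantom(phantom_spec(seed = 12))
  expect_false(identical(a$series$data, c$series$data))
})

test_that("Rician noise has the Rayleigh mean at S0 = 0 and vanishes at high SNR", {
  ph <- build_phantom(phantom_spec(noise_sigma = 3, seed = 5))
  bg <- ph$series$data[1, , , ][ph$truth$disc_labels == 0]
  expect_equal(mean(bg), 3 * sqrt(pi / 2), tolerance = 0.02)
  # high SNR: empirical mean converges to the noise-free signal
  sp <- ideal_spec(noise_sigma = 0.5, seed = 6, np = 100, af = 45)
  ph2 <- build_phantom(sp)
  np <- ph2$truth$compartments == 1L
  expect_equal(mean(ph2$series$data[1, , , ][np]),
               sp$s0_np * exp(-sp$echo_times[1] / 100), tolerance = 0.01)
})

test_that("build_cohorts bookkeeping: counts, rates, grade gating", {
  coh <- build_cohorts(4, 3, hiz_rate_patients = 0.8, hiz_rate_controls = 0,
                       seed = 3, noise_sigma = 0)
  expect_equal(nrow(coh$table), 35)
  expect_equal(sum(coh$table$cohort == "patient"), 20)
  expect_equal(sum(coh$table$cohort == "control"), 15)
  # zero rate -> no HIZ in controls; HIZ only at grades >= 3
  expect_false(any(coh$table$hiz[coh$table$cohort == "control"]))
  expect_true(all(coh$table$grade[coh$table$hiz] >= 3))
  # ground truth agrees with the skeleton
  for (ph in coh$subjects) {
    expect_identical(ph$truth$discs$hiz, ph$meta$hiz)
    expect_identical(ph$truth$discs$grade, ph$meta$grade)
  }
})

test_that("modal grade follows the configured distribution", {
  coh <- build_cohorts(12, 2, seed = 4, noise_sigma = 0,
                       grade_probs_patients = c(0.05, 0.8, 0.05, 0.05, 0.05),
                       grade_probs_controls = c(0.05, 0.8, 0.05, 0.05, 0.05))
  tab <- table(coh$table$grade)
  expect_equal(names(which.max(tab)), "2")
  expect_equal(nrow(coh$table), 70)  # 5 discs x (12 + 2) subjects
})
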