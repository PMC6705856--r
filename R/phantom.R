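#' Multi-echo series container
#'
#' A 4-D magnitude image stack (echo x slice x row x col) with its echo
#' times and spatial geometry.
#'
#' @param data 4-D numeric array, dimensions echo x slice x row x col, all
#'   values >= 0.
#' @param echo_times strictly increasing positive echo times in ms, one per
#'   echo; at least 3 echoes.
#' @param geometry a [scan_geometry()].
#' @return Object of class `multi_echo_series`.
#' @export
multi_echo_series <- function(data, echo_times, geometry) {
  stop_if_not(length(dim(data)) == 4, "data must be a 4-D array (echo, slice, row, col)")
  stop_if_not(length(echo_times) >= 3, "at least 3 echoes are required")
  stop_if_not(all(diff(echo_times) > 0) && all(echo_times > 0),
              "echo times must be strictly increasing and positive")
  stop_if_not(dim(data)[1] == length(echo_times),
              "first dimension of data must match the number of echo times")
  stop_if_not(dim(data)[2] == length(geometry$slice_positions),
              "second dimension of data must match the number of slices")
  stop_if_not(all(data >= 0), "magnitude data must be non-negative")
  structure(list(data = data, echo_times = as.numeric(echo_times),
                 geometry = geometry),
            class = "multi_echo_series")
}

#' @export
print.multi_echo_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("multi_echo_series: %d echoes (%.1f-%.1f ms), %d slice(s), %d x %d\n",
              d[1], min(x$echo_times), max(x$echo_times), d[2], d[3], d[4]))
  invisible(x)
}

#' Default degeneration grade to compartment T2 table
#'
#' Nucleus pulposus (NP) T2 declines with Pfirrmann grade while annulus
#' fibrosus (AF) T2 stays flat, so the NP/AF distinction collapses as the
#' disc degenerates.  Values are plausible 1.5 T settings, not measurements
#' from any specific cohort.
#'
#' @return data.frame with columns `grade`, `np`, `af` (ms).
#' @export
default_t2_table <- function() {
  data.frame(grade = 1:5,
             np = c(120, 100, 80, 60, 50),
             af = c(45, 45, 45, 45, 45))
}

#' Describe one disc for the phantom generator
#'
#' @param level level label, e.g. "L4-L5".
#' @param center_mm in-plane centre (row mm, col mm) of the disc ellipse.
#' @param semi_axes_mm in-plane semi-axes in mm: (superior-inferior,
#'   anterior-posterior).  Defaults approximate a mid-sagittal lumbar disc
#'   cross-section.
#' @param grade Pfirrmann grade, integer 1-5.
#' @param hiz logical, whether the disc carries a posterior-annulus
#'   high-intensity zone (HIZ).
#' @return list of class `disc_descriptor`.
#' @export
disc_descriptor <- function(level, center_mm, semi_axes_mm = c(5, 17),
                            grade = 2L, hiz = FALSE) {
  stop_if_not(length(center_mm) == 2, "center_mm must be length 2")
  stop_if_not(length(semi_axes_mm) == 2 && all(semi_axes_mm > 0),
              "semi_axes_mm must be two positive values")
  stop_if_not(grade %in% 1:5, "grade must be an integer in 1..5")
  structure(list(level = level, center_mm = as.numeric(center_mm),
                 semi_axes_mm = as.numeric(semi_axes_mm),
                 grade = as.integer(grade), hiz = isTRUE(hiz)),
            class = "disc_descriptor")
}

#' Specify a synthetic multi-echo disc phantom
#'
#' The phantom is a parallel stack of (by default) three sagittal slices.
#' Each disc is an in-plane ellipse replicated over the slices, with a
#' high-T2 nucleus pulposus (NP) core inside a low-T2 annulus fibrosus (AF)
#' ring.  The NP T2 declines with Pfirrmann grade (see [default_t2_table()]),
#' emulating the loss of hydration and of NP/AF distinction in disc
#' degeneration.  A HIZ, when present, is a small bright (long-T2) focus in
#' the posterior annulus, confined to the posterior fifth of the disc's
#' anterior-posterior extent, and is accompanied by a reduction of the NP T2
#' (`hiz_distinction_factor`) representing the altered nucleus composition of
#' discs with annular lesions.
#'
#' Noise-free voxel signal is `S0 * exp(-t / T2)` per compartment; Rician
#' magnitude noise of standard deviation `noise_sigma` is applied to every
#' voxel of every echo.
#'
#' @param discs list of [disc_descriptor()]s.
#' @param shape grid shape: (slices, rows, cols).
#' @param spacing in-plane pixel spacing mm (row, col); default matches a
#'   220 mm field of view on a 256 matrix.
#' @param slice_thickness,slice_gap slice thickness and gap in mm.
#' @param echo_times echo times in ms; default is an 8-echo train at
#'   11.1 ms spacing, a common multi-echo spin-echo protocol.
#' @param t2_table grade -> (np, af) T2 table, see [default_t2_table()].
#' @param s0_np,s0_af proton-density signal amplitudes (arbitrary units).
#' @param np_fraction NP ellipse semi-axes as a fraction of the disc's.
#' @param blend_base,blend_per_grade half-width (in normalised ellipse
#'   radius) of the smooth NP-to-AF transition ramp:
#'   `w = blend_base + blend_per_grade * (grade - 1)`.  The ramp widens
#'   with degeneration, emulating the progressive loss of NP/AF
#'   distinction; ground-truth NP and AF masks are the *pure* cores
#'   (inside / outside the ramp), so they stay exactly piecewise-constant.
#'   Set both to 0 for an ideal hard-edged two-compartment disc.
#' @param np_jitter_sd,af_jitter_sd per-disc biological variability:
#'   lognormal SD of a multiplicative factor applied to the grade's NP /
#'   AF T2 (discs of the same grade differ substantially in vivo).  Set to
#'   0 for deterministic compartment values.
#' @param hiz_t2 HIZ T2 (ms); bright relative to both compartments.
#' @param hiz_radius_mm HIZ radius in mm (rendered on the middle slice
#'   only; slice spacing exceeds the lesion size).
#' @param hiz_ap_position HIZ centre position along the disc's
#'   anterior-posterior extent as a fraction in \[0.8, 1\] (posterior
#'   fifth); the default places the lesion in the outermost posterior
#'   annulus, where such zones are observed.
#' @param hiz_distinction_factor fraction of the grade's NP-AF T2 gap
#'   retained by HIZ discs: their NP T2 collapses towards the AF value
#'   (`af + factor * (np - af)`), modelling the loss of nucleus hydration
#'   and of NP/AF tissue distinction reported for discs with annular
#'   lesions (1 disables the coupling).
#' @param noise_sigma Rician noise sigma (same units as `s0_*`).
#' @param seed integer seed; identical spec + seed give bit-identical output.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(discs = list(disc_descriptor("L4-L5", center_mm = c(20, 24))),
                         shape = c(3, 48, 56),
                         spacing = c(0.86, 0.86),
                         slice_thickness = 3.5, slice_gap = 0.7,
                         echo_times = c(11.1, 22.2, 33.3, 44.4, 55.5, 66.6, 77.7, 88.8),
                         t2_table = default_t2_table(),
                         s0_np = 100, s0_af = 80,
                         np_fraction = 0.65,
                         blend_base = 0.06, blend_per_grade = 0.04,
                         np_jitter_sd = 0.12, af_jitter_sd = 0.06,
                         hiz_t2 = 150, hiz_radius_mm = 1.3,
                         hiz_ap_position = 0.97,
                         hiz_distinction_factor = 0.10,
                         noise_sigma = 2, seed = 1L) {
  spec <- structure(list(discs = discs, shape = as.integer(shape),
                         spacing = as.numeric(spacing),
                         slice_thickness = slice_thickness, slice_gap = slice_gap,
                         echo_times = as.numeric(echo_times),
                         t2_table = t2_table,
                         s0_np = s0_np, s0_af = s0_af,
                         np_fraction = np_fraction,
                         blend_base = blend_base, blend_per_grade = blend_per_grade,
                         np_jitter_sd = np_jitter_sd, af_jitter_sd = af_jitter_sd,
                         hiz_t2 = hiz_t2, hiz_radius_mm = hiz_radius_mm,
                         hiz_ap_position = hiz_ap_position,
                         hiz_distinction_factor = hiz_distinction_factor,
                         noise_sigma = noise_sigma, seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stop_if_not(all(spec$echo_times > 0) && all(diff(spec$echo_times) > 0),
              "invalid spec: echo times must be strictly increasing and positive")
  stop_if_not(length(spec$shape) == 3 && all(spec$shape >= 1),
              "invalid spec: shape must be (slices, rows, cols)")
  tt <- spec$t2_table
  stop_if_not(identical(tt$grade, 1:5), "invalid spec: t2_table must cover grades 1..5")
  stop_if_not(all(tt$np[1:3] >= tt$af[1:3]),
              "invalid spec: NP T2 must be >= AF T2 for grades 1-3")
  gap <- tt$np - tt$af
  stop_if_not(all(diff(gap) <= 0),
              "invalid spec: NP/AF T2 gap must converge monotonically with grade")
  stop_if_not(spec$hiz_ap_position >= 0.8 && spec$hiz_ap_position <= 1,
              "invalid spec: HIZ centre must lie in the posterior fifth of the disc (hiz_ap_position in [0.8, 1])")
  stop_if_not(spec$np_fraction > 0 && spec$np_fraction < 1,
              "invalid spec: np_fraction must be in (0, 1)")
  stop_if_not(spec$blend_base >= 0 && spec$blend_per_grade >= 0,
              "invalid spec: blend widths must be >= 0")
  stop_if_not(spec$np_jitter_sd >= 0 && spec$af_jitter_sd >= 0,
              "invalid spec: jitter SDs must be >= 0")
  stop_if_not(spec$noise_sigma >= 0, "invalid spec: noise_sigma must be >= 0")
  for (d in spec$discs) stop_if_not(inherits(d, "disc_descriptor"),
                                    "invalid spec: discs must be disc_descriptor objects")
  invisible(spec)
}

# magnitude of complex Gaussian noise added to a noise-free signal
rician <- function(s, sigma) {
  if (sigma <= 0) return(s)
  sqrt((s + stats::rnorm(length(s), 0, sigma))^2 +
         stats::rnorm(length(s), 0, sigma)^2)
}

#' Build a synthetic multi-echo disc phantom
#'
#' Renders the discs described by a [phantom_spec()] into a noise-free
#' compartment model (NP / AF / HIZ), simulates the multi-echo spin-echo
#' magnitude signal `S0 * exp(-t/T2)` at the spec's echo times, applies
#' Rician noise, and returns the series together with ground-truth label
#' maps and a structural reference image on its own (offset, coarser) grid
#' for segmentation.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `ivd_phantom` with elements:
#'   * `series`: [multi_echo_series()];
#'   * `truth`: ground truth — `disc_labels` (slice x row x col integer
#'     array, 0 = background, i = disc i), `compartments` (0 background,
#'     1 NP, 2 AF, 3 HIZ), `discs` (data.frame of level, grade, hiz and the
#'     true compartment T2 values), `t2_true` (noise-free per-voxel T2);
#'   * `structural`: list with `image` (slice x row x col array) and
#'     `geometry`, emulating the T1-weighted series the discs are outlined
#'     on (different field of view and pixel spacing than the T2 map).
#' @export
build_phantom <- function(spec) {
  validate_phantom_spec(spec)
  nsl <- spec$shape[1]; nr <- spec$shape[2]; nc <- spec$shape[3]
  row_mm <- (seq_len(nr) - 1) * spec$spacing[1]
  col_mm <- (seq_len(nc) - 1) * spec$spacing[2]
  mid <- ceiling(nsl / 2)

  t2 <- array(0, c(nsl, nr, nc))
  s0 <- array(0, c(nsl, nr, nc))
  disc_lab <- array(0L, c(nsl, nr, nc))
  comp_lab <- array(0L, c(nsl, nr, nc))
  # in-plane helper grids (row varies down rows of the matrix)
  R <- matrix(row_mm, nr, nc)
  C <- matrix(col_mm, nr, nc, byrow = TRUE)

  # per-disc biological jitter, drawn first in the seeded stream so the
  # compartment values are reproducible independently of the noise draw
  nd <- length(spec$discs)
  jit <- with_seed(spec$seed, {
    list(np = exp(stats::rnorm(nd, 0, spec$np_jitter_sd)),
         af = exp(stats::rnorm(nd, 0, spec$af_jitter_sd)))
  })

  disc_meta <- list()
  for (i in seq_along(spec$discs)) {
    d <- spec$discs[[i]]
    a <- d$semi_axes_mm[1]; b <- d$semi_axes_mm[2]
    rho <- sqrt(((R - d$center_mm[1]) / a)^2 + ((C - d$center_mm[2]) / b)^2)
    full2d <- rho <= 1
    # smooth NP -> AF transition ramp; pure cores stay piecewise-constant
    w <- spec$blend_base + spec$blend_per_grade * (d$grade - 1)
    cnp <- spec$np_fraction
    if (w > 0) {
      u <- pmin(pmax((cnp + w - rho) / (2 * w), 0), 1)
      g <- u * u * (3 - 2 * u)
    } else {
      g <- (rho <= cnp) * 1
    }
    np2d <- full2d & (rho <= cnp - w)
    af2d <- full2d & (rho >= cnp + w)
    hiz2d <- matrix(FALSE, nr, nc)
    if (d$hiz) {
      hc_col <- d$center_mm[2] - b + spec$hiz_ap_position * 2 * b
      hiz2d <- ((R - d$center_mm[1])^2 + (C - hc_col)^2) <= spec$hiz_radius_mm^2
      hiz2d <- hiz2d & full2d & !np2d
      stop_if_not(any(hiz2d),
                  "invalid spec: HIZ does not intersect the annulus on this grid")
    }
    np_t2 <- spec$t2_table$np[d$grade] * jit$np[i]
    af_t2 <- spec$t2_table$af[d$grade] * jit$af[i]
    if (d$hiz) np_t2 <- af_t2 + spec$hiz_distinction_factor * (np_t2 - af_t2)
    t2_2d <- af_t2 + (np_t2 - af_t2) * g
    s0_2d <- spec$s0_af + (spec$s0_np - spec$s0_af) * g
    for (s in seq_len(nsl)) {
      fl <- full2d
      if (any(disc_lab[s, , ][fl] != 0)) stop("invalid spec: discs overlap")
      dl <- disc_lab[s, , ]; cl <- comp_lab[s, , ]
      t2s <- t2[s, , ]; s0s <- s0[s, , ]
      dl[fl] <- i
      cl[fl] <- 4L                      # transition zone by default
      cl[np2d] <- 1L
      cl[af2d] <- 2L
      t2s[fl] <- t2_2d[fl]
      s0s[fl] <- s0_2d[fl]
      if (d$hiz && s == mid) {
        cl[hiz2d] <- 3L
        t2s[hiz2d] <- spec$hiz_t2
        s0s[hiz2d] <- spec$s0_np
      }
      disc_lab[s, , ] <- dl; comp_lab[s, , ] <- cl
      t2[s, , ] <- t2s; s0[s, , ] <- s0s
    }
    disc_meta[[i]] <- data.frame(disc = i, level = d$level, grade = d$grade,
                                 hiz = d$hiz, t2_np = np_t2, t2_af = af_t2,
                                 t2_hiz = if (d$hiz) spec$hiz_t2 else NA_real_)
  }
  discs_df <- do.call(rbind, disc_meta)

  slice_pos <- (seq_len(nsl) - 1) * (spec$slice_thickness + spec$slice_gap)
  geom <- scan_geometry(spacing = spec$spacing, slice_positions = slice_pos,
                        origin = c(0, 0), posterior = c(0, 1),
                        slice_thickness = spec$slice_thickness)

  ne <- length(spec$echo_times)
  dat <- array(0, c(ne, nsl, nr, nc))
  decay_safe <- ifelse(t2 > 0, t2, 1)   # background has s0 = 0 anyway
  # separate stream from the jitter draw above
  noise_seed <- (spec$seed + 104729L) %% (2^31 - 1)
  out <- with_seed(noise_seed, {
    for (e in seq_len(ne)) {
      sig <- s0 * exp(-spec$echo_times[e] / decay_safe)
      sig[s0 == 0] <- 0
      dat[e, , , ] <- array(rician(sig, spec$noise_sigma), dim(sig))
    }
    # structural reference: different FOV/pixel spacing, smooth in-disc shading
    st_sp <- c(0.9375, 0.9375)
    st_or <- c(-4.2, -3.4)
    st_nr <- ceiling((max(row_mm) + 8.4) / st_sp[1])
    st_nc <- ceiling((max(col_mm) + 6.8) / st_sp[2])
    st_R <- matrix(st_or[1] + (seq_len(st_nr) - 1) * st_sp[1], st_nr, st_nc)
    st_C <- matrix(st_or[2] + (seq_len(st_nc) - 1) * st_sp[2], st_nr, st_nc, byrow = TRUE)
    base <- matrix(20, st_nr, st_nc)
    for (d in spec$discs) {
      a <- d$semi_axes_mm[1]; b <- d$semi_axes_mm[2]
      rho2 <- ((st_R - d$center_mm[1]) / a)^2 + ((st_C - d$center_mm[2]) / b)^2
      inside <- rho2 <= 1
      base[inside] <- 100 * (1 - 0.2 * rho2[inside])
    }
    st <- array(0, c(nsl, st_nr, st_nc))
    for (s in seq_len(nsl)) {
      st[s, , ] <- base + matrix(stats::rnorm(st_nr * st_nc, 0, 1), st_nr, st_nc)
    }
    list(dat = dat, st = st,
         st_geom = scan_geometry(spacing = st_sp, slice_positions = slice_pos,
                                 origin = st_or, posterior = c(0, 1),
                                 slice_thickness = spec$slice_thickness))
  })

  structure(list(
    series = multi_echo_series(out$dat, spec$echo_times, geom),
    truth = list(disc_labels = disc_lab, compartments = comp_lab,
                 discs = discs_df, t2_true = t2, s0_true = s0),
    structural = list(image = out$st, geometry = out$st_geom),
    spec = spec), class = "ivd_phantom")
}

#' Generate patient-like and control-like phantom cohorts
#'
#' Each subject carries five lumbar discs (L1-L2 ... L5-S1) stacked in one
#' sagittal phantom.  Because the generator emulates a *specific* published
#' cohort structure rather than an infinite population, Pfirrmann grades
#' are quota-allocated: per cohort, the disc count is split over grades by
#' largest-remainder rounding of the configured distribution and the grade
#' labels are then randomly permuted over the cohort's discs.  HIZ lesions
#' are likewise quota-assigned — only discs of grade >= 3 are eligible
#' (HIZs are not observed in grades 1-2), and `round(rate * n_eligible)`
#' eligible discs are drawn at random.  Per-subject random streams are
#' derived deterministically from the top-level seed.
#'
#' @param n_patients,n_controls subject counts (>= 1).
#' @param hiz_rate_patients,hiz_rate_controls fraction in \[0,1\] of
#'   grade >= 3 discs that carry an HIZ, per cohort.
#' @param seed top-level seed.
#' @param grade_probs_patients,grade_probs_controls length-5 probability
#'   vectors over Pfirrmann grades 1..5.  Defaults follow the grade mix of a
#'   published lumbar cohort (mode at grade 2, few grade-5 discs), with the
#'   patient-like cohort shifted towards higher grades.
#' @param ... further arguments passed to [phantom_spec()] (e.g.
#'   `noise_sigma`, `hiz_distinction_factor`).
#' @return list with `subjects` (list of [build_phantom()] results, each
#'   with a `meta` data.frame attached) and `table`, a cohort-table skeleton
#'   (one row per disc: subject, cohort, level, grade, hiz).
#' @export
build_cohorts <- function(n_patients, n_controls,
                          hiz_rate_patients = 0.35, hiz_rate_controls = 0.25,
                          seed = 1L,
                          grade_probs_patients = c(12, 55, 33, 22, 2) / 124,
                          grade_probs_controls = c(7, 36, 6, 9, 1) / 59,
                          ...) {
  stop_if_not(n_patients >= 1 && n_controls >= 1, "counts must be >= 1")
  stop_if_not(hiz_rate_patients >= 0 && hiz_rate_patients <= 1 &&
                hiz_rate_controls >= 0 && hiz_rate_controls <= 1,
              "HIZ rates must be in [0, 1]")
  levels5 <- c("L1-L2", "L2-L3", "L3-L4", "L4-L5", "L5-S1")
  n <- n_patients + n_controls
  plan <- with_seed(seed, {
    subj_seeds <- sample.int(2^31 - 2, n)
    cohort_plan <- function(n_subj, probs, rate, prefix) {
      n_discs <- 5 * n_subj
      grades <- sample(rep.int(1:5, quota_counts(n_discs, probs)))
      hiz <- rep(FALSE, n_discs)
      eligible <- which(grades >= 3)
      n_hiz <- round(rate * length(eligible))
      if (n_hiz > 0) hiz[sample(eligible, n_hiz)] <- TRUE
      data.frame(
        subject = sprintf("%s%02d", prefix, rep(seq_len(n_subj), each = 5)),
        cohort = if (prefix == "P") "patient" else "control",
        level = rep(levels5, n_subj), grade = grades, hiz = hiz,
        stringsAsFactors = FALSE)
    }
    out <- rbind(cohort_plan(n_patients, grade_probs_patients,
                             hiz_rate_patients, "P"),
                 cohort_plan(n_controls, grade_probs_controls,
                             hiz_rate_controls, "C"))
    out$seed <- rep(subj_seeds, each = 5)
    out
  })

  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    meta <- plan[plan$subject == unique(plan$subject)[i], ]
    discs <- lapply(seq_len(5), function(k) {
      disc_descriptor(meta$level[k],
                      center_mm = c(14 + (k - 1) * 30, 24),
                      semi_axes_mm = c(5, 17),
                      grade = meta$grade[k], hiz = meta$hiz[k])
    })
    sp <- phantom_spec(discs = discs,
                       shape = c(3, ceiling((14 + 4 * 30 + 14) / 0.86), 56),
                       seed = meta$seed[1], ...)
    ph <- build_phantom(sp)
    ph$meta <- meta[, c("subject", "cohort", "level", "grade", "hiz")]
    subjects[[i]] <- ph
  }
  table <- plan[, c("subject", "cohort", "level", "grade", "hiz")]
  rownames(table) <- NULL
  list(subjects = subjects, table = table)
}
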