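#' Fit the mono-exponential T2 model to one voxel
#'
#' The multi-echo spin-echo signal is modelled as a pure mono-exponential
#' decay `S(t) = S0 * exp(-t / T2)`.  The log-linear method performs
#' weighted least squares on `ln S` versus `t` with weights proportional to
#' the squared signal, which counteracts the variance distortion introduced
#' by the log transform; the nonlinear method refines that solution by
#' least squares on the original scale.
#'
#' A voxel is invalid when any echo magnitude is non-positive (the
#' log-domain fit is undefined), when the fitted slope is non-negative (no
#' decay), or when the fitted T2 exceeds `ceiling`.
#'
#' @param signal per-echo magnitudes.
#' @param echo_times echo times in ms, strictly increasing, length >= 3.
#' @param method `"loglinear"` (default) or `"nonlinear"`.
#' @param ceiling hard upper bound on T2 in ms (default unbounded here; see
#'   [truncate_bright_noise()] for map-level truncation).
#' @return list with `s0`, `t2` (ms), `valid`, `r2` (weighted R-squared of
#'   the log-linear fit).
#' @export
fit_t2_voxel <- function(signal, echo_times,
                         method = c("loglinear", "nonlinear"),
                         ceiling = Inf) {
  method <- match.arg(method)
  stop_if_not(length(echo_times) >= 3, "at least 3 echoes are required")
  stop_if_not(all(diff(echo_times) > 0), "echo times must be strictly increasing")
  stop_if_not(length(signal) == length(echo_times),
              "signal and echo_times must have equal length")
  invalid <- list(s0 = NA_real_, t2 = NA_real_, valid = FALSE, r2 = NA_real_)
  if (any(!is.finite(signal)) || any(signal <= 0)) return(invalid)

  t <- as.numeric(echo_times)
  y <- log(signal)
  w <- signal^2
  sw <- sum(w); swt <- sum(w * t); swy <- sum(w * y)
  swtt <- sum(w * t^2); swty <- sum(w * t * y)
  den <- sw * swtt - swt^2
  slope <- (sw * swty - swt * swy) / den
  inter <- (swy - slope * swt) / sw
  if (!is.finite(slope) || slope >= 0) return(invalid)
  s0 <- exp(inter); t2 <- -1 / slope
  ybar <- swy / sw
  sstot <- sum(w * (y - ybar)^2)
  ssres <- sum(w * (y - (inter + slope * t))^2)
  r2 <- if (sstot > 0) 1 - ssres / sstot else NA_real_

  if (method == "nonlinear") {
    ref <- refine_exp_fit(signal, t, s0, t2)
    s0 <- ref$s0; t2 <- ref$t2
    if (!is.finite(t2) || t2 <= 0 || !is.finite(s0) || s0 <= 0) return(invalid)
  }
  if (t2 > ceiling) return(list(s0 = s0, t2 = t2, valid = FALSE, r2 = r2))
  list(s0 = s0, t2 = t2, valid = TRUE, r2 = r2)
}

# least-squares refinement of (S0, T2) on the original signal scale,
# started from the log-linear solution
refine_exp_fit <- function(s, t, s0_0, t2_0) {
  sse0 <- sum((s - s0_0 * exp(-t / t2_0))^2)
  if (sse0 <= 1e-24 * sum(s^2)) return(list(s0 = s0_0, t2 = t2_0))  # already exact
  df <- data.frame(s = s, t = t)
  # convergence is judged below by the achieved SSE, so nls "iteration
  # limit" warnings carry no information here
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(s ~ S0 * exp(-t / T2), data = df,
                 start = list(S0 = s0_0, T2 = t2_0),
                 control = stats::nls.control(maxiter = 500, tol = 1e-10,
                                              minFactor = 1e-12,
                                              warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    if (sum((s - cf[["S0"]] * exp(-t / cf[["T2"]]))^2) <= sse0 + 1e-12) {
      return(list(s0 = cf[["S0"]], t2 = cf[["T2"]]))
    }
  }
  # fallback: derivative-free minimisation from the log-linear start
  obj <- function(p) sum((s - p[1] * exp(-t / p[2]))^2)
  op <- stats::optim(c(s0_0, t2_0), obj, method = "Nelder-Mead",
                     control = list(reltol = 1e-14, maxit = 5000))
  list(s0 = op$par[1], t2 = op$par[2])
}

#' Fit a voxel-wise T2 map
#'
#' Applies the mono-exponential fit of [fit_t2_voxel()] to every voxel of a
#' multi-echo series (optionally restricted to a mask), producing per-voxel
#' T2, S0, validity flags and the log-linear fit's weighted R-squared.  The
#' log-linear path is fully vectorised; the nonlinear path refines each
#' masked voxel individually.
#'
#' @param series a [multi_echo_series()].
#' @param mask optional: a logical array (slice x row x col) or a
#'   data.frame with columns `slice`, `row`, `col`; voxels outside the mask
#'   are left invalid and NA.
#' @param method `"loglinear"` or `"nonlinear"`.
#' @param ceiling hard T2 ceiling passed to the voxel fit (default `Inf`).
#' @return object of class `t2_map`: list with arrays `t2`, `s0`, `valid`,
#'   `r2` (slice x row x col) and the source `geometry` and `echo_times`.
#' @export
fit_t2_map <- function(series, mask = NULL,
                       method = c("loglinear", "nonlinear"), ceiling = Inf) {
  method <- match.arg(method)
  stop_if_not(inherits(series, "multi_echo_series"), "series must be a multi_echo_series")
  d <- dim(series$data)
  ne <- d[1]; vshape <- d[2:4]
  nvox <- prod(vshape)
  t <- series$echo_times

  keep <- rep(TRUE, nvox)
  if (!is.null(mask)) {
    if (is.array(mask) || is.matrix(mask)) {
      stop_if_not(all(dim(mask) == vshape), "mask dimensions must match the series grid")
      keep <- as.vector(mask)
    } else {
      stop_if_not(all(c("slice", "row", "col") %in% names(mask)),
                  "mask must be logical array or data.frame(slice,row,col)")
      if (any(mask$slice < 1 | mask$slice > vshape[1] |
                mask$row < 1 | mask$row > vshape[2] |
                mask$col < 1 | mask$col > vshape[3])) {
        stop("mask lies outside the image grid")
      }
      keep <- rep(FALSE, nvox)
      idx <- mask$slice + (mask$row - 1) * vshape[1] +
        (mask$col - 1) * vshape[1] * vshape[2]
      keep[idx] <- TRUE
    }
  }

  # voxels x echoes matrix; voxel linear order matches array(slice,row,col)
  S <- matrix(aperm(series$data, c(2, 3, 4, 1)), nrow = nvox, ncol = ne)
  t2v <- rep(NA_real_, nvox); s0v <- rep(NA_real_, nvox)
  r2v <- rep(NA_real_, nvox); okv <- rep(FALSE, nvox)

  cand <- which(keep & rowSums(S <= 0 | !is.finite(S)) == 0)
  if (length(cand)) {
    Sm <- S[cand, , drop = FALSE]
    Y <- log(Sm); W <- Sm^2
    sw <- rowSums(W)
    swt <- drop(W %*% t)
    swy <- rowSums(W * Y)
    swtt <- drop(W %*% t^2)
    swty <- drop((W * Y) %*% t)
    den <- sw * swtt - swt^2
    slope <- (sw * swty - swt * swy) / den
    inter <- (swy - slope * swt) / sw
    ybar <- swy / sw
    sstot <- rowSums(W * (Y - ybar)^2)
    ssres <- rowSums(W * (Y - (inter + outer(slope, t)))^2)
    r2 <- ifelse(sstot > 0, 1 - ssres / sstot, NA_real_)
    ok <- is.finite(slope) & slope < 0
    t2fit <- -1 / slope
    s0fit <- exp(inter)
    if (method == "nonlinear") {
      for (j in which(ok)) {
        ref <- refine_exp_fit(Sm[j, ], t, s0fit[j], t2fit[j])
        t2fit[j] <- ref$t2; s0fit[j] <- ref$s0
      }
      ok <- ok & is.finite(t2fit) & t2fit > 0 & is.finite(s0fit) & s0fit > 0
    }
    ok <- ok & t2fit <= ceiling
    t2v[cand] <- ifelse(is.finite(slope) & slope < 0, t2fit, NA_real_)
    s0v[cand] <- ifelse(is.finite(slope) & slope < 0, s0fit, NA_real_)
    r2v[cand] <- r2
    okv[cand] <- ok
  }

  structure(list(t2 = array(t2v, vshape), s0 = array(s0v, vshape),
                 valid = array(okv, vshape), r2 = array(r2v, vshape),
                 geometry = series$geometry, echo_times = t,
                 method = method),
            class = "t2_map")
}

#' @export
print.t2_map <- function(x, ...) {
  cat(sprintf("t2_map (%s): %d/%d valid voxels, T2 range %.1f-%.1f ms\n",
              x$method, sum(x$valid), length(x$valid),
              suppressWarnings(min(x$t2[x$valid])),
              suppressWarnings(max(x$t2[x$valid]))))
  invisible(x)
}

#' Truncate bright noise in a T2 map
#'
#' Voxels whose fitted T2 exceeds `ceiling` are marked invalid (removed
#' from all downstream statistics); all other voxels are untouched.  Fitted
#' T2 values far above tissue range arise from noise-only voxels and would
#' otherwise distort histogram metrics.  The operation is idempotent.
#'
#' @param map a `t2_map`.
#' @param ceiling positive T2 ceiling in ms (default 300).
#' @return the truncated `t2_map`.
#' @export
truncate_bright_noise <- function(map, ceiling = 300) {
  stop_if_not(inherits(map, "t2_map"), "map must be a t2_map")
  stop_if_not(is.numeric(ceiling) && length(ceiling) == 1 && ceiling > 0,
              "ceiling must be a positive number (ms)")
  drop_idx <- map$valid & !is.na(map$t2) & map$t2 > ceiling
  map$valid[drop_idx] <- FALSE
  map
}
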