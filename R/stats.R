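#' Mann-Whitney U test
#'
#' Two-sided rank-sum test.  In exact mode (the default whenever the pooled
#' sample has at most 20 observations) the null distribution of U is
#' obtained by full enumeration of all group assignments of the pooled
#' values, which handles ties exactly; the two-sided p-value is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`.  In normal mode the
#' tie-corrected Gaussian approximation with continuity correction is used.
#'
#' @param a,b numeric samples, both nonempty.
#' @param mode `"auto"` (exact when `length(a) + length(b) <= 20`),
#'   `"exact"` or `"normal"`.
#' @return list with `U` (statistic for sample `a`), `p` (two-sided),
#'   `mode` actually used.
#' @export
mann_whitney_u <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  stop_if_not(length(a) >= 1 && length(b) >= 1, "both samples must be nonempty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (mode == "auto") mode <- if (n <= 20) "exact" else "normal"

  if (mode == "exact") {
    stop_if_not(n <= 20, "exact mode supports pooled n <= 20")
    idx <- utils::combn(n, na)
    us <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    eps <- 1e-9
    pl <- mean(us <= u + eps)
    pg <- mean(us >= u - eps)
    p <- min(1, 2 * min(pl, pg))
  } else {
    mu <- na * nb / 2
    tie <- table(r)
    sig2 <- na * nb / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- u - mu
      cc <- sign(z) * 0.5
      z <- (z - cc) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(U = u, p = p, mode = mode)
}

#' Cohen's kappa for two raters
#'
#' Unweighted kappa from the contingency table of two equal-length ordinal
#' rating vectors (e.g. Pfirrmann grades): `(p_o - p_e) / (1 - p_e)` where
#' `p_o` is the observed and `p_e` the chance agreement.
#'
#' @param r1,r2 rating vectors of equal length >= 2; at least two distinct
#'   categories must be present overall.
#' @return list with `kappa` (NA and `defined = FALSE` when both raters are
#'   constant and equal, where chance agreement is 1), `p_o`, `p_e`, `n`.
#' @export
cohens_kappa <- function(r1, r2) {
  stop_if_not(length(r1) == length(r2), "rating vectors must have equal length")
  stop_if_not(length(r1) >= 2, "at least 2 rated items are required")
  keep <- !is.na(r1) & !is.na(r2)
  n_dropped <- sum(!keep)
  r1 <- r1[keep]; r2 <- r2[keep]
  lev <- sort(unique(c(r1, r2)))
  stop_if_not(length(lev) >= 2, "at least 2 categories must be present")
  tab <- table(factor(r1, levels = lev), factor(r2, levels = lev)) / length(r1)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (1 - pe < .Machine$double.eps) {
    return(list(kappa = NA_real_, p_o = po, p_e = pe, n = length(r1),
                n_dropped = n_dropped, defined = FALSE))
  }
  list(kappa = (po - pe) / (1 - pe), p_o = po, p_e = pe, n = length(r1),
       n_dropped = n_dropped, defined = TRUE)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation, computed from the two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`
#' with `MSR` the between-item, `MSC` the between-rater and `MSE` the
#' residual mean square.  The confidence interval uses the standard F-based
#' construction (McGraw-Wong).
#'
#' @param ratings numeric matrix, items in rows, raters in columns
#'   (n >= 2 items, k >= 2 raters); rows with missing values are dropped
#'   and counted.
#' @param conf confidence level for the interval.
#' @return list with `icc`, `lower`, `upper`, the mean squares, `n`, `k`,
#'   and `defined` (FALSE when between-item variance is zero).
#' @export
icc_2_1 <- function(ratings, conf = 0.95) {
  x <- as.matrix(ratings)
  stop_if_not(is.numeric(x), "ratings must be numeric")
  keep <- stats::complete.cases(x)
  n_dropped <- sum(!keep)
  x <- x[keep, , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  stop_if_not(n >= 2 && k >= 2, "need >= 2 items and >= 2 raters")
  rowm <- rowMeans(x); colm <- colMeans(x); grand <- mean(x)
  if (stats::var(rowm) == 0) {
    return(list(icc = NA_real_, lower = NA_real_, upper = NA_real_,
                msr = NA_real_, msc = NA_real_, mse = NA_real_,
                n = n, k = k, n_dropped = n_dropped, defined = FALSE))
  }
  msr <- k * stats::var(rowm)
  msc <- n * stats::var(colm)
  sst <- sum((x - grand)^2)
  sse <- sst - (n - 1) * msr - (k - 1) * msc
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf
  a <- k * icc / (n * (1 - icc))
  bb <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + bb * mse)^2 /
    ((a * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  list(icc = icc, lower = lower, upper = upper,
       msr = msr, msc = msc, mse = mse, n = n, k = k,
       n_dropped = n_dropped, defined = TRUE)
}

#' Interpret an agreement coefficient
#'
#' Maps a kappa value to the Landis-Koch bands (slight / fair / moderate /
#' substantial / almost perfect) or an ICC to the Cicchetti bands (poor /
#' fair / good / excellent).  Bands are applied with cut points at the
#' printed upper edges, so a value falling in a printed gap (e.g. kappa
#' 0.205, between 0.20 and 0.21) is assigned to the higher band.
#'
#' @param value finite coefficient.
#' @param scale `"landis_koch"` (kappa) or `"cicchetti"` (ICC).
#' @return character label.
#' @export
interpret_agreement <- function(value, scale = c("landis_koch", "cicchetti")) {
  scale <- match.arg(scale)
  stop_if_not(is.finite(value), "value must be finite")
  if (scale == "landis_koch") {
    if (value < 0) return("poor")
    if (value <= 0.20) return("slight")
    if (value <= 0.40) return("fair")
    if (value <= 0.60) return("moderate")
    if (value <= 0.80) return("substantial")
    return("almost perfect")
  }
  if (value < 0.40) return("poor")
  if (value < 0.60) return("fair")
  if (value <= 0.74) return("good")
  "excellent"
}
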