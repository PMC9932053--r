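#' Cumulative-sum profiles
#'
#' The profile is the running cumulative sum of a data series; it is the
#' object actually detrended by DFA and its multivariate extensions.
#'
#' @param x numeric vector, or matrix with one series per column.
#' @return Object of the same shape containing cumulative sums.
#' @export
dfa_profile <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) < 1L) stop("empty series")
    apply(x, 2, cumsum)
  } else {
    if (length(x) < 1L) stop("empty series")
    cumsum(x)
  }
}

#' Default logarithmic scale grid
#'
#' Roughly `n_scales` log-spaced window sizes between `s_min` and
#' `s_max` frames.  The lower bound keeps at least `order + 3` points
#' per window beyond the polynomial degrees of freedom; the upper bound
#' `N/4` is the usual DFA variance-control limit.
#'
#' @param n series length in frames.
#' @param order detrending polynomial order (default 2).
#' @param n_scales target number of scales (default 20).
#' @param s_min,s_max grid limits in frames.
#' @return Increasing integer vector of scales (frames).
#' @export
scale_grid <- function(n, order = 2L, n_scales = 20L,
                       s_min = max(8L, order + 3L), s_max = floor(n / 4)) {
  if (s_max < s_min)
    stop("series too short for a scale grid: N = ", n)
  unique(round(exp(seq(log(s_min), log(s_max), length.out = n_scales))))
}

# Sliding-window detrended covariance over a scale grid.  Two routes:
#
# * explicit: residuals of every window are formed directly (blocked
#   over window starts to bound memory) and cross-multiplied.  The
#   pointwise subtraction profile - fit keeps the relative error of a
#   residual near eps * |profile| / |residual|, which is benign even
#   for very smooth (alpha ~ 2) series.  Cost O((N-s)(s+1)) per scale,
#   used for small scales and as a fallback.
#
# * moment: the residual cross-sum of a window equals
#   w_i' w_j - S_i' (V'V)^{-1} S_j with V the local polynomial design
#   and S_p the window polynomial moments, all obtainable from global
#   cumulative sums, so a scale costs O(N m (order + m)) independent of
#   s.  Subtracting two large squared quantities cancels, so this route
#   is only used at large scales where residuals are a sizable fraction
#   of the windowed profile; a non-positive diagonal triggers the
#   explicit fallback.
#
# Residuals are invariant under adding any global polynomial of degree
# <= order to a profile (its restriction to a window is absorbed by
# the fit), so profiles are pre-reduced by a global fit to curb
# cancellation at large N.
dpcca_core <- function(X, scales, order = 2L) {
  X <- as.matrix(X)
  N <- nrow(X); m <- ncol(X)
  order <- as.integer(order)
  if (order < 1L || order > 3L) stop("detrending order must be 1, 2 or 3")
  Y <- apply(X, 2, cumsum)
  Y <- matrix(Y, nrow = N, dimnames = list(NULL, colnames(X)))
  tt <- seq_len(N) - (N + 1) / 2
  Vg <- outer(tt / max(abs(tt), 1), 0:order, "^")
  Y <- qr.resid(qr(Vg), Y)
  Cq <- lapply(0:order, function(q) rbind(0, apply(tt^q * Y, 2, cumsum)))

  out <- vector("list", length(scales))
  for (si in seq_along(scales)) {
    s <- as.integer(scales[si])
    if (s + 1L > N || s + 1L < order + 2L) next
    F2 <- if ((N - s) * (s + 1) <= 2^24) {
      f2_scale_explicit(Y, s, order)
    } else {
      cand <- f2_scale_moment(Y, s, order, Cq, tt)
      if (any(diag(cand) <= 0)) f2_scale_explicit(Y, s, order) else cand
    }
    dimnames(F2) <- list(colnames(X), colnames(X))
    out[[si]] <- F2
  }
  out
}

f2_scale_explicit <- function(Y, s, order) {
  N <- nrow(Y); m <- ncol(Y)
  u <- ((0:s) - s / 2) / max(s / 2, 1)
  V <- outer(u, 0:order, "^")
  VtVi <- solve(crossprod(V))
  starts <- seq_len(N - s)
  block <- max(1L, 2L^21L %/% (s + 1L))
  F2 <- matrix(0, m, m)
  for (chunk in split(starts, ceiling(starts / block))) {
    idx <- outer(chunk, 0:s, "+")
    R <- matrix(0, length(chunk) * (s + 1L), m)
    for (j in seq_len(m)) {
      Wm <- matrix(Y[idx, j], nrow = length(chunk))
      R[, j] <- Wm - ((Wm %*% V) %*% VtVi) %*% t(V)
    }
    F2 <- F2 + crossprod(R)
  }
  F2 / ((N - s) * (s + 1L))
}

f2_scale_moment <- function(Y, s, order, Cq, tt) {
  N <- nrow(Y); m <- ncol(Y)
  h <- s / 2
  a <- seq_len(N - s)                       # window starts
  cen <- tt[a] + h                          # window centers (tt units)
  # raw windowed cross-sums via per-sample window multiplicity
  w <- pmin(seq_len(N), s + 1L, N - s, N - seq_len(N) + 1L)
  sumD <- crossprod(Y, Y * w)
  # window moments S_p (scaled local coordinate u = (tt - cen)/h)
  Tq <- lapply(Cq, function(C) C[a + s + 1L, , drop = FALSE] -
                               C[a, , drop = FALSE])
  S <- vector("list", order + 1L)
  for (p in 0:order) {
    acc <- 0
    for (q in 0:p)
      acc <- acc + choose(p, q) * (-cen)^(p - q) * Tq[[q + 1L]]
    S[[p + 1L]] <- acc / h^p
  }
  u <- ((0:s) - h) / h
  V <- outer(u, 0:order, "^")
  W <- solve(crossprod(V))
  cross <- matrix(0, m, m)
  for (p in 0:order)
    for (q in 0:order)
      if (W[p + 1L, q + 1L] != 0)
        cross <- cross + W[p + 1L, q + 1L] * crossprod(S[[p + 1L]],
                                                      S[[q + 1L]])
  (sumD - (cross + t(cross)) / 2) / ((N - s) * (s + 1L))
}

#' Sliding-window detrending residuals
#'
#' Splits a profile into all `N - s` sliding windows of `s + 1` points,
#' fits a polynomial of degree `order` in each by least squares and
#' returns the residuals.  The flattened residual series has length
#' `(N - s)(s + 1)`, the normalizer of the detrended covariance.
#'
#' @param profile numeric vector: a cumulative-sum profile (see
#'   [dfa_profile()]).
#' @param s scale (window size parameter) in frames; windows span
#'   `s + 1` samples.
#' @param order polynomial detrending order (default 2).
#' @param flat if `TRUE` (default) return the window-major flattened
#'   vector; otherwise an `(N - s) x (s + 1)` matrix, one window per row.
#' @return Residuals, flattened or as a matrix.
#' @export
sliding_residuals <- function(profile, s, order = 2L, flat = TRUE) {
  profile <- as.numeric(profile)
  N <- length(profile)
  s <- as.integer(s)
  if (s + 1L > N)
    stop("scale s = ", s, " too large for series of length ", N)
  if (s + 1L < order + 2L)
    stop("scale s = ", s, " too small for detrending order ", order)
  u <- ((0:s) - s / 2) / max(s / 2, 1)
  V <- outer(u, 0:order, "^")
  H <- V %*% solve(crossprod(V), t(V))
  Wm <- matrix(profile[outer(seq_len(N - s), 0:s, "+")], nrow = N - s)
  R <- Wm - Wm %*% H
  if (flat) as.vector(t(R)) else R
}

#' Detrended covariance matrix at one scale
#'
#' Pairwise covariance of aligned sliding-window residual series:
#' `F2[i, j] = sum(Y_i * Y_j) / length(Y)`.  Diagonal entries are the
#' squared DFA fluctuation functions.
#'
#' @param residuals matrix with one flattened residual series per
#'   column (all from the same scale), as returned by
#'   [sliding_residuals()].
#' @return Symmetric m x m matrix `F2(s)`.
#' @export
fluctuation_matrix <- function(residuals) {
  residuals <- as.matrix(residuals)
  if (nrow(residuals) < 1L) stop("empty residual set")
  crossprod(residuals) / nrow(residuals)
}

#' Detrended cross-correlation coefficients (DCCA)
#'
#' Normalizes a detrended covariance matrix to correlation form:
#' `R[i, j] = F2[i, j] / sqrt(F2[i, i] * F2[j, j])`.  The diagonal is
#' identically 1 and off-diagonal entries lie in `[-1, 1]` up to
#' floating-point rounding.
#'
#' @param F2 symmetric detrended covariance matrix.
#' @return Matrix `R(s)` of cross-correlation coefficients.
#' @export
dcca_coefficients <- function(F2) {
  F2 <- as.matrix(F2)
  d <- diag(F2)
  # a constant series leaves only rounding noise in its residuals:
  # treat eps^2-level diagonal entries (relative to the largest) as zero
  tol <- .Machine$double.eps^1.5 * max(0, d, na.rm = TRUE)
  if (any(!is.finite(d) | d <= tol)) {
    bad <- which(!is.finite(d) | d <= tol)
    lab <- if (!is.null(colnames(F2))) colnames(F2)[bad] else bad
    stop("degenerate (constant or invalid) series: zero fluctuation for ",
         paste(lab, collapse = ", "))
  }
  stats::cov2cor(F2)
}

#' Detrended partial cross-correlation coefficients (DPCCA)
#'
#' Inverts the DCCA coefficient matrix and renormalizes,
#' `P[i, j] = -C[i, j] / sqrt(C[i, i] * C[j, j])` with `C = R^{-1}`,
#' yielding the correlation between two series with the linear influence
#' of all remaining series removed.  A near-singular `R` is
#' regularized by a small ridge (`lambda = 1e-8 * trace(R)/m`) before
#' inversion; if it is still singular the scale is flagged unusable.
#'
#' @param R DCCA coefficient matrix at one scale.
#' @param ridge ridge factor relative to the mean diagonal (default
#'   1e-8); set 0 to disable.
#' @return Matrix `P(s)` with unit diagonal, or `NULL` if `R` is
#'   singular even after regularization.
#' @export
dpcca_coefficients <- function(R, ridge = 1e-8) {
  R <- as.matrix(R)
  C <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(C) && ridge > 0) {
    lam <- ridge * sum(diag(R)) / ncol(R)
    C <- tryCatch(solve(R + diag(lam, ncol(R))), error = function(e) NULL)
  }
  if (is.null(C)) return(NULL)
  d <- diag(C)
  # a proper correlation matrix has an inverse with diagonal >= 1; a
  # non-positive diagonal signals an indefinite R (e.g. an inserted
  # shifted covariance inconsistent with the remaining entries)
  if (any(!is.finite(d) | d <= 0)) return(NULL)
  P <- -C / sqrt(outer(d, d))
  diag(P) <- 1
  dimnames(P) <- dimnames(R)
  P
}

#' Multi-scale DFA/DCCA/DPCCA of a set of series
#'
#' Runs the full detrended covariance pipeline on `m` simultaneous
#' series over a grid of scales: profiles, sliding second-order (by
#' default) detrending, the covariance matrices `F2(s)`, cross-correlation
#' coefficients `R(s)` and partial coefficients `P(s)`.
#'
#' @param x numeric matrix (frames x series) or [trajectory_set()]; for
#'   a trajectory set, the X and Y coordinate series of every part are
#'   analyzed jointly (columns named `"<part>.x"`, `"<part>.y"`).
#' @param scales integer vector of scales in frames; default
#'   [scale_grid()].
#' @param order detrending order, 1-3 (default 2).
#' @param fps frames per second used for the seconds axis (taken from
#'   the trajectory set when available).
#' @return Object of class `dpcca`: list with `labels`, `scales`
#'   (frames), `scale_seconds`, arrays `F2`, `R`, `P` (m x m x
#'   n_scales), logical `singular` per scale, `order`, `fps`, `n`.
#' @export
dpcca <- function(x, scales = NULL, order = 2L, fps = NULL) {
  if (inherits(x, "trajectory_set")) {
    if (is.null(fps)) fps <- x$fps
    x <- traj_series_matrix(x)
  }
  x <- as.matrix(x)
  if (is.null(fps)) fps <- 1
  if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
  if (is.null(scales)) scales <- scale_grid(nrow(x), order = order)
  scales <- sort(unique(as.integer(scales)))
  F2l <- dpcca_core(x, scales, order = order)
  keep <- !vapply(F2l, is.null, TRUE)
  scales <- scales[keep]; F2l <- F2l[keep]
  m <- ncol(x); S <- length(scales)
  F2 <- array(NA_real_, c(m, m, S),
              dimnames = list(colnames(x), colnames(x), NULL))
  Rc <- F2; Pc <- F2
  singular <- logical(S)
  for (k in seq_len(S)) {
    F2[, , k] <- F2l[[k]]
    Rk <- dcca_coefficients(F2l[[k]])
    Rc[, , k] <- Rk
    Pk <- dpcca_coefficients(Rk)
    if (is.null(Pk)) singular[k] <- TRUE else Pc[, , k] <- Pk
  }
  structure(
    list(labels = colnames(x), scales = scales,
         scale_seconds = scales / fps, F2 = F2, R = Rc, P = Pc,
         singular = singular, order = order, fps = fps, n = nrow(x)),
    class = "dpcca")
}

#' @export
print.dpcca <- function(x, ...) {
  cat(sprintf(
    "<dpcca> %d series, N = %d, order %d, %d scales (%g-%g frames)\n",
    length(x$labels), x$n, x$order, length(x$scales),
    min(x$scales), max(x$scales)))
  invisible(x)
}

#' DFA fluctuation function of a single series
#'
#' Convenience wrapper: `F(s) = sqrt(F2[1, 1](s))` over a scale grid.
#'
#' @inheritParams dpcca
#' @param x numeric vector.
#' @return Data frame with columns `scale` (frames), `seconds`, `F`.
#' @export
dfa <- function(x, scales = NULL, order = 2L, fps = 1) {
  a <- dpcca(matrix(as.numeric(x), dimnames = list(NULL, "x")),
             scales = scales, order = order, fps = fps)
  data.frame(scale = a$scales, seconds = a$scale_seconds,
             F = sqrt(a$F2[1, 1, ]))
}

#' Fit a DFA scaling exponent
#'
#' Least-squares slope of `log F(s)` versus `log s`, optionally
#' restricted to a scale band.
#'
#' @param scales scales in frames.
#' @param f fluctuation function values `F(s)` (positive).
#' @param band optional `c(lo, hi)` range of scales to include.
#' @return Fitted exponent (slope).
#' @export
dfa_exponent <- function(scales, f, band = NULL) {
  keep <- is.finite(f) & f > 0
  if (!is.null(band)) keep <- keep & scales >= band[1] & scales <= band[2]
  if (sum(keep) < 2L) return(NA_real_)
  stats::coef(stats::lm(log(f[keep]) ~ log(scales[keep])))[[2]]
}

#' Delay-resolved detrended coupling of two residual series
#'
#' Extends the detrended covariance by scanning relative shifts `k`
#' with `|k| <= max_shift` between the residual series of two parts:
#' the covariance is recomputed between the windows of the first series
#' and the windows of the second series shifted by `k` frames (a
#' relatively shifted copy of the data), using only overlapping windows
#' and renormalized by the overlap count, so values are comparable
#' across shifts and the `k = 0` value reproduces the undelayed
#' detrended covariance exactly.  The coupling strength is the maximum
#' over shifts of the DCCA-normalized cross-covariance, and the
#' maximizing shift is the delay: `T > 0` means the first series
#' leads (its windows match the second series' later windows).  Ties
#' are broken toward the smallest `|k|`, then toward negative `k`.
#'
#' @param res1,res2 residuals from [sliding_residuals()] at the same
#'   scale: either window matrices (`flat = FALSE`) or flattened
#'   vectors.
#' @param s the scale in frames (sets the default shift range).
#' @param max_shift maximum shift magnitude (default `floor(s / 2)`).
#' @return List with `strength`, `delay`, and the full `shifts` /
#'   `values` profile (normalized cross-covariance per shift).
#' @export
delayed_coupling <- function(res1, res2, s, max_shift = floor(s / 2)) {
  if (s < 2) stop("scale too small for delay analysis (s >= 2 required)")
  res1 <- as_window_matrix(res1, s)
  res2 <- as_window_matrix(res2, s)
  if (!identical(dim(res1), dim(res2)))
    stop("residual series must be aligned")
  max_shift <- as.integer(max_shift)
  cc <- shifted_window_cross(res1, res2, max_shift)
  norm <- sqrt(mean(res1^2) * mean(res2^2))
  vals <- cc$value / norm
  ord <- order(-vals, abs(cc$shift), cc$shift)
  best <- ord[1L]
  list(strength = vals[best], delay = cc$shift[best],
       shifts = cc$shift, values = vals)
}

as_window_matrix <- function(res, s) {
  if (is.matrix(res)) {
    if (ncol(res) != s + 1L)
      stop("residual matrix does not match scale s = ", s)
    res
  } else {
    if (length(res) %% (s + 1L) != 0L)
      stop("flattened residuals do not match scale s = ", s)
    matrix(res, ncol = s + 1L, byrow = TRUE)
  }
}

# shift-resolved detrended cross-covariance of two residual window
# matrices (windows x (s+1)); shifting the second series' data by k
# frames shifts its window index by k, so
#   value(k) = sum_a <R1[a, ], R2[a + k, ]> / (overlap * (s+1))
shifted_window_cross <- function(R1, R2, K) {
  A <- nrow(R1); w <- ncol(R1)
  if (K >= A) stop("shift range exceeds the number of windows")
  ks <- seq.int(-K, K)
  vals <- vapply(ks, function(k) {
    if (k >= 0) {
      i <- seq_len(A - k)
      sum(R1[i, , drop = FALSE] * R2[i + k, , drop = FALSE]) / ((A - k) * w)
    } else {
      i <- seq_len(A + k)
      sum(R1[i - k, , drop = FALSE] * R2[i, , drop = FALSE]) / ((A + k) * w)
    }
  }, 0.0)
  list(shift = ks, value = vals)
}

#' Total squared displacement fluctuation matrix
#'
#' Combines per-axis analyses: the total squared displacement is the
#' sum of the squared displacements of the projections on the X and Y
#' axes, so the combined detrended covariance matrix is the elementwise
#' sum of the per-axis matrices at each scale.
#'
#' @param fx,fy `dpcca` objects for the X- and Y-axis series of the
#'   same parts on identical scale grids.
#' @return A `dpcca` object with `F2` summed and `R`/`P` recomputed
#'   from the combined matrices.
#' @export
total_squared_displacement <- function(fx, fy) {
  stopifnot(inherits(fx, "dpcca"), inherits(fy, "dpcca"))
  if (!identical(fx$scales, fy$scales))
    stop("axis analyses must share one scale grid")
  if (length(fx$labels) != length(fy$labels))
    stop("axis analyses must cover the same parts")
  out <- fx
  out$labels <- sub("\\.[xy]$", "", fx$labels)
  dimnames(out$F2) <- list(out$labels, out$labels, NULL)
  for (k in seq_along(out$scales)) {
    F2k <- fx$F2[, , k] + fy$F2[, , k]
    out$F2[, , k] <- F2k
    Rk <- dcca_coefficients(F2k)
    out$R[, , k] <- Rk
    Pk <- dpcca_coefficients(Rk)
    if (is.null(Pk)) {
      out$singular[k] <- TRUE
      out$P[, , k] <- NA_real_
    } else {
      out$singular[k] <- FALSE
      out$P[, , k] <- Pk
    }
  }
  dimnames(out$R) <- dimnames(out$F2)
  dimnames(out$P) <- dimnames(out$F2)
  out
}

#' Restrict a `dpcca` analysis to a subset of its series
#'
#' Slices the covariance matrices to the requested series and
#' recomputes `R` and `P` from the submatrices (partial correlations
#' are conditional on the retained set only, so they must be
#' recomputed, not sliced).
#'
#' @param a `dpcca` object.
#' @param labels series labels to keep.
#' @return A `dpcca` object over the subset.
#' @export
dpcca_subset <- function(a, labels) {
  stopifnot(inherits(a, "dpcca"))
  idx <- match(labels, a$labels)
  if (anyNA(idx)) stop("unknown series: ",
                       paste(labels[is.na(idx)], collapse = ", "))
  out <- a
  out$labels <- labels
  out$F2 <- a$F2[idx, idx, , drop = FALSE]
  out$R <- out$F2; out$P <- out$F2
  out$singular <- logical(length(a$scales))
  for (k in seq_along(a$scales)) {
    Rk <- dcca_coefficients(out$F2[, , k])
    out$R[, , k] <- Rk
    Pk <- dpcca_coefficients(Rk)
    if (is.null(Pk)) {
      out$singular[k] <- TRUE
      out$P[, , k] <- NA_real_
    } else out$P[, , k] <- Pk
  }
  out
}

#' Per-axis and combined analysis of one animal
#'
#' Runs the multi-scale [dpcca()] once on the joint set of X- and
#' Y-axis projections of every body part (which provides the
#' cross-axis, "unspecific" correlations), derives the per-axis
#' analyses from it, and combines the axes into the
#' total-squared-displacement analysis.
#'
#' @param traj a clean [trajectory_set()].
#' @inheritParams dpcca
#' @return List with `dpcca` objects `x`, `y`, `xy`, `total`.
#' @export
analyze_trajectory <- function(traj, scales = NULL, order = 2L) {
  stopifnot(inherits(traj, "trajectory_set"))
  if (any(traj$status == "missing"))
    stop("trajectory contains missing samples; run fill_gaps() first")
  if (is.null(scales)) scales <- scale_grid(traj$n_frames, order = order)
  fxy <- dpcca(traj, scales = scales, order = order)
  fx <- dpcca_subset(fxy, paste0(traj$parts, ".x"))
  fy <- dpcca_subset(fxy, paste0(traj$parts, ".y"))
  list(x = fx, y = fy, xy = fxy,
       total = total_squared_displacement(fx, fy))
}

#' Tidy export of a `dpcca` object
#'
#' @param a `dpcca` object.
#' @param animal animal identifier column value.
#' @return Long data frame with columns `animal`, `series_i`,
#'   `series_j`, `scale_frames`, `scale_seconds`, `F2`, `R`, `P`.
#' @export
dpcca_table <- function(a, animal = "animal") {
  stopifnot(inherits(a, "dpcca"))
  m <- length(a$labels)
  idx <- which(upper.tri(diag(m), diag = TRUE), arr.ind = TRUE)
  do.call(rbind, lapply(seq_along(a$scales), function(k) {
    data.frame(animal = animal,
               series_i = a$labels[idx[, 1]],
               series_j = a$labels[idx[, 2]],
               scale_frames = a$scales[k],
               scale_seconds = a$scale_seconds[k],
               F2 = a$F2[, , k][idx],
               R = a$R[, , k][idx],
               P = a$P[, , k][idx])
  }))
}
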