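#' Tukey-fence outlier removal
#'
#' Removes values outside `[Q1 - k * IQR, Q3 + k * IQR]`.  Quartiles use
#' linear interpolation between order statistics (quantile type 7); the
#' convention is recorded in the result.  With fewer than 4 values
#' fencing is skipped with a warning (quartiles would be meaningless).
#'
#' @param values numeric vector.
#' @param k fence multiplier (default 1.5).
#' @return List with `kept`, `removed`, `fence` (the interval) and
#'   `quartile_type`.
#' @export
tukey_fence <- function(values, k = 1.5) {
  values <- values[is.finite(values)]
  if (length(values) < 4L) {
    warning("fewer than 4 values: Tukey fencing skipped")
    return(list(kept = values, removed = numeric(0),
                fence = c(-Inf, Inf), quartile_type = 7L))
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fence <- c(q[1] - k * iqr, q[2] + k * iqr)
  inside <- values >= fence[1] & values <= fence[2]
  list(kept = values[inside], removed = values[!inside], fence = fence,
       quartile_type = 7L)
}

#' Mann-Whitney U test
#'
#' Rank-sum test of two independent samples.  The reported `U` is the
#' statistic of the first sample (number of pairs where `a` exceeds
#' `b`, ties counted half).  When both groups have at most 8
#' observations the two-sided p-value is computed by exhaustive
#' enumeration of all group assignments of the pooled values (exact
#' even under ties); otherwise the tie-corrected normal approximation
#' with continuity correction is used.
#'
#' @param a,b numeric vectors (each `n >= 2`).
#' @param exact force (`TRUE`) or suppress (`FALSE`) enumeration;
#'   default chooses by group size.
#' @return List with `U`, `p`, `method`, `n_a`, `n_b`.
#' @export
mann_whitney <- function(a, b, exact = NULL) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    stop("both groups need at least 2 finite values (got ", na, ", ", nb, ")")
  pooled <- c(a, b)
  r <- rank(pooled)
  u_of <- function(idx_a) sum(r[idx_a]) - na * (na + 1) / 2
  U <- u_of(seq_len(na))
  mu <- na * nb / 2
  if (is.null(exact)) exact <- na <= 8L && nb <= 8L
  if (exact) {
    combos <- utils::combn(na + nb, na)
    Us <- apply(combos, 2, u_of)
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    n <- na + nb
    ties <- table(pooled)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal approximation"
  }
  list(U = U, p = p, method = method, n_a = na, n_b = nb)
}

#' Scale-resolved group comparison
#'
#' For every metric and scale (and, when present, time window), applies
#' Tukey fencing within each group and then the Mann-Whitney U test
#' between groups, producing the scale profile of p-values.  P-values
#' are adjusted across scales within each metric (and window) —
#' Bonferroni by default, Benjamini-Hochberg optionally.
#'
#' @param samples data frame with columns `group` (two levels),
#'   `animal`, `metric`, `scale`, `value`, and optionally `window`.
#' @param fence_k Tukey fence multiplier; `NULL` disables fencing.
#' @param adjust `"bonferroni"` (default), `"BH"`, or `"none"`.
#' @return Data frame with one row per (metric, window, scale):
#'   `metric`, `window`, `scale`, `U`, `p`, `p_adj`, `n_test`,
#'   `n_control`, `outliers_removed`.
#' @export
scale_profile <- function(samples, fence_k = 1.5,
                          adjust = c("bonferroni", "BH", "none")) {
  adjust <- match.arg(adjust)
  req <- c("group", "animal", "metric", "scale", "value")
  if (!all(req %in% names(samples)))
    stop("samples must have columns ", paste(req, collapse = ", "))
  groups <- sort(unique(as.character(samples$group)))
  if (length(groups) != 2L)
    stop("exactly two groups required, got: ",
         paste(groups, collapse = ", "))
  if (is.null(samples$window)) samples$window <- NA_integer_
  key <- paste(samples$metric, samples$window, samples$scale, sep = "\r")
  rows <- lapply(split(samples, key), function(d) {
    va <- d$value[d$group == groups[1]]
    vb <- d$value[d$group == groups[2]]
    removed <- 0L
    if (!is.null(fence_k)) {
      if (length(va) >= 4L) {
        fa <- tukey_fence(va, fence_k); removed <- length(fa$removed)
        va <- fa$kept
      }
      if (length(vb) >= 4L) {
        fb <- tukey_fence(vb, fence_k); removed <- removed + length(fb$removed)
        vb <- fb$kept
      }
    }
    if (length(va) < 2L || length(vb) < 2L)
      return(data.frame(metric = d$metric[1], window = d$window[1],
                        scale = d$scale[1], U = NA_real_, p = NA_real_,
                        n_test = length(vb), n_control = length(va),
                        outliers_removed = removed))
    mw <- mann_whitney(va, vb)
    data.frame(metric = d$metric[1], window = d$window[1],
               scale = d$scale[1], U = mw$U, p = mw$p,
               n_test = length(vb), n_control = length(va),
               outliers_removed = removed)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$metric, out$window, out$scale), ]
  fam <- paste(out$metric, out$window, sep = "\r")
  out$p_adj <- stats::ave(out$p, fam, FUN = function(p) {
    ok <- is.finite(p)
    p[ok] <- stats::p.adjust(p[ok], method = if (adjust == "none") "none"
                             else adjust)
    p
  })
  out[, c("metric", "window", "scale", "U", "p", "p_adj",
          "n_test", "n_control", "outliers_removed")]
}

#' Pairwise correlation metric for gliding-window maps
#'
#' Builds a metric function, suitable for [time_scale_map()], returning
#' the DCCA coefficient `R` (or DPCCA coefficient `P`) between one body
#' part and a reference part — by default the body midpoint — for a
#' chosen pair of axes.  Same-axis pairs measure specific correlations;
#' cross-axis pairs (e.g. part X vs. midpoint Y) give the unspecific
#' baseline.
#'
#' @param part body-part label.
#' @param ref reference part (default `"midpoint"`).
#' @param axis,ref_axis coordinate axes `"x"`/`"y"` for part and
#'   reference.
#' @param stat `"R"` (default) or `"P"`.
#' @param order detrending order.
#' @return Function `(traj, scales) -> numeric vector` of metric values
#'   per scale.
#' @export
pair_correlation_metric <- function(part, ref = "midpoint", axis = "x",
                                    ref_axis = axis, stat = c("R", "P"),
                                    order = 2L) {
  stat <- match.arg(stat)
  function(traj, scales) {
    a <- dpcca(traj, scales = scales, order = order)
    i <- match(paste0(part, ".", axis), a$labels)
    j <- match(paste0(ref, ".", ref_axis), a$labels)
    if (is.na(i) || is.na(j))
      stop("part '", part, "' or reference '", ref, "' not found")
    a[[stat]][i, j, ]
  }
}

#' Gliding-window time-scale p-value map
#'
#' Recomputes a per-animal metric in gliding windows of
#' `window_seconds` duration (50% overlap by default) and tests it
#' between groups per (window, scale) cell, localizing group
#' discrepancies jointly in time and scale.  Scales larger than a third
#' of the window are dropped with a warning.
#'
#' @param trajs list of clean [trajectory_set()] objects.
#' @param groups group label per trajectory (two levels).
#' @param metric_fun function `(traj, scales) -> numeric` per scale,
#'   e.g. from [pair_correlation_metric()].
#' @param scales scales in frames.
#' @param window_seconds gliding-window duration (default 30).
#' @param overlap fractional window overlap in `[0, 1)` (default 0.5).
#' @inheritParams scale_profile
#' @return Data frame per (window, scale): `window`,
#'   `window_start_s`, `scale`, `scale_s`, `U`, `p`, `p_adj`, counts.
#' @export
time_scale_map <- function(trajs, groups, metric_fun, scales,
                           window_seconds = 30, overlap = 0.5,
                           fence_k = 1.5,
                           adjust = c("bonferroni", "BH", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(length(trajs) == length(groups))
  fps <- trajs[[1]]$fps
  n <- min(vapply(trajs, function(t) t$n_frames, 0L))
  wlen <- round(window_seconds * fps)
  if (n < 2 * wlen * (1 - overlap) + wlen)
    stop("recording too short for gliding-window analysis (need >= 2 windows)")
  scales <- sort(unique(as.integer(scales)))
  ok <- scales <= wlen / 3
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " scale(s) larger than window/3")
    scales <- scales[ok]
  }
  step <- max(1L, round(wlen * (1 - overlap)))
  starts <- seq.int(1L, n - wlen + 1L, by = step)
  samples <- do.call(rbind, lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    do.call(rbind, lapply(seq_along(starts), function(wi) {
      sub <- window_trajectory(tr, starts[wi], wlen)
      data.frame(group = groups[i], animal = tr$animal_id,
                 metric = "metric", window = wi, scale = scales,
                 value = metric_fun(sub, scales))
    }))
  }))
  prof <- scale_profile(samples, fence_k = fence_k, adjust = adjust)
  prof$window_start_s <- (starts[prof$window] - 1) / fps
  prof$scale_s <- prof$scale / fps
  prof[, c("window", "window_start_s", "scale", "scale_s", "U", "p",
           "p_adj", "n_test", "n_control", "outliers_removed")]
}

# extract a frame window [start, start + len - 1] as a trajectory_set
window_trajectory <- function(traj, start, len) {
  idx <- seq.int(start, start + len - 1L)
  trajectory_set(traj$x[idx, , drop = FALSE], traj$y[idx, , drop = FALSE],
                 parts = traj$parts, fps = traj$fps,
                 animal_id = traj$animal_id,
                 status = traj$status[idx, , drop = FALSE])
}

#' Normality diagnostics
#'
#' Kolmogorov-Smirnov (against a normal with the sample's moments) and
#' Shapiro-Wilk p-values, used descriptively to justify nonparametric
#' group testing.  A constant sample is reported as non-testable.
#'
#' @param values numeric vector, `n >= 3`.
#' @return List with `ks_p`, `shapiro_p`, `n`, `testable`.
#' @export
normality_report <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) stop("need at least 3 finite values")
  if (stats::sd(values) == 0)
    return(list(ks_p = NA_real_, shapiro_p = NA_real_,
                n = length(values), testable = FALSE))
  ks <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
  sw <- stats::shapiro.test(values[seq_len(min(length(values), 5000L))])
  list(ks_p = ks$p.value, shapiro_p = sw$p.value, n = length(values),
       testable = TRUE)
}
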