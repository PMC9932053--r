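#' Localize the scaling crossover of a fluctuation function
#'
#' Open-field fluctuation functions show two asymptotic regimes —
#' `F(s) ~ s^2` at small scales (smooth, persistent displacement) and
#' `F(s) ~ s^(1/2)` at large scales (confinement-dominated, nearly
#' random displacement).  Dividing by `s^rho` with a rotation exponent
#' strictly between the two slopes (5/4 for the pair 2, 1/2) turns the
#' crossover into a maximum of the rotated curve; its position is the
#' crossover scale.  The grid argmax is refined by parabolic
#' interpolation of `log(F/s^rho)` against `log s` through the three
#' points around the maximum, and a boundary flag is raised when the
#' maximum sits at a grid edge (no interior crossover detectable).
#'
#' @param scales scales in frames (>= 5 values).
#' @param f fluctuation function values `F(s)`, strictly positive.
#' @param rho rotation exponent (default 5/4).
#' @param fps frames per second for the seconds conversion (default 1).
#' @return Object of class `crossover_estimate`: list with
#'   `s_frames`, `s_seconds`, `boundary`, `rho`, `rotated` (the rotated
#'   curve), `scales`.
#' @export
locate_crossover <- function(scales, f, rho = 1.25, fps = 1) {
  scales <- as.numeric(scales); f <- as.numeric(f)
  if (length(scales) < 5L) stop("need at least 5 scales")
  if (any(!is.finite(f) | f <= 0)) stop("fluctuation values must be positive")
  rot <- log(f) - rho * log(scales)
  i <- which.max(rot)
  boundary <- i == 1L || i == length(scales)
  if (boundary) {
    sx <- scales[i]
  } else {
    lx <- log(scales[(i - 1):(i + 1)])
    ly <- rot[(i - 1):(i + 1)]
    # exact vertex of the interpolating parabola (Newton form)
    f12 <- (ly[2] - ly[1]) / (lx[2] - lx[1])
    f123 <- ((ly[3] - ly[2]) / (lx[3] - lx[2]) - f12) / (lx[3] - lx[1])
    sx <- if (is.finite(f123) && f123 < 0) {
      exp(min(max((lx[1] + lx[2]) / 2 - f12 / (2 * f123), lx[1]), lx[3]))
    } else scales[i]
  }
  structure(
    list(s_frames = sx, s_seconds = sx / fps, boundary = boundary,
         rho = rho, rotated = exp(rot), scales = scales),
    class = "crossover_estimate")
}

#' @export
print.crossover_estimate <- function(x, ...) {
  cat(sprintf("<crossover> s_x = %.1f frames (%.2f s)%s, rho = %g\n",
              x$s_frames, x$s_seconds,
              if (x$boundary) " [boundary]" else "", x$rho))
  invisible(x)
}

#' Fit the asymptotic scaling exponents on both sides of a crossover
#'
#' Least-squares slopes of `log F` vs `log s` on the bands `s < s_x / 2`
#' and `s > 2 s_x`.  The factor-2 guard bands keep the fits clear of the
#' crossover region, which DFA is known to smear toward larger scales.
#' A side with fewer than 3 usable scales yields `NA`.
#'
#' @inheritParams locate_crossover
#' @param s_x crossover scale in frames (e.g. from [locate_crossover()]).
#' @param guard guard-band factor (default 2).
#' @return Named vector `c(H_small, H_large)`.
#' @export
fit_exponents <- function(scales, f, s_x, guard = 2) {
  scales <- as.numeric(scales); f <- as.numeric(f)
  fit_side <- function(keep) {
    if (sum(keep & is.finite(f) & f > 0) < 3L) return(NA_real_)
    dfa_exponent(scales[keep], f[keep])
  }
  c(H_small = fit_side(scales < s_x / guard),
    H_large = fit_side(scales > s_x * guard))
}

#' Crossover table for one animal
#'
#' Locates the crossover and fits both exponents for the DFA
#' fluctuation function of every part on both axes.
#'
#' @param analysis result of [analyze_trajectory()].
#' @param animal animal identifier.
#' @param rho rotation exponent (default 5/4).
#' @return Data frame: `animal`, `part`, `axis`, `s_x_frames`,
#'   `s_x_seconds`, `H_small`, `H_large`, `boundary`.
#' @export
crossover_table <- function(analysis, animal = "animal", rho = 1.25) {
  rows <- list()
  for (axis in c("x", "y")) {
    a <- analysis[[axis]]
    for (j in seq_along(a$labels)) {
      f <- sqrt(a$F2[j, j, ])
      cx <- locate_crossover(a$scales, f, rho = rho, fps = a$fps)
      ex <- fit_exponents(a$scales, f, cx$s_frames)
      rows[[length(rows) + 1L]] <- data.frame(
        animal = animal, part = sub("\\.[xy]$", "", a$labels[j]),
        axis = axis,
        s_x_frames = cx$s_frames, s_x_seconds = cx$s_seconds,
        H_small = ex[["H_small"]], H_large = ex[["H_large"]],
        boundary = cx$boundary)
    }
  }
  do.call(rbind, rows)
}
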