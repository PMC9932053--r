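# Independent oracles: deliberately naive implementations, kept free of
# the package's code paths.

# Eq.-style detrended covariance matrix by literal loops: profile each
# series, fit a degree-`order` polynomial with lm() in every sliding
# window of s+1 points, collect residuals, cross-multiply.
oracle_F2 <- function(X, s, order = 2) {
  N <- nrow(X); m <- ncol(X)
  Y <- apply(X, 2, cumsum)
  L <- (N - s) * (s + 1)
  res <- matrix(0, L, m)
  for (j in seq_len(m)) {
    for (a in seq_len(N - s)) {
      w <- Y[a:(a + s), j]
      tloc <- seq_len(s + 1)
      fit <- stats::lm(w ~ poly(tloc, order, raw = TRUE))
      res[((a - 1) * (s + 1) + 1):(a * (s + 1)), j] <- stats::residuals(fit)
    }
  }
  crossprod(res) / L
}

oracle_R <- function(F2) {
  d <- sqrt(diag(F2))
  F2 / outer(d, d)
}

oracle_P <- function(R) {
  C <- solve(R)
  P <- -C / sqrt(outer(diag(C), diag(C)))
  diag(P) <- 1
  P
}

# textbook three-variable partial correlation from pairwise r's
oracle_partial3 <- function(r12, r13, r23) {
  (r12 - r13 * r23) / sqrt((1 - r13^2) * (1 - r23^2))
}

# per-sample forward fill with nearest-neighbour prefix
oracle_forward_fill <- function(v) {
  out <- v
  first <- which(is.finite(v))[1]
  for (i in seq_along(v)) {
    if (is.finite(v[i])) next
    prev <- which(is.finite(v[seq_len(i)]))
    out[i] <- if (length(prev) > 0) v[max(prev)] else v[first]
  }
  out
}

# brute-force running median with shrinking centered windows
oracle_runmed <- function(v, k) {
  h <- (k - 1) / 2
  n <- length(v)
  vapply(seq_len(n), function(i) {
    hh <- min(h, i - 1, n - i)
    stats::median(v[(i - hh):(i + hh)])
  }, 0.0)
}

# exact two-sided Mann-Whitney p by enumeration of group assignments,
# with U computed by direct pair counting (not ranks)
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a); nb <- length(b)
  u_direct <- function(av, bv)
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  U <- u_direct(a, b)
  mu <- na * nb / 2
  combos <- utils::combn(na + nb, na)
  Us <- apply(combos, 2, function(ia)
    u_direct(pooled[ia], pooled[-ia]))
  list(U = U, p = mean(abs(Us - mu) >= abs(U - mu) - 1e-12))
}
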