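test_that("dfa_profile is the cumulative sum and differencing inverts it", {
  expect_equal(dfa_profile(c(1, 1, 1)), c(1, 2, 3))
  expect_equal(dfa_profile(c(0, 0, 0)), c(0, 0, 0))
  set.seed(5)
  x <- rnorm(300)
  p <- dfa_profile(x)
  expect_equal(diff(c(0, p)), x)
  expect_error(dfa_profile(numeric(0)), "empty")
})

test_that("sliding residuals vanish for polynomial profiles", {
  # profile exactly quadratic -> order-2 detrending nulls it
  n <- 60
  prof <- 0.3 * (1:n)^2 - 2 * (1:n) + 5
  expect_lt(max(abs(sliding_residuals(prof, 10, order = 2))), 1e-8)
  # constant series -> linear profile -> zero residuals at order >= 1
  prof_lin <- dfa_profile(rep(2.5, n))
  expect_lt(max(abs(sliding_residuals(prof_lin, 10, order = 1))), 1e-9)
  expect_error(sliding_residuals(prof, 2, order = 2), "too small")
  expect_error(sliding_residuals(prof, n + 3, order = 2), "too large")
})

test_that("a single window reproduces classic polynomial regression", {
  set.seed(7)
  n <- 21
  prof <- dfa_profile(rnorm(n))
  r <- sliding_residuals(prof, n - 1, order = 2, flat = FALSE)
  expect_equal(nrow(r), 1L)
  tloc <- seq_len(n)
  fit <- lm(prof ~ poly(tloc, 2, raw = TRUE))
  expect_equal(as.numeric(r[1, ]), unname(residuals(fit)),
               tolerance = 1e-10)
})

test_that("fluctuation matrix diagonal equals an independent DFA", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(80:160, 1)
    x <- rnorm(n)
    s <- sample(8:16, 1)
    F2 <- fluctuation_matrix(cbind(sliding_residuals(dfa_profile(x), s)))
    expect_equal(F2[1, 1], oracle_F2(cbind(x), s)[1, 1], tolerance = 1e-10)
  }
})

test_that("duplicated and negated series behave as the algebra demands", {
  set.seed(9)
  x <- rnorm(150)
  X <- cbind(a = x, b = x, c = -x)
  F2 <- gaitscale:::dpcca_core(X, 12)[[1]]
  expect_equal(F2[1, 2], F2[1, 1], tolerance = 1e-12)
  expect_equal(F2[1, 3], -F2[1, 1], tolerance = 1e-12)
})

test_that("fast core agrees with brute-force loops (Eqs. of the pipeline)", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(60:200, 1)
    m <- sample(2:4, 1)
    s <- sample(8:20, 1)
    X <- matrix(rnorm(n * m), n, m)
    b <- oracle_F2(X, s)
    f <- gaitscale:::dpcca_core(X, s)[[1]]
    expect_equal(unname(f), b, tolerance = 1e-10)
    expect_equal(unname(dcca_coefficients(f)), oracle_R(b),
                 tolerance = 1e-10)
    expect_equal(unname(dpcca_coefficients(dcca_coefficients(f))),
                 oracle_P(oracle_R(b)), tolerance = 1e-9)
  }
})

test_that("dcca_coefficients has unit diagonal and detects degeneracy", {
  set.seed(13)
  X <- matrix(rnorm(500 * 3), 500, 3)
  a <- dpcca(X, scales = c(8, 16, 32))
  for (k in 1:3) {
    expect_equal(diag(a$R[, , k]), rep(1, 3), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(abs(a$R[, , k]) <= 1 + 1e-9))
    expect_equal(a$R[, , k], t(a$R[, , k]))
    expect_equal(a$P[, , k], t(a$P[, , k]))
  }
  # affine transform of a series leaves R at exactly 1
  x <- rnorm(300)
  F2 <- gaitscale:::dpcca_core(cbind(x, 3 * x + 7), 10)[[1]]
  expect_equal(dcca_coefficients(F2)[1, 2], 1, tolerance = 1e-10)
  # constant series -> named degeneracy error
  cst <- cbind(ok = rnorm(100), flat = rep(1, 100))
  expect_error(dcca_coefficients(gaitscale:::dpcca_core(cst, 8)[[1]]),
               "flat")
})

test_that("partial coefficients match closed forms", {
  set.seed(17)
  # m = 2: P equals R
  X2 <- matrix(rnorm(400 * 2), 400, 2)
  F2 <- gaitscale:::dpcca_core(X2, 16)[[1]]
  R <- dcca_coefficients(F2)
  P <- dpcca_coefficients(R)
  expect_equal(P[1, 2], R[1, 2], tolerance = 1e-12)
  # m = 3: textbook partial-correlation formula
  X3 <- matrix(rnorm(400 * 3), 400, 3)
  R3 <- dcca_coefficients(gaitscale:::dpcca_core(X3, 16)[[1]])
  P3 <- dpcca_coefficients(R3)
  expect_equal(P3[1, 2],
               oracle_partial3(R3[1, 2], R3[1, 3], R3[2, 3]),
               tolerance = 1e-10)
})

test_that("conditioning removes chain-mediated correlation", {
  # x -> y -> z: z depends on y only; P_xz ~ 0 while R_xz is sizable
  p_xz <- c(); r_xz <- c()
  for (seed in 1:10) {
    set.seed(seed)
    n <- 4096
    x <- gen_power_law_series(n, 1.2, seed = seed)
    y <- 0.8 * x + 0.6 * gen_power_law_series(n, 1.2, seed = seed + 100)
    z <- 0.8 * y + 0.6 * gen_power_law_series(n, 1.2, seed = seed + 200)
    a <- dpcca(cbind(x = x, y = y, z = z), scales = c(32, 64))
    r_xz <- c(r_xz, a$R[1, 3, ])
    p_xz <- c(p_xz, a$P[1, 3, ])
  }
  expect_gt(median(r_xz), 0.3)
  expect_lt(median(abs(p_xz)), 0.1)
})

test_that("independent series decorrelate at scales up to N/8", {
  r12 <- sapply(1:10, function(seed) {
    x <- gen_power_law_series(2^14, 1.0, seed = seed)
    y <- gen_power_law_series(2^14, 1.0, seed = seed + 999)
    a <- dpcca(cbind(x, y), scales = c(64, 512, 2048))
    abs(a$R[1, 2, ])
  })
  expect_true(all(apply(r12, 1, median) < 0.1))
})

test_that("delayed coupling recovers exact and delayed copies", {
  set.seed(23)
  x <- gen_power_law_series(1200, 1.0, seed = 23)
  r <- sliding_residuals(dfa_profile(x), 20, flat = FALSE)
  auto <- delayed_coupling(r, r, 20)
  expect_identical(auto$delay, 0L)
  expect_equal(auto$strength, 1)
  # shifted copy: exact recovery at s >= 2 * delay
  xd <- c(rep(0, 5), x[1:1195])
  for (s in c(10, 16, 40)) {
    r1 <- sliding_residuals(dfa_profile(x), s, flat = FALSE)
    r2 <- sliding_residuals(dfa_profile(xd), s, flat = FALSE)
    fwd <- delayed_coupling(r1, r2, s)
    expect_identical(fwd$delay, 5L)
    swapped <- delayed_coupling(r2, r1, s)
    expect_identical(swapped$delay, -5L)
  }
  expect_error(delayed_coupling(r, r, 1), "too small")
})

test_that("delayed coupling at k = 0 reproduces the undelayed covariance", {
  set.seed(29)
  x <- rnorm(300); y <- 0.5 * x + rnorm(300)
  s <- 12
  r1 <- sliding_residuals(dfa_profile(x), s)
  r2 <- sliding_residuals(dfa_profile(y), s)
  F2 <- fluctuation_matrix(cbind(r1, r2))
  dc <- delayed_coupling(r1, r2, s)
  k0 <- dc$values[dc$shifts == 0] * sqrt(mean(r1^2) * mean(r2^2))
  expect_equal(k0, F2[1, 2], tolerance = 1e-14)
})

test_that("total squared displacement adds axes and respects isotropy", {
  set.seed(37)
  n <- 1024
  parts <- c("a", "midpoint")
  scales <- c(16, 64)
  xs <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, parts))
  zeros <- matrix(0, n, 2, dimnames = list(NULL, parts))
  fx <- dpcca(xs, scales = scales)
  f0 <- fx; f0$F2[] <- 0  # fabricate an all-zero Y-axis analysis
  tot <- total_squared_displacement(fx, f0)
  expect_equal(tot$F2, fx$F2, ignore_attr = TRUE)

  # i.i.d. same-law axes: total ~ 2x each axis
  ratios <- sapply(1:10, function(seed) {
    set.seed(seed)
    X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, parts))
    Y <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, parts))
    fX <- dpcca(X, scales = scales); fY <- dpcca(Y, scales = scales)
    t2 <- total_squared_displacement(fX, fY)
    mean(diag(t2$F2[, , 1]) / diag(fX$F2[, , 1]))
  })
  expect_gte(median(ratios), 1.8)
  expect_lte(median(ratios), 2.2)

  # rotating coordinates by 45 degrees leaves the total within 5%
  set.seed(41)
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, parts))
  Y <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, parts))
  th <- pi / 4
  Xr <- cos(th) * X - sin(th) * Y
  Yr <- sin(th) * X + cos(th) * Y
  t1 <- total_squared_displacement(dpcca(X, scales = scales),
                                   dpcca(Y, scales = scales))
  t2 <- total_squared_displacement(dpcca(Xr, scales = scales),
                                   dpcca(Yr, scales = scales))
  expect_equal(diag(t1$F2[, , 1]), diag(t2$F2[, , 1]), tolerance = 0.05)
})

test_that("dpcca_subset matches a direct analysis of the subset", {
  traj <- make_traj(n = 400, parts = c("a", "b", "midpoint"))
  an <- analyze_trajectory(traj, scales = c(10, 20, 40))
  direct <- dpcca(traj$x, scales = c(10, 20, 40), fps = traj$fps)
  expect_equal(unname(an$x$F2), unname(direct$F2), tolerance = 1e-12)
  expect_equal(unname(an$x$P), unname(direct$P), tolerance = 1e-10)
  expect_error(dpcca_subset(an$xy, "nope"), "unknown series")
})

test_that("scale_grid respects its bounds", {
  g <- scale_grid(4096)
  expect_true(all(diff(g) > 0))
  expect_gte(min(g), 8)
  expect_lte(max(g), 1024)
  expect_error(scale_grid(10), "too short")
})
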