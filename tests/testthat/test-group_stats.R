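test_that("tukey_fence removes the hand-computed outlier", {
  res <- tukey_fence(c(1, 2, 3, 4, 100))
  expect_equal(res$removed, 100)
  expect_equal(res$fence, c(-1, 7))  # Q1 = 2, Q3 = 4 under type 7
  expect_equal(res$kept, c(1, 2, 3, 4))
})

test_that("tukey_fence keeps ties, is idempotent and calibrated", {
  same <- tukey_fence(rep(3, 10))
  expect_length(same$removed, 0)
  expect_warning(tukey_fence(c(1, 2, 3)), "skipped")
  # idempotence on its own output
  set.seed(4)
  v <- c(rnorm(50), 8, -9)
  f1 <- tukey_fence(v)
  f2 <- tukey_fence(f1$kept)
  expect_identical(f2$kept, f1$kept[f1$kept >= f2$fence[1] &
                                    f1$kept <= f2$fence[2]])
  # uniform data: < 2% removed (median over seeds)
  frac <- sapply(1:10, function(seed) {
    set.seed(seed)
    length(tukey_fence(runif(1000))$removed) / 1000
  })
  expect_lt(median(frac), 0.02)
})

test_that("mann_whitney reproduces the exhaustive example", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)  # 2 / choose(6, 3)
  expect_identical(mw$method, "exact enumeration")
  # identical samples: p = 1 within exact granularity
  same <- mann_whitney(c(2, 4, 9), c(2, 4, 9))
  expect_equal(same$p, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "at least 2")
})

test_that("exact p agrees with the independent enumeration oracle", {
  set.seed(19)
  for (rep in 1:8) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- sample(1:6, na, replace = TRUE)  # ties likely
    b <- sample(1:6, nb, replace = TRUE)
    mine <- mann_whitney(a, b)
    orac <- oracle_mw_exact(a, b)
    expect_equal(mine$U, orac$U)
    expect_equal(mine$p, orac$p)
  }
})

test_that("normal approximation is close to exact near the boundary", {
  set.seed(8)
  a <- rnorm(9); b <- rnorm(9) + 1
  approx <- mann_whitney(a, b)
  expect_identical(approx$method, "normal approximation")
  exact <- mann_whitney(a, b, exact = TRUE)
  expect_lt(abs(approx$p - exact$p), 0.02)
})

test_that("scale_profile reduces to one test on a single scale", {
  set.seed(5)
  samples <- data.frame(
    group = rep(c("control", "test"), each = 6),
    animal = paste0("a", 1:12), metric = "m", scale = 10,
    value = c(rnorm(6), rnorm(6) + 3))
  prof <- scale_profile(samples, fence_k = NULL)
  expect_identical(nrow(prof), 1L)
  direct <- mann_whitney(samples$value[1:6], samples$value[7:12])
  expect_equal(prof$p, direct$p)
  expect_equal(prof$p_adj, prof$p)  # single test, no correction
})

test_that("scale_profile adjusts across scales and orders its output", {
  set.seed(6)
  grid <- c(5, 10, 20)
  samples <- do.call(rbind, lapply(grid, function(s) data.frame(
    group = rep(c("control", "test"), each = 8),
    animal = paste0("a", 1:16), metric = "m", scale = s,
    value = c(rnorm(8), rnorm(8) + (s == 10) * 4))))
  prof <- scale_profile(samples)
  expect_identical(prof$scale, grid)
  expect_true(all(prof$p_adj >= prof$p - 1e-15))
  expect_lt(prof$p_adj[prof$scale == 10], 0.05)
  expect_gt(min(prof$p_adj[prof$scale != 10]), 0.05)
  expect_error(scale_profile(samples[samples$group == "test", ]),
               "two groups")
})

test_that("time_scale_map localizes a first-half-only difference", {
  # two-part animals, fps 5: coupling differs between groups only in
  # the first half of the recording
  make_animal <- function(coupled, seed) {
    set.seed(seed)
    n <- 640
    half <- n / 2
    mid <- gen_power_law_series(n, 1.2, seed = seed)
    e <- gen_power_law_series(n, 1.2, seed = seed + 500)
    rho1 <- if (coupled) 0.95 else 0
    part <- c(rho1 * mid[1:half] + sqrt(1 - rho1^2) * e[1:half],
              0.95 * mid[(half + 1):n] + sqrt(1 - 0.95^2) * e[(half + 1):n])
    xm <- cbind(part = part, midpoint = mid)
    trajectory_set(xm, xm[, 2:1], parts = c("part", "midpoint"), fps = 5,
                   animal_id = paste0("an", seed, coupled))
  }
  trajs <- c(lapply(1:6, make_animal, coupled = TRUE),
             lapply(101:106, make_animal, coupled = FALSE))
  groups <- rep(c("control", "test"), each = 6)
  mp <- time_scale_map(trajs, groups,
                       pair_correlation_metric("part", "midpoint",
                                               axis = "x"),
                       scales = c(10, 20, 40), window_seconds = 30,
                       overlap = 0.5, fence_k = NULL, adjust = "none")
  n_frames <- 640; wlen <- 150
  first_half <- mp$window_start_s + 30 <= (n_frames / 5) / 2 + 15
  sig <- mp$p < 0.05
  expect_gt(sum(sig[first_half]), 0)
  expect_gt(mean(sig[first_half]), 2 * max(mean(sig[!first_half]), 0.05))
})

test_that("time_scale_map drops over-long scales and degenerates cleanly", {
  trajs <- lapply(1:8, function(i) make_traj(n = 500, fps = 5,
                                             parts = c("part", "midpoint"),
                                             seed = i))
  groups <- rep(c("control", "test"), 4)
  expect_warning(
    mp <- time_scale_map(trajs, groups,
                         pair_correlation_metric("part", "midpoint"),
                         scales = c(10, 100), window_seconds = 30,
                         overlap = 0, fence_k = NULL),
    "window/3")
  expect_true(all(mp$scale <= 50))
  expect_error(
    time_scale_map(trajs, groups,
                   pair_correlation_metric("part", "midpoint"),
                   scales = 10, window_seconds = 200),
    "too short")
})

test_that("normality_report calibrates on known distributions", {
  gauss_ok <- sapply(1:5, function(seed) {
    set.seed(seed)
    r <- normality_report(rnorm(500))
    r$ks_p > 0.05 && r$shapiro_p > 0.05
  })
  expect_gte(sum(gauss_ok), 4)
  expo_reject <- sapply(1:5, function(seed) {
    set.seed(seed + 50)
    r <- normality_report(rexp(500))
    r$ks_p < 0.05 && r$shapiro_p < 0.05
  })
  expect_gte(sum(expo_reject), 4)
  cst <- normality_report(rep(1, 10))
  expect_false(cst$testable)
  expect_error(normality_report(c(1, 2)), "at least 3")
})
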