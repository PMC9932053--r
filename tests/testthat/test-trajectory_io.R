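test_that("read_dlc_csv parses a fully observed 7-part table", {
  path <- withr::local_tempfile(fileext = ".csv")
  ref <- write_fixture_csv(path, n = 100)
  out <- read_dlc_csv(path, likelihood_threshold = 0.6)
  expect_s3_class(out$traj, "trajectory_set")
  expect_identical(out$traj$parts, default_parts())
  expect_identical(out$traj$n_frames, 100L)
  expect_equal(sum(out$traj$status == "missing"), 0)
  expect_equal(unname(out$traj$x), unname(ref$x), tolerance = 1e-12)
  expect_equal(dim(out$likelihood), c(100L, 7L))
})

test_that("frames below the likelihood threshold are flagged missing", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture_csv(path, n = 50, lik_override = list(
    frames = 10:12, part_index = 3, value = 0.1))
  traj <- read_dlc_csv(path, likelihood_threshold = 0.6)$traj
  expect_identical(unname(traj$status[10:12, 3]), rep("missing", 3))
  expect_true(all(is.na(traj$x[10:12, 3])))
  expect_equal(sum(traj$status == "missing"), 3)
})

test_that("read errors name the malformed header row or empty table", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scorer,m,m,m", "oops,p,p,p", "coords,x,y,likelihood",
               "0,1,2,0.9"), path)
  expect_error(read_dlc_csv(path), "row 2")
  writeLines(c("scorer,m,m,m", "bodyparts,p,p,p", "coords,x,y,likelihood"),
             path)
  expect_error(read_dlc_csv(path), "empty table")
  expect_error(read_dlc_csv(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("write -> read round-trips positions to 1e-9", {
  traj <- make_traj(n = 120)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dlc_csv(traj, path)
  back <- read_dlc_csv(path)$traj
  expect_identical(back$parts, traj$parts)
  expect_equal(back$x, traj$x, tolerance = 1e-9)
  expect_equal(back$y, traj$y, tolerance = 1e-9)
  # second round trip is exact (formatting is idempotent)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_dlc_csv(back, path2)
  expect_identical(read_dlc_csv(path2)$traj$x, back$x)
})

test_that("write_dlc_csv handles degenerate inputs", {
  traj1 <- make_traj(n = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dlc_csv(traj1, path)
  expect_equal(read_dlc_csv(path)$traj$n_frames, 1L)
  empty <- trajectory_set(matrix(0, 2, 0), matrix(0, 2, 0),
                          parts = character(0))
  expect_error(write_dlc_csv(empty, path), "no parts")
})

test_that("fill_gaps forward-fills with nearest-neighbour prefix", {
  x <- matrix(c(1, NA, NA, 4), ncol = 1)
  tr <- trajectory_set(x, x, parts = "p")
  filled <- fill_gaps(tr)
  expect_equal(unname(filled$x[, 1]), c(1, 1, 1, 4))
  expect_identical(unname(filled$status[, 1]),
                   c("observed", "gap-filled", "gap-filled", "observed"))

  x2 <- matrix(c(NA, 2, 3), ncol = 1)
  tr2 <- trajectory_set(x2, x2, parts = "p")
  expect_equal(unname(fill_gaps(tr2)$x[, 1]), c(2, 2, 3))
})

test_that("fill_gaps matches the per-sample oracle and is idempotent", {
  set.seed(11)
  for (rep in 1:5) {
    v <- as.numeric(1:200)
    v[sample(200, 30)] <- NA          # ~15% missing
    if (!is.finite(v[1])) v[1] <- 1   # keep a finite sample somewhere
    tr <- trajectory_set(matrix(v), matrix(rev(v)), parts = "p")
    filled <- fill_gaps(tr)
    expect_equal(unname(filled$x[, 1]), oracle_forward_fill(v))
    expect_equal(unname(filled$y[, 1]), oracle_forward_fill(rev(v)))
    expect_false(any(filled$status == "missing"))
    expect_identical(fill_gaps(filled)$x, filled$x)
  }
  all_na <- trajectory_set(matrix(NA_real_, 5), matrix(NA_real_, 5),
                           parts = "p")
  expect_error(fill_gaps(all_na), "no observed samples")
})

test_that("median_filter removes spikes and matches the brute-force oracle", {
  v <- c(0, 0, 100, 0, 0)
  tr <- trajectory_set(matrix(v), matrix(v), parts = "p")
  expect_equal(unname(median_filter(tr, 5)$x[, 1]), oracle_runmed(v, 5))
  expect_equal(unname(median_filter(tr, 5)$x[3, 1]), 0)

  set.seed(3)
  w <- rnorm(60)
  trw <- trajectory_set(matrix(w), matrix(w), parts = "p")
  expect_equal(unname(median_filter(trw, 5)$x[, 1]), oracle_runmed(w, 5))

  const <- trajectory_set(matrix(rep(2, 10)), matrix(rep(3, 10)),
                          parts = "p")
  expect_equal(unname(median_filter(const, 5)$x[, 1]), rep(2, 10))

  ramp <- trajectory_set(matrix(as.numeric(1:20)),
                         matrix(as.numeric(1:20)), parts = "p")
  expect_equal(unname(median_filter(ramp, 5)$x[3:18, 1]),
               as.numeric(3:18))
})

test_that("median_filter validates its window", {
  tr <- make_traj(n = 10, parts = "p")
  expect_error(median_filter(tr, 4), "odd")
  expect_error(median_filter(tr, 11), "exceeds")
  expect_identical(median_filter(tr, 1)$x, tr$x)
})

test_that("preprocessing chain leaves no missing samples", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture_csv(path, n = 80, lik_override = list(
    frames = c(1:4, 40:45), part_index = 2, value = 0))
  traj <- read_dlc_csv(path)$traj
  clean <- preprocess_trajectory(traj)
  expect_false(any(clean$status == "missing"))
  expect_false(anyNA(clean$x))
  expect_identical(clean$n_frames, traj$n_frames)
})
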