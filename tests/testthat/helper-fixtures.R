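# Programmatic fixtures (no files on disk).

# small fully-observed trajectory with deterministic coordinates
make_traj <- function(n = 100, parts = default_parts(), fps = 30,
                      seed = 1) {
  set.seed(seed)
  m <- length(parts)
  x <- matrix(rnorm(n * m), n, m)
  y <- matrix(rnorm(n * m), n, m)
  trajectory_set(x, y, parts = parts, fps = fps, animal_id = "fixture")
}

# hand-written DLC CSV text (independent of write_dlc_csv)
write_fixture_csv <- function(path, n = 100, parts = default_parts(),
                              likelihood = 0.99, lik_override = NULL,
                              seed = 1) {
  set.seed(seed)
  m <- length(parts)
  lik <- matrix(likelihood, n, m)
  if (!is.null(lik_override))
    lik[lik_override$frames, lik_override$part_index] <- lik_override$value
  xs <- matrix(round(runif(n * m, 0, 700), 3), n, m)
  ys <- matrix(round(runif(n * m, 0, 700), 3), n, m)
  lines <- c(
    paste(c("scorer", rep("model", 3 * m)), collapse = ","),
    paste(c("bodyparts", rep(parts, each = 3)), collapse = ","),
    paste(c("coords", rep(c("x", "y", "likelihood"), m)), collapse = ","))
  for (i in seq_len(n)) {
    row <- as.vector(rbind(xs[i, ], ys[i, ], lik[i, ]))
    lines <- c(lines, paste(c(i - 1, row), collapse = ","))
  }
  writeLines(lines, path)
  list(x = xs, y = ys, lik = lik)
}

# two-part trajectory with a known coupled structure
make_coupled_traj <- function(n = 2048, rho = 0.8, delay = 0,
                              noise_sd = 0.02, seed = 1, fps = 30,
                              crossover_s = 3) {
  cfg <- synth_config(
    n_frames = n, fps = fps, crossover_s = crossover_s,
    parts = c("paw", "midpoint"),
    coupling = data.frame(part = "paw", rho = rho, delay = delay),
    noise_sd = noise_sd, seed = seed)
  gen_animal(cfg)
}
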