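#' Read a DeepLabCut-style trajectory CSV
#'
#' Parses the three-header-row CSV dialect emitted by marker-free pose
#' estimation: row 1 `scorer`, row 2 `bodyparts`, row 3 `coords`, with an
#' `x`, `y`, `likelihood` column triplet per tracked part and one data
#' row per video frame.  Frames whose detection likelihood falls below
#' `likelihood_threshold` are marked missing; [fill_gaps()] replaces them
#' afterwards so that the analysis never sees gaps.
#'
#' Empty cells and `NaN`/`NA` literals in the coordinate columns are both
#' treated as missing regardless of the likelihood value.
#'
#' @param path path to the CSV file.
#' @param likelihood_threshold detections with confidence below this value
#'   are treated as missed (default 0.6).
#' @param fps sampling rate to attach, frames per second (default 30).
#' @param animal_id identifier; defaults to the file name without extension.
#' @return A list with components `traj` (a [trajectory_set()] with missing
#'   samples flagged) and `likelihood` (frames x parts matrix in `[0,1]`).
#' @export
read_dlc_csv <- function(path, likelihood_threshold = 0.6, fps = 30,
                         animal_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (likelihood_threshold < 0 || likelihood_threshold > 1)
    stop("likelihood_threshold must be in [0, 1]")
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) < 4L)
    stop("empty table: ", path, " has no data rows below the three header rows")
  h1 <- tolower(trimws(raw[1, 1])); h2 <- tolower(trimws(raw[2, 1]))
  h3 <- tolower(trimws(raw[3, 1]))
  if (h1 != "scorer")
    stop("malformed header: row 1 must start with 'scorer', got '", raw[1, 1], "'")
  if (!h2 %in% c("bodyparts", "bodypart"))
    stop("malformed header: row 2 must start with 'bodyparts', got '", raw[2, 1], "'")
  if (h3 != "coords")
    stop("malformed header: row 3 must start with 'coords', got '", raw[3, 1], "'")
  bodyparts <- as.character(raw[2, -1])
  coords <- tolower(as.character(raw[3, -1]))
  parts <- unique(bodyparts)
  if (length(parts) == 0L) stop("no body-part columns found in ", path)

  data <- raw[-(1:3), -1, drop = FALSE]
  num <- suppressWarnings(
    vapply(data, function(col) as.numeric(col), numeric(nrow(data))))
  num <- matrix(num, nrow = nrow(data))
  n <- nrow(num)

  pick <- function(part, coord) {
    j <- which(bodyparts == part & coords == coord)
    if (length(j) != 1L)
      stop("malformed header: expected exactly one '", coord,
           "' column for part '", part, "' (row 3)")
    num[, j]
  }
  x <- sapply(parts, pick, coord = "x")
  y <- sapply(parts, pick, coord = "y")
  lik <- sapply(parts, function(p) {
    j <- which(bodyparts == p & coords == "likelihood")
    if (length(j) == 1L) num[, j] else rep(1, n)
  })
  x <- matrix(x, nrow = n, dimnames = list(NULL, parts))
  y <- matrix(y, nrow = n, dimnames = list(NULL, parts))
  lik <- matrix(lik, nrow = n, dimnames = list(NULL, parts))
  lik[!is.finite(lik)] <- 0

  miss <- !is.finite(x) | !is.finite(y) | lik < likelihood_threshold
  x[miss] <- NA_real_; y[miss] <- NA_real_
  if (is.null(animal_id))
    animal_id <- sub("\\.[Cc][Ss][Vv]$", "", basename(path))
  traj <- trajectory_set(x, y, parts = parts, fps = fps,
                         animal_id = animal_id)
  list(traj = traj, likelihood = lik)
}

#' Write a trajectory set in the DeepLabCut CSV dialect
#'
#' Emits the same three-header-row format accepted by [read_dlc_csv()].
#' The likelihood column is written as 1.0 for samples currently observed
#' or preprocessed, 0.0 for missing ones (missing coordinates are written
#' as empty cells).
#'
#' @param traj a [trajectory_set()].
#' @param path output file path.
#' @param scorer value for the first header row (default `"gaitscale"`).
#' @return `path`, invisibly.
#' @export
write_dlc_csv <- function(traj, path, scorer = "gaitscale") {
  stopifnot(inherits(traj, "trajectory_set"))
  if (length(traj$parts) == 0L) stop("trajectory set has no parts")
  m <- length(traj$parts); n <- traj$n_frames
  fmt <- function(v) ifelse(is.finite(v), formatC(v, digits = 12,
                                                 format = "g"), "")
  cells <- matrix("", nrow = n, ncol = 3 * m)
  for (j in seq_len(m)) {
    cells[, 3 * j - 2] <- fmt(traj$x[, j])
    cells[, 3 * j - 1] <- fmt(traj$y[, j])
    cells[, 3 * j] <- ifelse(traj$status[, j] == "missing", "0.0", "1.0")
  }
  header <- rbind(
    c("scorer", rep(scorer, 3 * m)),
    c("bodyparts", rep(traj$parts, each = 3)),
    c("coords", rep(c("x", "y", "likelihood"), m)))
  body <- cbind(as.character(seq_len(n) - 1L), cells)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(apply(rbind(header, body), 1, paste, collapse = ","), con)
  invisible(path)
}

#' Fill detection gaps by nearest-neighbor propagation
#'
#' Every missing sample is replaced by the previous observed value of the
#' same part and coordinate; a missing prefix (no previous value exists)
#' is filled with the first observed value.  After this step the
#' trajectory contains no missing samples.  Idempotent.
#'
#' @param traj a [trajectory_set()] possibly containing missing samples.
#' @return A gap-free [trajectory_set()] with provenance flags updated to
#'   `"gap-filled"` for replaced samples.
#' @export
fill_gaps <- function(traj) {
  stopifnot(inherits(traj, "trajectory_set"))
  x <- traj$x; y <- traj$y; status <- traj$status
  for (j in seq_along(traj$parts)) {
    miss <- status[, j] == "missing"
    if (!any(miss)) next
    if (all(miss))
      stop("part '", traj$parts[j],
           "' has no observed samples and cannot be gap-filled")
    x[, j] <- fill_forward(x[, j])
    y[, j] <- fill_forward(y[, j])
    status[miss, j] <- "gap-filled"
  }
  trajectory_set(x, y, parts = traj$parts, fps = traj$fps,
                 animal_id = traj$animal_id, status = status)
}

# forward fill with nearest-neighbor prefix; NA marks missing
fill_forward <- function(v) {
  obs <- which(is.finite(v))
  if (length(obs) == 0L) stop("no observed samples")
  # index of the last observed sample at or before each position
  idx <- cummax(ifelse(is.finite(v), seq_along(v), 0L))
  idx[idx == 0L] <- obs[1L]           # missing prefix -> first observed
  v[idx]
}

#' Running median filter for trajectory smoothing
#'
#' Replaces each coordinate by the median over a centered window of
#' `window` frames, suppressing single-frame anomalies such as jitter
#' noise and short marker swaps.  Near the edges the window shrinks
#' symmetrically (widths 1, 3, ..., `window`), so the series length is
#' unchanged and no data are invented.  `window = 1` is the identity.
#'
#' @param traj a gap-free [trajectory_set()].
#' @param window odd positive integer, number of frames (default 5).
#' @return The filtered [trajectory_set()]; provenance flags of samples
#'   that changed are set to `"filtered"`.
#' @export
median_filter <- function(traj, window = 5L) {
  stopifnot(inherits(traj, "trajectory_set"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd positive integer, got ", window)
  if (window > traj$n_frames)
    stop("window (", window, ") exceeds trajectory length (",
         traj$n_frames, ")")
  if (any(traj$status == "missing"))
    stop("median_filter requires a gap-free trajectory; run fill_gaps() first")
  if (window == 1L) return(traj)
  x <- traj$x; y <- traj$y; status <- traj$status
  for (j in seq_along(traj$parts)) {
    xf <- running_median(x[, j], window)
    yf <- running_median(y[, j], window)
    changed <- xf != x[, j] | yf != y[, j]
    status[changed, j] <- "filtered"
    x[, j] <- xf; y[, j] <- yf
  }
  trajectory_set(x, y, parts = traj$parts, fps = traj$fps,
                 animal_id = traj$animal_id, status = status)
}

# centered running median; the first/last (k-1)/2 samples use shrunken
# centered windows of widths 1, 3, ..., k (runmed's end rules differ)
running_median <- function(v, k) {
  n <- length(v)
  h <- (k - 1L) %/% 2L
  out <- stats::runmed(v, k = k, endrule = "keep")
  for (i in seq_len(min(h, n))) {
    hh <- min(i - 1L, n - i)
    out[i] <- stats::median(v[(i - hh):(i + hh)])
    jj <- n - i + 1L
    hh <- min(i - 1L, jj - 1L)
    out[jj] <- stats::median(v[(jj - hh):(jj + hh)])
  }
  out
}

#' Standard preprocessing chain
#'
#' Gap filling followed by the running median filter, the order used for
#' raw tracking output.
#'
#' @inheritParams median_filter
#' @return A clean [trajectory_set()].
#' @export
preprocess_trajectory <- function(traj, window = 5L) {
  median_filter(fill_gaps(traj), window = window)
}
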