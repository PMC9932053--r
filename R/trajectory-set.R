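#' Body-part trajectory container
#'
#' A `trajectory_set` holds the time-indexed 2-D positions of `m` tracked
#' body parts of one animal, together with the sampling rate and a
#' per-sample provenance flag.  It is the common currency of the package:
#' the reader ([read_dlc_csv()]), the preprocessing steps ([fill_gaps()],
#' [median_filter()]) and the synthetic generator ([gen_animal()]) all
#' produce one, and the fluctuation analysis consumes one.
#'
#' @param x,y numeric matrices (frames x parts) of coordinates; `NA`
#'   marks a missing (undetected) sample.  Column names, if present,
#'   must agree with `parts`.
#' @param parts character vector of unique body-part labels, one per
#'   column of `x`/`y`.
#' @param fps sampling rate in frames per second (default 30).
#' @param animal_id identifier string.
#' @param status optional character matrix, same shape as `x`, with
#'   entries `"observed"`, `"missing"`, `"gap-filled"` or `"filtered"`.
#'   Defaults to `"observed"` where both coordinates are finite and
#'   `"missing"` elsewhere.
#'
#' @return An object of class `trajectory_set`: a list with elements
#'   `animal_id`, `fps`, `parts`, `x`, `y`, `status`, `n_frames`.
#' @export
trajectory_set <- function(x, y, parts, fps = 30, animal_id = "animal",
                           status = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  storage.mode(x) <- "double"; storage.mode(y) <- "double"
  if (!identical(dim(x), dim(y)))
    stop("x and y must have identical dimensions")
  if (nrow(x) < 1L) stop("empty trajectory: at least one frame required")
  parts <- as.character(parts)
  if (length(parts) != ncol(x))
    stop("number of part labels (", length(parts),
         ") does not match number of columns (", ncol(x), ")")
  if (anyDuplicated(parts)) stop("body-part labels must be unique")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("fps must be a single positive number")
  colnames(x) <- parts; colnames(y) <- parts
  if (is.null(status)) {
    status <- matrix("observed", nrow(x), ncol(x))
    status[!is.finite(x) | !is.finite(y)] <- "missing"
  } else {
    status <- as.matrix(status)
    if (!identical(dim(status), dim(x)))
      stop("status must have the same shape as x")
  }
  colnames(status) <- parts
  structure(
    list(animal_id = as.character(animal_id), fps = fps, parts = parts,
         x = x, y = y, status = status, n_frames = nrow(x)),
    class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  n_missing <- sum(x$status == "missing")
  cat(sprintf(
    "<trajectory_set> animal '%s': %d parts, %d frames @ %g fps (%.1f s)\n",
    x$animal_id, length(x$parts), x$n_frames, x$fps, x$n_frames / x$fps))
  cat("  parts:", paste(x$parts, collapse = ", "), "\n")
  if (n_missing > 0)
    cat(sprintf("  %d missing samples (%.1f%%)\n", n_missing,
                100 * n_missing / length(x$status)))
  invisible(x)
}

#' Canonical seven-point tracking layout
#'
#' The standard marker set for open-field rodent tracking: snout, the
#' four paws, the body midpoint and the tail base.  The midpoint acts as
#' the reference node (network backbone) in the coupling analysis.
#'
#' @return Character vector of seven part labels.
#' @export
default_parts <- function() {
  c("snout", "front_paw_left", "front_paw_right", "midpoint",
    "hind_paw_left", "hind_paw_right", "tail_base")
}

# internal: frames x (2m) matrix of interleaved X/Y series with
# axis-tagged column names ("<part>.x", "<part>.y")
traj_series_matrix <- function(traj, axes = c("x", "y")) {
  stopifnot(inherits(traj, "trajectory_set"))
  cols <- list()
  for (p in traj$parts) {
    if ("x" %in% axes) cols[[paste0(p, ".x")]] <- traj$x[, p]
    if ("y" %in% axes) cols[[paste0(p, ".y")]] <- traj$y[, p]
  }
  do.call(cbind, cols)
}
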