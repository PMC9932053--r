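#' Delay-aligned partial couplings between all body-part pairs
#'
#' For one animal and one scale, computes for every unordered pair of
#' parts the shift-maximized detrended partial correlation and the
#' maximizing delay.  Residuals are computed per axis from the sliding
#' second-order detrending; the X- and Y-axis delayed cross-covariances
#' are summed (total squared displacement) before the shifted entry is
#' re-inserted into the covariance matrix and propagated through the
#' DCCA normalization and matrix inversion, so the reported strength is
#' the shift-maximized partial correlation.  `delay > 0` means the
#' first part of the pair leads.
#'
#' @param traj a clean [trajectory_set()].
#' @param scale scale in frames.
#' @param order detrending order (default 2).
#' @param max_shift maximum delay magnitude in frames (default
#'   `floor(scale / 2)`).
#' @return Data frame with one row per unordered pair (`part_i` before
#'   `part_j` in part order): `part_i`, `part_j`, `strength`, `delay`
#'   (frames, positive = `part_i` leads).
#' @export
delayed_partial_couplings <- function(traj, scale, order = 2L,
                                      max_shift = floor(scale / 2)) {
  stopifnot(inherits(traj, "trajectory_set"))
  if (scale < 2) stop("scale too small for delay analysis")
  parts <- traj$parts
  m <- length(parts)
  if (m < 2L) stop("need at least two parts")
  res <- list()
  for (axis in c("x", "y")) {
    coords <- if (axis == "x") traj$x else traj$y
    res[[axis]] <- lapply(parts, function(p)
      sliding_residuals(cumsum(coords[, p]), scale, order = order,
                        flat = FALSE))
  }
  flat <- function(axis) sapply(res[[axis]], function(R) as.vector(t(R)))
  F2 <- fluctuation_matrix(flat("x")) + fluctuation_matrix(flat("y"))
  pairs <- which(upper.tri(diag(m)), arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(pairs)), function(pi) {
    i <- pairs[pi, 1]; j <- pairs[pi, 2]
    ccx <- shifted_window_cross(res$x[[i]], res$x[[j]], max_shift)
    ccy <- shifted_window_cross(res$y[[i]], res$y[[j]], max_shift)
    vals <- vapply(seq_along(ccx$shift), function(k) {
      F2k <- F2
      F2k[i, j] <- F2k[j, i] <- ccx$value[k] + ccy$value[k]
      Rk <- stats::cov2cor(F2k)
      Pk <- dpcca_coefficients(Rk)
      if (is.null(Pk)) NA_real_ else Pk[i, j]
    }, 0.0)
    ord <- order(-vals, abs(ccx$shift), ccx$shift, na.last = TRUE)
    best <- ord[1L]
    data.frame(part_i = parts[i], part_j = parts[j],
               strength = vals[best], delay = ccx$shift[best])
  })
  do.call(rbind, rows)
}

#' Assemble the directed body-part interaction graph
#'
#' Turns delay-aligned couplings at one scale into a directed graph:
#' nodes are body parts; each pair contributes one edge whose direction
#' follows the sign of the delay (the leading part is the source — the
#' cause precedes the response), with zero-delay pairs emitted as
#' undirected.  Edges touching the body midpoint form the network
#' backbone.
#'
#' @param couplings data frame from [delayed_partial_couplings()]
#'   (columns `part_i`, `part_j`, `strength`, `delay`), covering every
#'   pair of `parts`.
#' @param parts node labels in display order.
#' @param scale scale in frames the couplings were computed at.
#' @param fps frames per second, for delays in seconds.
#' @return Object of class `interaction_graph`: list with `nodes` and
#'   an `edges` data frame (`src`, `dst`, `directed`, `strength`,
#'   `delay_s`, `scale_s`, `backbone`).
#' @export
build_graph <- function(couplings, parts, scale, fps = 30) {
  need <- which(upper.tri(diag(length(parts))), arr.ind = TRUE)
  want <- paste(parts[need[, 1]], parts[need[, 2]], sep = "~")
  have <- paste(couplings$part_i, couplings$part_j, sep = "~")
  missing <- setdiff(want, have)
  if (length(missing) > 0)
    stop("incomplete couplings: missing pair(s) ",
         paste(missing, collapse = ", "))
  edges <- do.call(rbind, lapply(seq_len(nrow(couplings)), function(r) {
    ci <- couplings[r, ]
    if (ci$delay >= 0) {
      src <- ci$part_i; dst <- ci$part_j
    } else {
      src <- ci$part_j; dst <- ci$part_i
    }
    data.frame(src = src, dst = dst, directed = ci$delay != 0,
               strength = ci$strength, delay_s = abs(ci$delay) / fps,
               scale_s = scale / fps,
               backbone = "midpoint" %in% c(ci$part_i, ci$part_j))
  }))
  structure(list(nodes = parts, edges = edges, scale_frames = scale,
                 fps = fps),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("<interaction_graph> %d nodes, %d edges (scale %.2f s)\n",
              length(x$nodes), nrow(x$edges),
              x$scale_frames / x$fps))
  invisible(x)
}

#' Scale-resolved interaction networks for one animal
#'
#' Convenience wrapper: delay-aligned partial couplings and graph
#' construction at each requested scale (default the 5 s and 30 s
#' reporting scales).
#'
#' @param traj a clean [trajectory_set()].
#' @param scale_seconds scales in seconds (default `c(5, 30)`).
#' @inheritParams delayed_partial_couplings
#' @return Named list of `interaction_graph` objects.
#' @export
body_part_network <- function(traj, scale_seconds = c(5, 30), order = 2L) {
  graphs <- lapply(scale_seconds, function(ss) {
    s <- round(ss * traj$fps)
    build_graph(delayed_partial_couplings(traj, s, order = order),
                parts = traj$parts, scale = s, fps = traj$fps)
  })
  names(graphs) <- paste0(scale_seconds, "s")
  graphs
}

# canonical per-pair table (part_i < part_j in node order, signed delay)
graph_pair_table <- function(g) {
  ord <- match(g$edges$src, g$nodes) < match(g$edges$dst, g$nodes)
  data.frame(
    part_i = ifelse(ord, g$edges$src, g$edges$dst),
    part_j = ifelse(ord, g$edges$dst, g$edges$src),
    strength = g$edges$strength,
    delay_s = ifelse(ord, 1, -1) * g$edges$delay_s)
}

#' Compare interaction graphs between two groups
#'
#' Per-edge differences of coupling strength and delay between two
#' cohorts (each given as one graph or a list of per-animal graphs at
#' the same scale over the same node set).  Delays are compared on the
#' canonical signed axis (positive when the first part in node order
#' leads) and summarized by group medians; no significance is attached.
#'
#' @param graphs_a,graphs_b `interaction_graph` or list thereof (group
#'   a = reference, b = comparison).
#' @return Data frame per pair: `part_i`, `part_j`, `strength_a`,
#'   `strength_b`, `d_strength`, `delay_a_s`, `delay_b_s`, `d_delay_s`
#'   (differences are b minus a).
#' @export
compare_graphs <- function(graphs_a, graphs_b) {
  as_list <- function(g) if (inherits(g, "interaction_graph")) list(g) else g
  ga <- as_list(graphs_a); gb <- as_list(graphs_b)
  if (!setequal(ga[[1]]$nodes, gb[[1]]$nodes))
    stop("graphs have different node sets")
  med <- function(gl) {
    tab <- do.call(rbind, lapply(gl, graph_pair_table))
    key <- paste(tab$part_i, tab$part_j, sep = "~")
    data.frame(key = unique(key),
               strength = tapply(tab$strength, key, stats::median)[unique(key)],
               delay_s = tapply(tab$delay_s, key, stats::median)[unique(key)])
  }
  ma <- med(ga); mb <- med(gb)
  if (!setequal(ma$key, mb$key)) stop("graphs cover different pairs")
  mb <- mb[match(ma$key, mb$key), ]
  parts <- do.call(rbind, strsplit(ma$key, "~", fixed = TRUE))
  data.frame(part_i = parts[, 1], part_j = parts[, 2],
             strength_a = ma$strength, strength_b = mb$strength,
             d_strength = mb$strength - ma$strength,
             delay_a_s = ma$delay_s, delay_b_s = mb$delay_s,
             d_delay_s = mb$delay_s - ma$delay_s,
             row.names = NULL)
}

#' Export an interaction graph
#'
#' Writes GraphML (via igraph, with typed edge attributes `strength`,
#' `delay_s`, `scale_s`, `directed_edge`, `backbone`) or a flat
#' edge-list CSV.  Both round-trip through [import_graph()].
#'
#' @param graph an `interaction_graph`.
#' @param path output file.
#' @param format `"graphml"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(graph, "interaction_graph"))
  if (format == "csv") {
    utils::write.csv(graph$edges, path, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      graph$edges[, c("src", "dst", "directed", "strength", "delay_s",
                      "scale_s", "backbone")],
      directed = TRUE,
      vertices = data.frame(name = graph$nodes))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read back an exported interaction graph
#'
#' @param path file written by [export_graph()].
#' @param format `"graphml"` or `"csv"`.
#' @param scale_frames,fps metadata not carried by the flat formats;
#'   defaults recover them from the edge attributes where possible.
#' @return An `interaction_graph`.
#' @export
import_graph <- function(path, format = c("graphml", "csv"),
                         scale_frames = NULL, fps = 30) {
  format <- match.arg(format)
  if (format == "csv") {
    edges <- utils::read.csv(path, stringsAsFactors = FALSE)
    nodes <- unique(c(edges$src, edges$dst))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- igraph::V(g)$name
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(src = el$from, dst = el$to,
                        directed = as.logical(el$directed),
                        strength = el$strength, delay_s = el$delay_s,
                        scale_s = el$scale_s,
                        backbone = as.logical(el$backbone))
  }
  if (is.null(scale_frames))
    scale_frames <- round(edges$scale_s[1] * fps)
  structure(list(nodes = nodes, edges = edges,
                 scale_frames = scale_frames, fps = fps),
            class = "interaction_graph")
}
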