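#' Default pipeline configuration
#'
#' All tunable parameters of the simulate/analyze/compare pipeline with
#' their defaults.  The configuration is serialized (with its hash and
#' the package version) into every output directory for reproducibility.
#'
#' @return Named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    fps = 30,
    likelihood_threshold = 0.6,
    median_window = 5L,
    detrend_order = 2L,
    n_scales = 20L,
    rotation_exponent = 1.25,
    window_seconds = 30,
    window_overlap = 0.5,
    fence_k = 1.5,
    adjust = "bonferroni",
    graph_scales_s = c(5, 30),
    px_per_cm = NULL,
    seed = 1L,
    simulate = list(
      n_per_group = 10L,
      n_frames = 27000L,
      crossover_s_control = 8,
      crossover_s_test = 4,
      alpha_small = 2,
      alpha_large = 0.5,
      rho = 0.8,
      noise_sd = 0.05)
  ), class = "pipeline_config")
}

#' Load a YAML pipeline configuration
#'
#' Reads a YAML file and merges it over [default_config()]; unknown
#' keys are rejected.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return A `pipeline_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_into <- function(base, upd, prefix = "") {
    for (k in names(upd)) {
      if (!k %in% names(base))
        stop("unknown config key: ", prefix, k)
      if (is.list(base[[k]]) && is.list(upd[[k]]))
        base[[k]] <- merge_into(base[[k]], upd[[k]], paste0(prefix, k, "."))
      else base[[k]] <- upd[[k]]
    }
    base
  }
  structure(merge_into(unclass(cfg), user), class = "pipeline_config")
}

# stable polynomial hash of the deparsed config (reproducibility stamp);
# kept below 2^31 so double arithmetic stays exact
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(unclass(cfg)), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_run_metadata <- function(cfg, out_dir) {
  meta <- list(config = unclass(cfg), config_hash = config_hash(cfg),
               package_version = as.character(
                 utils::packageVersion("gaitscale")))
  yaml::write_yaml(meta, file.path(out_dir, "run_metadata.yaml"))
}

#' Simulate a synthetic cohort to DeepLabCut CSV files
#'
#' Generates a two-group synthetic study (crossover-shifted test group
#' by default) and writes one DLC-dialect CSV per animal plus a
#' manifest listing files, group labels and generative parameters.
#' Deterministic under the configured seed.
#'
#' @param cfg a `pipeline_config` (see [default_config()]).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the manifest as a data frame.
#' @export
cmd_simulate <- function(cfg = default_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sm <- cfg$simulate
  mk <- function(sx) synth_config(
    n_frames = sm$n_frames, fps = cfg$fps, crossover_s = sx,
    alpha_small = sm$alpha_small, alpha_large = sm$alpha_large,
    coupling = data.frame(part = setdiff(default_parts(), "midpoint"),
                          rho = sm$rho, delay = 0L),
    noise_sd = sm$noise_sd, seed = cfg$seed)
  study <- gen_group_study(sm$n_per_group, mk(sm$crossover_s_control),
                           mk(sm$crossover_s_test), seed = cfg$seed)
  manifest <- data.frame(
    file = paste0(names(study$trajs), ".csv"),
    animal = names(study$trajs), group = study$groups)
  for (i in seq_along(study$trajs))
    write_dlc_csv(study$trajs[[i]], file.path(out_dir, manifest$file[i]))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  write_run_metadata(cfg, out_dir)
  message("wrote ", nrow(manifest), " trajectories to ", out_dir)
  invisible(manifest)
}

#' Analyze a directory of trajectory CSVs
#'
#' Reads every CSV listed in the manifest (or all CSVs in the
#' directory), preprocesses (gap filling + median filter), runs the
#' multi-scale DFA/DCCA/DPCCA analysis per axis, and writes tidy
#' tables: `fluctuation.csv` (per pair, axis combination and scale) and
#' `crossovers.csv` (per part and axis).
#'
#' @param in_dir directory with DLC CSV files (and optionally
#'   `manifest.csv`).
#' @param cfg a `pipeline_config`.
#' @param out_dir output directory.
#' @return Invisibly, a list with both tables.
#' @export
cmd_analyze <- function(in_dir, cfg = default_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(in_dir, "manifest.csv")
  if (file.exists(manifest_path)) {
    manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  } else {
    files <- setdiff(list.files(in_dir, pattern = "\\.csv$"), "manifest.csv")
    if (length(files) == 0L) stop("no CSV files found in ", in_dir)
    manifest <- data.frame(file = files,
                           animal = sub("\\.csv$", "", files),
                           group = NA_character_)
  }
  fluct <- list(); cross <- list(); parts_ref <- NULL
  for (i in seq_len(nrow(manifest))) {
    fp <- file.path(in_dir, manifest$file[i])
    traj <- read_dlc_csv(fp, cfg$likelihood_threshold, fps = cfg$fps,
                         animal_id = manifest$animal[i])$traj
    if (is.null(parts_ref)) parts_ref <- traj$parts
    missing_parts <- setdiff(parts_ref, traj$parts)
    if (length(missing_parts) > 0)
      stop("file ", manifest$file[i], " is missing tracked part(s): ",
           paste(missing_parts, collapse = ", "))
    traj <- preprocess_trajectory(traj, window = cfg$median_window)
    scales <- scale_grid(traj$n_frames, order = cfg$detrend_order,
                         n_scales = cfg$n_scales)
    an <- analyze_trajectory(traj, scales = scales,
                             order = cfg$detrend_order)
    tab <- dpcca_table(an$xy, animal = manifest$animal[i])
    tab$group <- manifest$group[i]
    fluct[[i]] <- tab
    cx <- crossover_table(an, animal = manifest$animal[i],
                          rho = cfg$rotation_exponent)
    cx$group <- manifest$group[i]
    cross[[i]] <- cx
  }
  fluct <- do.call(rbind, fluct)
  cross <- do.call(rbind, cross)
  utils::write.csv(fluct, file.path(out_dir, "fluctuation.csv"),
                   row.names = FALSE)
  utils::write.csv(cross, file.path(out_dir, "crossovers.csv"),
                   row.names = FALSE)
  write_run_metadata(cfg, out_dir)
  message("analyzed ", nrow(manifest), " animals -> ", out_dir)
  invisible(list(fluctuation = fluct, crossovers = cross))
}

#' Compare two groups from analysis tables
#'
#' Consumes the tables written by [cmd_analyze()]: tests crossover
#' positions between groups per part and axis, and builds per-scale
#' p-value profiles of the part-vs-midpoint correlation coefficients
#' (specific, same-axis, and unspecific, cross-axis).  Results go to
#' `comparisons.csv` and `crossover_tests.csv`.
#'
#' @param analysis_dir directory written by [cmd_analyze()].
#' @param cfg a `pipeline_config`.
#' @param out_dir output directory.
#' @return Invisibly, a list with both result tables.
#' @export
cmd_compare <- function(analysis_dir, cfg = default_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fluct <- utils::read.csv(file.path(analysis_dir, "fluctuation.csv"),
                           stringsAsFactors = FALSE)
  cross <- utils::read.csv(file.path(analysis_dir, "crossovers.csv"),
                           stringsAsFactors = FALSE)
  groups <- setdiff(unique(fluct$group), NA)
  if (length(groups) != 2L)
    stop("comparison needs exactly two labeled groups, found ",
         length(groups))
  # crossover-position tests per (part, axis)
  key <- interaction(cross$part, cross$axis, drop = TRUE)
  ct <- do.call(rbind, lapply(split(cross, key), function(d) {
    va <- d$s_x_seconds[d$group == groups[1]]
    vb <- d$s_x_seconds[d$group == groups[2]]
    if (!is.null(cfg$fence_k)) {
      if (length(va) >= 4) va <- tukey_fence(va, cfg$fence_k)$kept
      if (length(vb) >= 4) vb <- tukey_fence(vb, cfg$fence_k)$kept
    }
    mw <- mann_whitney(va, vb)
    data.frame(part = d$part[1], axis = d$axis[1], U = mw$U, p = mw$p,
               median_control = stats::median(va),
               median_test = stats::median(vb))
  }))
  ct$p_adj <- stats::p.adjust(ct$p, method = cfg$adjust)
  # per-scale correlation profiles: part vs midpoint, specific X-X plus
  # unspecific X-Y, from the joint-axis table
  is_mid <- function(s) sub("\\.[xy]$", "", s) == "midpoint"
  sel <- (is_mid(fluct$series_j) & !is_mid(fluct$series_i)) |
         (is_mid(fluct$series_i) & !is_mid(fluct$series_j))
  fm <- fluct[sel & !is.na(fluct$group), ]
  part_of <- function(s) sub("\\.[xy]$", "", s)
  axis_of <- function(s) sub("^.*\\.", "", s)
  pcol <- ifelse(is_mid(fm$series_i), fm$series_j, fm$series_i)
  mcol <- ifelse(is_mid(fm$series_i), fm$series_i, fm$series_j)
  fm$metric <- paste0(part_of(pcol), ".", axis_of(pcol), "_vs_mid.",
                      axis_of(mcol), ".R")
  samples <- data.frame(group = fm$group, animal = fm$animal,
                        metric = fm$metric, scale = fm$scale_seconds,
                        value = fm$R)
  prof <- scale_profile(samples, fence_k = cfg$fence_k,
                        adjust = cfg$adjust)
  utils::write.csv(ct, file.path(out_dir, "crossover_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(prof, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  write_run_metadata(cfg, out_dir)
  invisible(list(crossover_tests = ct, comparisons = prof))
}
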