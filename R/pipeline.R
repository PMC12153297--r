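#' Default run configuration
#'
#' All tunable parameters of the pipeline in one validated list.
#' Physical calibration (`pixel_size_um`, `dt_s`) has no default and must
#' be supplied before tracking: the apparent diffusion coefficient in
#' um^2/s depends on it.  The remaining defaults are the standard
#' analysis settings: 250 ms frame interval movies analyzed with a
#' 3 px search radius, 20-frame rolling segments, a mobility threshold
#' of 0.0003 um^2/s reached in at least 10% of segments, 1000-replicate
#' randomization nulls with a 0.1 um minimum-separation cutoff and a
#' 21-bin position histogram.
#'
#' @param ... overrides as `name = value` pairs.
#' @return A validated named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    pixel_size_um = NA_real_,   # required for tracking; no guessing
    dt_s = 0.25,
    log_sigma_px = 2,
    threshold_k_sd = 1,
    stats_in_mask = TRUE,
    search_radius_px = 3,
    refine_window_px = 7L,
    seg_len = 20L,
    stride = 1L,
    d_min_um2_s = 3e-4,
    mobile_fraction_min = 0.10,
    n_sims = 1000L,
    cutoff_um = 0.1,
    bins = 21L,
    wrap = "circumferential",
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_param("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
}

validate_config <- function(cfg) {
  pos <- c("dt_s", "log_sigma_px", "search_radius_px", "cutoff_um")
  for (nm in c("dt_s", "log_sigma_px", "search_radius_px"))
    check_positive(cfg[[nm]], nm)
  check_nonneg(cfg$cutoff_um, "cutoff_um")
  check_nonneg(cfg$d_min_um2_s, "d_min_um2_s")
  if (!is.na(cfg$pixel_size_um)) check_positive(cfg$pixel_size_um, "pixel_size_um")
  if (cfg$seg_len < 2) stop_param("seg_len must be >= 2")
  if (cfg$mobile_fraction_min < 0 || cfg$mobile_fraction_min > 1)
    stop_param("mobile_fraction_min must lie in [0, 1]")
  if (!cfg$wrap %in% c("circumferential", "both", "none"))
    stop_param("wrap must be one of circumferential/both/none")
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file whose keys match [default_config()] fields.
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}

#' Generate a full set of synthetic fixtures on disk
#'
#' Writes a rendered movie (multi-frame TIFF) with its ground-truth
#' localization table, a set of synthetic cells (puncta + ends CSVs) and
#' a FRAP intensity CSV, plus a JSON manifest recording the seed and all
#' generation parameters so the outputs are reproducible from the
#' manifest alone.
#'
#' @param config a `run_config` (needs `pixel_size_um`).
#' @param out_dir output directory (created if missing).
#' @param n_particles,n_frames,d_mobile,mobile_fraction,sigma_loc_um
#'   movie ground-truth parameters.
#' @param n_cells,n_puncta,cell_length_um,cell_radius_um cell-pattern
#'   parameters.
#' @param frap_regime,frap_k FRAP regime and exchange rate (1/min).
#' @return invisibly, the manifest list.
#' @export
run_simulate <- function(config, out_dir,
                         n_particles = 8L, n_frames = 240L,
                         d_mobile = 0.003, mobile_fraction = 0.25,
                         sigma_loc_um = 0.02,
                         n_cells = 5L, n_puncta = 25L,
                         cell_length_um = 4, cell_radius_um = 0.4,
                         frap_regime = "exchange", frap_k = 0.15) {
  stopifnot(inherits(config, "run_config"))
  if (is.na(config$pixel_size_um))
    stop_param("config$pixel_size_um is required to render a movie")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop_param("cannot create output directory '%s'", out_dir)
  seed <- config$seed

  n_mobile <- round(mobile_fraction * n_particles)
  d <- c(rep(d_mobile, n_mobile), rep(0, n_particles - n_mobile))
  grid_n <- ceiling(sqrt(n_particles))
  span <- 64 * config$pixel_size_um
  margin <- span / (grid_n + 1)
  gx <- margin * (((seq_len(n_particles) - 1) %% grid_n) + 1)
  gy <- margin * (((seq_len(n_particles) - 1) %/% grid_n) + 1)
  tracks <- simulate_tracks(n_particles, n_frames, d, sigma_loc_um,
                            dt = config$dt_s, origin_x = gx, origin_y = gy,
                            seed = seed)
  movie <- render_movie(tracks, nrow = 64, ncol = 64,
                        pixel_size_um = config$pixel_size_um,
                        seed = seed + 1L)
  write_movie(movie, file.path(out_dir, "movie.tif"), scale_max = 2^16)
  write.csv(movie$truth, file.path(out_dir, "movie_truth.csv"),
            row.names = FALSE)

  cells <- lapply(seq_len(n_cells), function(i)
    simulate_cell_puncta("random", n_puncta, cell_length_um,
                         radius_mean_um = cell_radius_um,
                         cutoff_um = config$cutoff_um,
                         cell_id = sprintf("cell_%02d", i),
                         seed = seed + 100L + i))
  write_cells(cells, file.path(out_dir, "puncta.csv"),
              file.path(out_dir, "ends.csv"))

  frap <- simulate_frap(frap_regime, k = frap_k, seed = seed + 200L)
  write.csv(frap$data, file.path(out_dir, "frap.csv"), row.names = FALSE)

  manifest <- list(
    config = unclass(config),
    movie = list(n_particles = n_particles, n_frames = n_frames,
                 d_mobile = d_mobile, mobile_fraction = mobile_fraction,
                 sigma_loc_um = sigma_loc_um, scale_max = 2^16),
    cells = list(n_cells = n_cells, n_puncta = n_puncta,
                 length_um = cell_length_um, radius_um = cell_radius_um),
    frap = list(regime = frap_regime, k = frap_k),
    files = c("movie.tif", "movie_truth.csv", "puncta.csv", "ends.csv",
              "frap.csv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Detect and link one movie, writing CSV outputs
#'
#' @param config a `run_config` with `pixel_size_um` set.
#' @param movie_path multi-frame TIFF, or a `movie` object.
#' @param out_dir output directory for `tracks.csv` and `qc.json`.
#' @param scale_max TIFF intensity full scale (see [write_movie()]).
#' @return invisibly, the tracks data.frame.
#' @export
run_track <- function(config, movie_path, out_dir, scale_max = 2^16) {
  stopifnot(inherits(config, "run_config"))
  movie <- if (inherits(movie_path, "movie")) movie_path
           else read_movie(movie_path, config$pixel_size_um, config$dt_s,
                           scale_max = scale_max)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop_param("cannot create output directory '%s'", out_dir)
  tracks <- track_movie(movie,
                        log_sigma = config$log_sigma_px,
                        k_sd = config$threshold_k_sd,
                        search_radius = config$search_radius_px,
                        window = config$refine_window_px,
                        stats_in_mask = config$stats_in_mask)
  write.csv(tracks, file.path(out_dir, "tracks.csv"), row.names = FALSE)
  qc <- list(n_detections = nrow(tracks),
             n_tracks = length(unique(tracks$track_id)),
             single_punctum = length(unique(tracks$track_id)) < 2)
  jsonlite::write_json(qc, file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA)
  if (qc$single_punctum)
    warning("fewer than 2 puncta detected; movie fails QC for mobility scoring")
  invisible(tracks)
}

#' Score track mobility and write a per-movie summary
#'
#' @param config a `run_config`.
#' @param tracks_path tracks CSV (from [run_track()]) or a data.frame.
#' @param out_path output JSON path.
#' @param movie_id identifier recorded in the summary.
#' @return invisibly, the `movie_summary`.
#' @export
run_mobility <- function(config, tracks_path, out_path,
                         movie_id = "movie_1") {
  stopifnot(inherits(config, "run_config"))
  tracks <- if (is.data.frame(tracks_path)) tracks_path else read.csv(tracks_path)
  summ <- summarize_movie(tracks, dt = config$dt_s,
                          seg_len = config$seg_len, stride = config$stride,
                          d_min = config$d_min_um2_s,
                          mobile_fraction_min = config$mobile_fraction_min,
                          movie_id = movie_id)
  out <- summ[c("movie_id", "n_tracks_total", "n_tracks_short",
                "n_tracks_scored", "n_mobile", "percent_mobile", "qc_pass")]
  jsonlite::write_json(out, out_path, auto_unbox = TRUE, digits = NA)
  invisible(summ)
}

#' Spatial analysis of a strain's cells, with per-cell CSV and strain JSON
#'
#' @param config a `run_config`.
#' @param puncta_path,ends_path input CSVs (see [read_cells()]).
#' @param out_dir output directory for `cells.csv` and `strain.json`.
#' @return invisibly, the per-cell data.frame.
#' @export
run_spatial <- function(config, puncta_path, ends_path, out_dir) {
  stopifnot(inherits(config, "run_config"))
  cells <- read_cells(puncta_path, ends_path)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop_param("cannot create output directory '%s'", out_dir)
  res <- lapply(seq_along(cells), function(i)
    analyze_cell(cells[[i]], n_sims = config$n_sims,
                 cutoff_um = config$cutoff_um, wrap = config$wrap,
                 seed = config$seed + i))
  flat <- do.call(rbind, lapply(res, function(r) {
    if (isTRUE(r$excluded))
      data.frame(cell_id = r$cell_id, strain = r$strain, n = r$n,
                 length_um = NA, radius_um = NA, nnmd_um = NA,
                 density_per_um2 = NA, ce = NA, null_mean = NA,
                 null_sd = NA, p_two_sided = NA, asymmetry = NA,
                 excluded = TRUE)
    else
      data.frame(cell_id = r$cell_id, strain = r$strain, n = r$n,
                 length_um = r$length_um, radius_um = r$radius_um,
                 nnmd_um = r$nnmd_um, density_per_um2 = r$density_per_um2,
                 ce = r$ce, null_mean = r$null_mean, null_sd = r$null_sd,
                 p_two_sided = r$p_two_sided, asymmetry = r$asymmetry,
                 excluded = FALSE)
  }))
  write.csv(flat, file.path(out_dir, "cells.csv"), row.names = FALSE)
  ok <- !flat$excluded
  strain_res <- lapply(split(flat[ok, ], flat$strain[ok]), function(d) {
    if (nrow(d) < 2) return(list(n_cells = nrow(d), p_value = NA))
    st <- strain_test(d$ce, d$null_mean)
    c(list(n_cells = nrow(d), mean_ce = mean(d$ce)), st)
  })
  jsonlite::write_json(strain_res, file.path(out_dir, "strain.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(flat)
}

#' FRAP normalization from an intensity CSV
#'
#' @param config a `run_config` (unused parameters are accepted for
#'   interface uniformity).
#' @param intensities_path CSV with `replicate`, `category`, `roi_id`,
#'   `time_min`, `intensity`, or a data.frame.
#' @param out_path output CSV for the percent-of-original summary.
#' @return invisibly, the `frap_summary`.
#' @export
run_frap <- function(config, intensities_path, out_path) {
  data <- if (is.data.frame(intensities_path)) intensities_path
          else read.csv(intensities_path)
  corrected <- subtract_background(data)
  summ <- percent_of_original(corrected)
  write.csv(summ, out_path, row.names = FALSE)
  invisible(summ)
}
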