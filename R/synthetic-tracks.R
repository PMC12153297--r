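#' Simulate 2D Brownian particle tracks with localization noise
#'
#' Generates ground-truth tracks for benchmarking detection, linking and
#' mobility classification.  Each particle performs a 2D Brownian walk in
#' the imaging plane with per-axis increment variance `2 * D * dt`;
#' observed positions add i.i.d. Gaussian localization noise of standard
#' deviation `sigma_loc` per axis, so the observed mean squared
#' displacement follows `4 * D * tau + 4 * sigma_loc^2`.
#'
#' @param n_particles number of particles.
#' @param n_frames number of frames (>= 2).
#' @param d diffusion coefficient D in um^2/s (0 for stationary particles);
#'   recycled to `n_particles`.
#' @param sigma_loc localization noise sd in um.
#' @param dt frame interval in seconds.
#' @param origin_x,origin_y starting coordinates in um, recycled.
#' @param d_threshold particles with `d` above this are labeled `"mobile"`,
#'   the rest `"stationary"`; labels record ground truth, not a measurement.
#' @param seed RNG seed for reproducibility.
#'
#' @return An object of class `track_set`: a list with `positions` (a
#'   data.frame with columns `particle`, `frame`, `x_true_um`, `y_true_um`,
#'   `x_um`, `y_um`), `d`, `sigma_loc`, `dt`, `label` and `seed`.
#' @examples
#' ts <- simulate_tracks(n_particles = 3, n_frames = 40, d = c(0, 0, 0.01),
#'                       sigma_loc = 0.02, dt = 0.25, seed = 1)
#' head(ts$positions)
#' @export
simulate_tracks <- function(n_particles, n_frames, d, sigma_loc, dt = 0.25,
                            origin_x = 0, origin_y = 0,
                            d_threshold = 0, seed = NULL) {
  if (n_frames < 2) stop_param("`n_frames` must be at least 2")
  check_positive(dt, "dt")
  check_nonneg(sigma_loc, "sigma_loc")
  if (any(!is.finite(d)) || any(d < 0))
    stop_param("`d` must be non-negative and finite")
  d <- rep_len(d, n_particles)
  origin_x <- rep_len(origin_x, n_particles)
  origin_y <- rep_len(origin_y, n_particles)

  positions <- with_seed(seed, {
    out <- vector("list", n_particles)
    for (p in seq_len(n_particles)) {
      step_sd <- sqrt(2 * d[p] * dt)
      dx <- if (step_sd > 0) rnorm(n_frames - 1L, 0, step_sd) else numeric(n_frames - 1L)
      dy <- if (step_sd > 0) rnorm(n_frames - 1L, 0, step_sd) else numeric(n_frames - 1L)
      x <- origin_x[p] + c(0, cumsum(dx))
      y <- origin_y[p] + c(0, cumsum(dy))
      nx <- if (sigma_loc > 0) rnorm(n_frames, 0, sigma_loc) else numeric(n_frames)
      ny <- if (sigma_loc > 0) rnorm(n_frames, 0, sigma_loc) else numeric(n_frames)
      out[[p]] <- data.frame(particle = p, frame = seq_len(n_frames),
                             x_true_um = x, y_true_um = y,
                             x_um = x + nx, y_um = y + ny)
    }
    do.call(rbind, out)
  })

  structure(list(positions = positions,
                 d = d, sigma_loc = sigma_loc, dt = dt,
                 label = ifelse(d > d_threshold, "mobile", "stationary"),
                 seed = seed),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set: %d particles x %d frames, dt = %g s, sigma_loc = %g um\n",
              length(x$d), max(x$positions$frame), x$dt, x$sigma_loc))
  cat(sprintf("  labels: %s\n",
              paste(sprintf("%s=%d", names(table(x$label)), table(x$label)),
                    collapse = ", ")))
  invisible(x)
}

#' Render a synthetic fluorescence movie from ground-truth tracks
#'
#' Draws each particle as a 2D Gaussian spot (an idealized diffraction
#' limited point-spread function) on a constant background, then applies
#' Poisson shot noise and Gaussian read noise.  Emulates time-lapse TIRF
#' acquisition of membrane puncta.
#'
#' @param tracks a [simulate_tracks()] `track_set` (observed positions are
#'   used as the true emitter positions for rendering).
#' @param nrow,ncol image size in pixels.
#' @param pixel_size_um pixel size in um/px.
#' @param psf_sd_px Gaussian spot sd in px.
#' @param amplitude peak spot amplitude in counts.
#' @param background constant background level in counts.
#' @param poisson_noise logical; apply Poisson shot noise.
#' @param read_noise_sd Gaussian read noise sd in counts (0 disables).
#' @param cell_intensity diffuse fluorescence added inside the cell
#'   footprint (counts).  Real cells carry cytoplasmic signal that the
#'   time-average mask keys on; 0 renders spots on bare background.
#' @param cell_margin_px margin of the cell footprint around the bounding
#'   box of all particle positions.
#' @param seed RNG seed.
#'
#' @return A `movie` object: list with `frames` (array row x col x frame),
#'   `pixel_size_um`, `dt`, plus `truth`, a data.frame of true pixel
#'   coordinates (`particle`, `frame`, `x_px`, `y_px`) per frame.
#'   Particles falling outside the field raise an error rather than being
#'   cropped silently.
#' @export
render_movie <- function(tracks, nrow = 64, ncol = 64, pixel_size_um,
                         psf_sd_px = 1.3, amplitude = 200, background = 10,
                         poisson_noise = TRUE, read_noise_sd = 2,
                         cell_intensity = 30, cell_margin_px = 8,
                         seed = NULL) {
  stopifnot(inherits(tracks, "track_set"))
  check_positive(pixel_size_um, "pixel_size_um")
  check_positive(psf_sd_px, "psf_sd_px")
  check_nonneg(amplitude, "amplitude")
  check_nonneg(background, "background")
  pos <- tracks$positions
  x_px <- um_to_px(pos$x_um, pixel_size_um)
  y_px <- um_to_px(pos$y_um, pixel_size_um)
  out_of_field <- x_px < 1 | x_px > ncol | y_px < 1 | y_px > nrow
  if (any(out_of_field)) {
    bad <- unique(pos$particle[out_of_field])
    stop_param("particle(s) %s leave the %dx%d field; enlarge the image or shift origins",
               paste(bad, collapse = ", "), nrow, ncol)
  }
  n_frames <- max(pos$frame)
  frames <- array(background, dim = c(nrow, ncol, n_frames))
  if (cell_intensity > 0) {
    ri <- max(1L, floor(min(y_px)) - cell_margin_px):min(nrow, ceiling(max(y_px)) + cell_margin_px)
    rj <- max(1L, floor(min(x_px)) - cell_margin_px):min(ncol, ceiling(max(x_px)) + cell_margin_px)
    frames[ri, rj, ] <- frames[ri, rj, ] + cell_intensity
  }
  half <- ceiling(4 * psf_sd_px)
  for (k in seq_len(nrow(pos))) {
    f <- pos$frame[k]
    cx <- x_px[k]; cy <- y_px[k]
    ci <- max(1L, floor(cy) - half):min(nrow, ceiling(cy) + half)
    cj <- max(1L, floor(cx) - half):min(ncol, ceiling(cx) + half)
    gy <- exp(-(ci - cy)^2 / (2 * psf_sd_px^2))
    gx <- exp(-(cj - cx)^2 / (2 * psf_sd_px^2))
    frames[ci, cj, f] <- frames[ci, cj, f] + amplitude * outer(gy, gx)
  }
  frames <- with_seed(seed, {
    if (poisson_noise) {
      frames[] <- rpois(length(frames), lambda = frames)
    }
    if (read_noise_sd > 0) {
      frames <- frames + rnorm(length(frames), 0, read_noise_sd)
    }
    frames
  })
  truth <- data.frame(particle = pos$particle, frame = pos$frame,
                      x_px = x_px, y_px = y_px)
  new_movie(frames, pixel_size_um, tracks$dt, truth = truth)
}

#' Construct a movie object
#'
#' @param frames numeric array (rows x cols x frames) of non-negative-ish
#'   intensities (read noise may produce small negatives).
#' @param pixel_size_um pixel size in um/px.
#' @param dt frame interval in seconds.
#' @param truth optional ground-truth localization table.
#' @return A `movie` object.
#' @export
new_movie <- function(frames, pixel_size_um, dt, truth = NULL) {
  if (length(dim(frames)) != 3L || dim(frames)[3] < 2L)
    stop_param("`frames` must be a rows x cols x frames array with >= 2 frames")
  check_positive(pixel_size_um, "pixel_size_um")
  check_positive(dt, "dt")
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 dt = dt, truth = truth),
            class = "movie")
}

#' @export
print.movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("movie: %d x %d px, %d frames, %g um/px, dt = %g s\n",
              d[1], d[2], d[3], x$pixel_size_um, x$dt))
  invisible(x)
}
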