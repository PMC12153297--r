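#' Simulate 3D puncta positions on a cylindrical cell surface
#'
#' Places `n_puncta` points on the surface of a cylinder of the given
#' length and radius, in one of three regimes spanning the Clark-Evans
#' scale: `"random"` (homogeneous: X uniform along the axis, angle uniform
#' around it), `"grid"` (a triangular lattice on the unrolled surface,
#' optionally jittered - the maximally dispersed reference pattern) and
#' `"clumped"` (Gaussian clusters around random centers).  Whole cells are
#' regenerated until every unrolled nearest-neighbour distance exceeds
#' `cutoff_um`, emulating a minimum-resolvable separation; the default
#' 0.1 um matches the lateral resolution floor of structured-illumination
#' imaging.
#'
#' @param pattern one of `"random"`, `"grid"`, `"clumped"`.
#' @param n_puncta number of puncta (>= 1).
#' @param length_um cell length in um.
#' @param radius_mean_um,radius_sd_um per-cell cylinder radius drawn once
#'   from a Gaussian truncated positive.
#' @param cutoff_um minimum-separation cutoff on the unrolled surface in
#'   um; `0` disables rejection.
#' @param grid_jitter_um Gaussian jitter sd applied to lattice points.
#' @param n_clusters,cluster_sd_um cluster count and spread for the
#'   clumped regime.
#' @param radial_jitter_um optional per-punctum Gaussian sd on the radial
#'   distance, emulating cylinder-fit scatter.
#' @param max_attempts bound on whole-cell regenerations before the
#'   rejection loop errors out.
#' @param cell_id,strain identifiers carried into the output.
#' @param seed RNG seed.
#'
#' @return A `cell_record`: list with `cell_id`, `strain`, `puncta`
#'   (data.frame `x_um`, `y_um`, `z_um`), `ends` (data.frame `end_index`,
#'   `x_um`, `y_um`), and ground truth `radius_um`, `length_um`,
#'   `pattern`, `seed`.  The cell axis lies along X from 0 to `length_um`.
#' @export
simulate_cell_puncta <- function(pattern = c("random", "grid", "clumped"),
                                 n_puncta, length_um,
                                 radius_mean_um = 0.4, radius_sd_um = 0,
                                 cutoff_um = 0.1,
                                 grid_jitter_um = 0.05,
                                 n_clusters = 3, cluster_sd_um = 0.2,
                                 radial_jitter_um = 0,
                                 max_attempts = 1000L,
                                 cell_id = "cell_1", strain = "synthetic",
                                 seed = NULL) {
  pattern <- match.arg(pattern)
  if (n_puncta < 1) stop_param("`n_puncta` must be >= 1")
  check_positive(length_um, "length_um")
  check_positive(radius_mean_um, "radius_mean_um")
  check_nonneg(radius_sd_um, "radius_sd_um")
  check_nonneg(cutoff_um, "cutoff_um")

  # crude feasibility guard: each punctum needs a disc of radius cutoff/2
  area <- 2 * pi * radius_mean_um * length_um
  if (cutoff_um > 0 && n_puncta * pi * (cutoff_um / 2)^2 > area)
    stop_param(paste0("cannot place %d puncta at a %.3g um minimum-separation ",
                      "cutoff on a %.3g um^2 surface"),
               n_puncta, cutoff_um, area)

  res <- with_seed(seed, {
    found <- NULL
    for (attempt in seq_len(max_attempts)) {
      r <- rnorm(1, radius_mean_um, radius_sd_um)
      if (r <= 0) next
      circ <- 2 * pi * r
      xs <- switch(pattern,
        random = list(x = runif(n_puncta, 0, length_um),
                      s = runif(n_puncta, 0, circ)),
        grid = grid_points(n_puncta, length_um, circ, grid_jitter_um),
        clumped = clump_points(n_puncta, length_um, circ,
                               n_clusters, cluster_sd_um))
      x <- pmin(pmax(xs$x, 0), length_um)
      s <- xs$s %% circ
      if (length(x) >= 2 && cutoff_um > 0) {
        nnd <- wrapped_nnd(x, s, circ, wrap = "circumferential")
        if (min(nnd) <= cutoff_um) next
      }
      theta <- s / r
      rad <- r
      if (radial_jitter_um > 0)
        rad <- pmax(r + rnorm(length(x), 0, radial_jitter_um), 1e-6)
      found <- list(x = x, y = rad * cos(theta), z = rad * sin(theta),
                    radius = r)
      break
    }
    if (is.null(found))
      stop_param(paste0("no admissible configuration in %d attempts at the ",
                        "%.3g um cutoff; lower the density or the cutoff"),
                 max_attempts, cutoff_um)
    found
  })

  structure(list(cell_id = cell_id, strain = strain,
                 puncta = data.frame(x_um = res$x, y_um = res$y,
                                     z_um = res$z),
                 ends = data.frame(end_index = c(1L, 2L),
                                   x_um = c(0, length_um), y_um = c(0, 0)),
                 radius_um = res$radius, length_um = length_um,
                 pattern = pattern, seed = seed),
            class = "cell_record")
}

#' @export
print.cell_record <- function(x, ...) {
  cat(sprintf("cell_record %s (%s): %d puncta, L = %.2f um, pattern = %s\n",
              x$cell_id, x$strain, nrow(x$puncta), x$length_um, x$pattern))
  invisible(x)
}

# Triangular lattice on the unrolled (x, s) rectangle.  Column count is
# rounded so the lattice is commensurate with the circumference (the wrap
# dimension); row spacing is stretched to fit the length exactly.  When
# the lattice has more sites than n, a random subset is kept.
grid_points <- function(n, length_um, circ, jitter_sd) {
  a <- sqrt(2 * length_um * circ / (sqrt(3) * n))  # target spacing from density
  ncol <- max(1L, round(circ / a))
  a_s <- circ / ncol
  nrow <- max(1L, round(length_um / (sqrt(3) / 2 * a_s)))
  dx <- length_um / nrow
  i <- rep(seq_len(nrow), each = ncol)
  j <- rep(seq_len(ncol), times = nrow)
  x <- (i - 0.5) * dx
  s <- ((j - 1) + 0.5 * (i %% 2)) * a_s
  if (length(x) < n)
    stop_param("triangular lattice fits only %d of %d requested puncta; adjust the cell size",
               length(x), n)
  if (length(x) > n) {
    keep <- sample.int(length(x), n)
    x <- x[keep]; s <- s[keep]
  }
  if (jitter_sd > 0) {
    x <- x + rnorm(n, 0, jitter_sd)
    s <- s + rnorm(n, 0, jitter_sd)
  }
  list(x = x, s = s)
}

clump_points <- function(n, length_um, circ, n_clusters, cluster_sd) {
  n_clusters <- max(1L, min(n_clusters, n))
  cx <- runif(n_clusters, 0, length_um)
  cs <- runif(n_clusters, 0, circ)
  member <- sample.int(n_clusters, n, replace = TRUE)
  list(x = cx[member] + rnorm(n, 0, cluster_sd),
       s = cs[member] + rnorm(n, 0, cluster_sd))
}
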