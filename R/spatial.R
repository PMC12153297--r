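#' Align a cell's 3D puncta to its long axis
#'
#' Centers the puncta at their mean, builds the 3x3 scatter matrix of the
#' centered positions, and rotates its dominant principal axis onto X via
#' singular value decomposition.  The hand-picked end-wall positions are
#' then used to recenter the long axis on the cell midpoint (the puncta
#' mean need not coincide with it).  Sign convention: end 1 gets negative
#' X, making outputs deterministic.
#'
#' @param cell a `cell_record` (see [simulate_cell_puncta()]), or any list
#'   with `puncta` (`x_um`, `y_um`, `z_um`) and `ends` (`end_index`,
#'   `x_um`, `y_um`; end Z is taken on the cell axis).
#' @return An `aligned_cell`: list with `positions` (data.frame `x_um`,
#'   `y_um`, `z_um` in the aligned frame, long axis on X, origin at the
#'   midpoint), `length_um`, `radial_um` (per-punctum distance from the X
#'   axis), `rotation` (the 3x3 orthonormal matrix used), `cell_id`,
#'   `strain`.
#' @export
align_cell <- function(cell) {
  p <- as.matrix(cell$puncta[, c("x_um", "y_um", "z_um")])
  ends <- cell$ends[order(cell$ends$end_index), , drop = FALSE]
  if (nrow(p) < 2 && nrow(ends) < 2)
    stop_param("alignment needs >= 2 puncta or both cell ends")
  ctr <- colMeans(p)
  pc <- sweep(p, 2, ctr)
  e3 <- cbind(ends$x_um, ends$y_um, 0) # end Z unknown; taken on the axis
  ec <- sweep(e3, 2, ctr)

  if (nrow(p) >= 3) {
    scatter <- crossprod(pc)            # definite positive 3x3
    rot <- svd(scatter)$u               # columns = principal axes
  } else {
    # too few puncta for a stable SVD: align to the end-to-end vector
    axis <- ec[2, ] - ec[1, ]
    rot <- cbind(axis / sqrt(sum(axis^2)), diag(3)[, 2:3])
    rot <- qr.Q(qr(rot))
    if (sum(rot[, 1] * axis) < 0) rot[, 1] <- -rot[, 1]
  }
  if (det(rot) < 0) rot[, 3] <- -rot[, 3]
  # The hand-picked ends are 2D image coordinates: points on the cell
  # axis observed in the XY plane.  Their position along the axis is
  # recovered by projecting onto the in-plane component of the axis
  # direction (norm-corrected, so a tilted axis does not foreshorten the
  # length): for p = c + t u, t = (p_xy - c_xy) . u_xy / |u_xy|^2.
  axis_xy <- rot[1:2, 1]
  if (sum(axis_xy^2) < 1e-12)
    stop_param("cell axis is perpendicular to the imaging plane; end positions are uninformative")
  end_t <- as.numeric(ec[, 1:2] %*% axis_xy) / sum(axis_xy^2)
  # orient the axis so end 1 sits at negative X
  if (end_t[1] > end_t[2]) {
    rot[, 1] <- -rot[, 1]; rot[, 2] <- -rot[, 2]   # keep det = +1
    end_t <- -end_t
  }
  pr <- pc %*% rot
  shift <- mean(end_t)                  # end midpoint along the axis
  pr[, 1] <- pr[, 1] - shift
  len <- abs(end_t[2] - end_t[1])
  structure(list(positions = data.frame(x_um = pr[, 1], y_um = pr[, 2],
                                        z_um = pr[, 3]),
                 length_um = len,
                 radial_um = sqrt(pr[, 2]^2 + pr[, 3]^2),
                 rotation = rot,
                 cell_id = cell$cell_id %||% NA,
                 strain = cell$strain %||% NA),
            class = "aligned_cell")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Basal-body asymmetry over the long axis
#'
#' Ratio of the higher to the lower punctum count on the two sides of the
#' cell midpoint.  Puncta exactly at x = 0 are counted toward the side
#' with fewer puncta (conservative).  An empty side yields an infinite
#' ratio, returned with a flag instead of failing.
#'
#' @param aligned an [align_cell()] result.
#' @return list with `ratio` (>= 1, possibly `Inf`), `n_low`, `n_high`,
#'   `degenerate` (TRUE when one side is empty).
#' @export
asymmetry_ratio <- function(aligned) {
  x <- aligned$positions$x_um
  if (length(x) < 1) stop_param("no puncta")
  left <- sum(x < 0); right <- sum(x > 0); mid <- sum(x == 0)
  lo <- min(left, right) + mid
  hi <- max(left, right)
  if (mid > 0 && lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
  list(ratio = if (lo == 0) Inf else hi / lo,
       n_low = lo, n_high = hi, degenerate = lo == 0)
}

#' Mean relative-position histogram across cells
#'
#' Maps each punctum to a relative long-axis position in `[0, 1]`,
#' randomizes each cell's orientation (flip with probability 1/2, seeded)
#' so no side preference is imposed, and accumulates counts into
#' `bins` equal bins.
#'
#' @param cells list of `aligned_cell`s.
#' @param bins number of equal bins (default 21).
#' @param seed RNG seed for the orientation flips.
#' @return list with `breaks`, `counts` (total over cells; sums to the
#'   total punctum count), `mean_per_cell` (per-bin mean count per cell).
#' @export
position_histogram <- function(cells, bins = 21L, seed = NULL) {
  if (length(cells) < 1) stop_param("need >= 1 cell")
  breaks <- seq(0, 1, length.out = bins + 1L)
  mat <- with_seed(seed, {
    t(vapply(cells, function(cl) {
      rel <- cl$positions$x_um / cl$length_um + 0.5
      rel <- pmin(pmax(rel, 0), 1)
      if (runif(1) < 0.5) rel <- 1 - rel
      tabulate(pmin(findInterval(rel, breaks, rightmost.closed = TRUE), bins),
               nbins = bins)
    }, numeric(bins)))
  })
  list(breaks = breaks, counts = colSums(mat), mean_per_cell = colMeans(mat))
}

#' Fit a cylinder to an aligned cell
#'
#' Algebraic (Kasa) least-squares circle fit to the Y/Z projection of the
#' puncta, extended along X into a cylinder.  Closed-form and
#' deterministic; adequate at the point counts seen per cell.  With fewer
#' than 3 distinct projections the radius falls back to the mean radial
#' distance about the axis.
#'
#' @param aligned an [align_cell()] result.
#' @return A `cylinder_fit`: list with `center` (Y, Z), `radius_um`,
#'   `radius_sd_um` (sd of per-punctum distances to the fitted center),
#'   `length_um`, `area_um2` (lateral surface `2 pi r L`, cell ends
#'   excluded), `volume_um3` (`pi r^2 L`), `fallback` flag.
#' @export
fit_cylinder <- function(aligned) {
  yz <- as.matrix(aligned$positions[, c("y_um", "z_um")])
  L <- aligned$length_um
  fallback <- FALSE
  center <- c(0, 0)
  if (nrow(unique(round(yz, 12))) >= 3) {
    A <- cbind(2 * yz[, 1], 2 * yz[, 2], 1)
    b <- yz[, 1]^2 + yz[, 2]^2
    sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
    if (!is.null(sol) && is.finite(sol[3] + sol[1]^2 + sol[2]^2) &&
        sol[3] + sol[1]^2 + sol[2]^2 > 0) {
      center <- sol[1:2]
      r <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
    } else {
      fallback <- TRUE
    }
  } else {
    fallback <- TRUE
  }
  if (fallback) {
    r <- mean(sqrt(yz[, 1]^2 + yz[, 2]^2))
    if (r <= 0) stop_param("cannot fit a cylinder: all puncta on the axis")
  }
  d <- sqrt((yz[, 1] - center[1])^2 + (yz[, 2] - center[2])^2)
  structure(list(center = center, radius_um = r,
                 radius_sd_um = if (length(d) > 1) sd(d) else 0,
                 length_um = L,
                 area_um2 = 2 * pi * r * L,
                 volume_um3 = pi * r^2 * L,
                 fallback = fallback),
            class = "cylinder_fit")
}

#' Unroll puncta onto the cylinder surface
#'
#' Projects each punctum onto the fitted cylinder and cuts the cylinder
#' along its axis: the circumferential coordinate is `r * angle` with the
#' angle taken about the fitted circle center, giving flat coordinates
#' (`x_um`, `s_um`) on a `length x circumference` rectangle that is
#' periodic in `s`.  Radial deviation from the surface is discarded.
#'
#' @param aligned an [align_cell()] result.
#' @param fit a [fit_cylinder()] result.
#' @return An `unrolled_points`: list with `x_um`, `s_um` (in
#'   `[0, circumference)`), `circumference_um`, `length_um`, `radius_um`,
#'   `on_axis` (logical flags for puncta too close to the axis for a
#'   defined angle).
#' @export
unroll <- function(aligned, fit) {
  yz <- as.matrix(aligned$positions[, c("y_um", "z_um")])
  dy <- yz[, 1] - fit$center[1]
  dz <- yz[, 2] - fit$center[2]
  on_axis <- sqrt(dy^2 + dz^2) < 1e-9
  if (any(on_axis))
    warning(sum(on_axis), " punctum/a on the cylinder axis: angle undefined")
  ang <- atan2(dz, dy) %% (2 * pi)
  circ <- 2 * pi * fit$radius_um
  new_unrolled(x = aligned$positions$x_um, s = fit$radius_um * ang,
               circumference = circ, length = fit$length_um,
               radius = fit$radius_um, on_axis = on_axis)
}

#' Construct unrolled surface points directly
#'
#' Low-level constructor used by the unrolling step, the null simulator
#' and tests (e.g. lattice reference patterns).
#'
#' @param x longitudinal coordinates (um).
#' @param s circumferential coordinates (um; wrapped into
#'   `[0, circumference)`).
#' @param circumference surface circumference (um).
#' @param length surface length (um); defaults to `max(x) - min(x)`.
#' @param radius cylinder radius (um); defaults to
#'   `circumference / (2 pi)`.
#' @param on_axis logical flags (default all FALSE).
#' @return An `unrolled_points` object.
#' @export
new_unrolled <- function(x, s, circumference, length = NULL, radius = NULL,
                         on_axis = NULL) {
  check_positive(circumference, "circumference")
  structure(list(x_um = as.numeric(x),
                 s_um = as.numeric(s) %% circumference,
                 circumference_um = circumference,
                 length_um = length %||% (max(x) - min(x)),
                 radius_um = radius %||% (circumference / (2 * pi)),
                 on_axis = on_axis %||% rep(FALSE, base::length(x))),
            class = "unrolled_points")
}

# Pairwise distances on the unrolled rectangle.  wrap = "circumferential"
# applies the periodic metric in s only (the physical cylinder: no edge in
# the circumferential dimension, hard edges along the axis); "both" is a
# flat torus; "none" uses plain Euclidean distances.
unrolled_dist <- function(u, wrap = c("circumferential", "both", "none")) {
  wrap <- match.arg(wrap)
  dx <- abs(outer(u$x_um, u$x_um, "-"))
  if (wrap == "both") {
    Lx <- u$length_um
    dx <- pmin(dx, Lx - dx)
  }
  ds <- abs(outer(u$s_um, u$s_um, "-"))
  if (wrap != "none") ds <- pmin(ds, u$circumference_um - ds)
  sqrt(dx^2 + ds^2)
}

#' Nearest-neighbour distances on the unrolled surface
#'
#' Euclidean distances on the unrolled plane with a periodic wrap in the
#' circumferential dimension (the cylinder has no edge there) and hard
#' edges along the axis.
#'
#' @param u an `unrolled_points` object.
#' @param wrap `"circumferential"` (default, the physical cylinder),
#'   `"both"` (flat torus; reference patterns), or `"none"` (sensitivity
#'   analysis).
#' @return list with `nnd` (per-punctum nearest-neighbour distance) and
#'   `nnmd` (their mean).
#' @export
nn_distances <- function(u, wrap = "circumferential") {
  n <- length(u$x_um)
  if (n < 2) stop_param("nearest-neighbour distances need >= 2 puncta")
  d <- unrolled_dist(u, wrap)
  diag(d) <- Inf
  nnd <- apply(d, 1, min)
  list(nnd = nnd, nnmd = mean(nnd))
}

# vectorized nearest-neighbour mean distance for the simulators (avoids
# list/validation overhead in tight Monte-Carlo loops)
wrapped_nnd <- function(x, s, circumference, wrap = "circumferential") {
  dx <- abs(outer(x, x, "-"))
  ds <- abs(outer(s, s, "-"))
  ds <- pmin(ds, circumference - ds)
  d <- sqrt(dx^2 + ds^2)
  diag(d) <- Inf
  apply(d, 1, min)
}

#' Clark-Evans ratio of an unrolled point pattern
#'
#' Ratio of the observed mean nearest-neighbour distance to the value
#' expected for a homogeneous Poisson pattern of the same intensity on
#' the same surface area, `1 / (2 sqrt(rho))` with `rho = n / area`.
#' Values near 1 indicate spatial randomness; 0 is fully clumped
#' (coincident points) and `2 sqrt(2 / sqrt(3)) ~ 2.149` (a triangular
#' lattice) is the maximal dispersion.
#'
#' @param u an `unrolled_points` object.
#' @param area surface area in um^2; defaults to
#'   `length * circumference` of `u` (for a cylinder, `2 pi r L`,
#'   exclusive of the cell ends).
#' @param wrap metric mode passed to [nn_distances()].
#' @return A `ce_result`: list with `n`, `nnmd_um`, `density_per_um2`,
#'   `expected_nnd_um`, `ce`.
#' @export
clark_evans <- function(u, area = NULL, wrap = "circumferential") {
  area <- area %||% (u$length_um * u$circumference_um)
  if (!is.numeric(area) || area <= 0) stop_param("`area` must be positive")
  nn <- nn_distances(u, wrap)
  n <- length(u$x_um)
  rho <- n / area
  expected <- 1 / (2 * sqrt(rho))
  structure(list(n = n, nnmd_um = nn$nnmd, density_per_um2 = rho,
                 expected_nnd_um = expected, ce = nn$nnmd / expected),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("ce_result: n = %d, NNMD = %.4f um, density = %.3f /um^2, CE = %.4f\n",
              x$n, x$nnmd_um, x$density_per_um2, x$ce))
  invisible(x)
}

#' Per-cell Monte-Carlo randomization null for the Clark-Evans ratio
#'
#' Simulates `n_sims` cells matched to a measured cell: same punctum
#' count and length, radius drawn per replicate from a Gaussian with the
#' cell's mean radial distance and its sd (truncated positive, capturing
#' cylinder-fit uncertainty), positions randomized uniformly in X and in
#' the angle about the axis.  Replicates are redrawn until all unrolled
#' nearest-neighbour distances exceed `cutoff_um`, emulating the imaging
#' resolution floor (which by itself shifts the null CE slightly above 1).
#' The Clark-Evans ratio is computed exactly as for observed cells.
#'
#' @param n punctum count of the measured cell.
#' @param length_um cell length.
#' @param radial_mean_um,radial_sd_um mean and sd of the cell's radial
#'   distances (sd 0 fixes the radius).
#' @param n_sims number of replicates (default 1000).
#' @param cutoff_um minimum-separation cutoff (default 0.1 um; 0
#'   disables).
#' @param wrap metric mode (see [nn_distances()]).
#' @param max_attempts per-replicate bound on rejections.
#' @param seed RNG seed.
#' @return A `null_distribution`: list with `ce` (all simulated values),
#'   `mean`, `sd`, `n_sims`, `cutoff_um`, `seed`.
#' @export
simulate_null <- function(n, length_um, radial_mean_um, radial_sd_um = 0,
                          n_sims = 1000L, cutoff_um = 0.1,
                          wrap = "circumferential",
                          max_attempts = 1000L, seed = NULL) {
  if (n < 2) stop_param("the null needs >= 2 puncta")
  check_positive(length_um, "length_um")
  check_positive(radial_mean_um, "radial_mean_um")
  check_nonneg(cutoff_um, "cutoff_um")
  both <- identical(wrap, "both")
  ce <- with_seed(seed, {
    vapply(seq_len(n_sims), function(k) {
      for (attempt in seq_len(max_attempts)) {
        r <- rnorm(1, radial_mean_um, radial_sd_um)
        if (r <= 0) next
        circ <- 2 * pi * r
        x <- runif(n, 0, length_um)
        s <- runif(n, 0, circ)
        dx <- abs(outer(x, x, "-"))
        if (both) dx <- pmin(dx, length_um - dx)
        ds <- abs(outer(s, s, "-"))
        ds <- pmin(ds, circ - ds)
        d <- sqrt(dx^2 + ds^2)
        diag(d) <- Inf
        nnd <- apply(d, 1, min)
        if (cutoff_um > 0 && min(nnd) <= cutoff_um) next
        rho <- n / (circ * length_um)
        return(mean(nnd) * 2 * sqrt(rho))
      }
      stop_param("null replicate found no admissible configuration in %d attempts at the %.3g um cutoff",
                 max_attempts, cutoff_um)
    }, numeric(1))
  })
  structure(list(ce = ce, mean = mean(ce), sd = sd(ce),
                 n_sims = n_sims, cutoff_um = cutoff_um, seed = seed),
            class = "null_distribution")
}

#' Empirical-CDF probability of an observed Clark-Evans value
#'
#' Evaluates the empirical cumulative distribution function of the null
#' at the observed value.  Sidedness is reported three ways: the lower
#' tail `F(obs)`, the upper tail `1 - F(obs^-)`, and a two-sided
#' probability `min(1, 2 min(lower, upper))`; the two-sided value is what
#' summaries use.
#'
#' @param observed observed CE value.
#' @param null a [simulate_null()] result (or numeric vector of null CE
#'   values).
#' @return list with `lower`, `upper`, `two_sided`.
#' @export
ecdf_probability <- function(observed, null) {
  ce <- if (inherits(null, "null_distribution")) null$ce else as.numeric(null)
  if (length(ce) < 1) stop_param("empty null distribution")
  lower <- mean(ce <= observed)
  upper <- mean(ce >= observed)
  list(lower = lower, upper = upper,
       two_sided = min(1, 2 * min(lower, upper)))
}

#' Paired strain-level test of observed vs randomized Clark-Evans values
#'
#' Two-sided paired t-test across the cells of a strain, each observed CE
#' compared with the mean of that cell's own randomization null.
#'
#' @param observed_ce per-cell observed CE values.
#' @param null_means per-cell null means (same order).
#' @return list with `p_value`, `t`, `df`, `mean_difference`, `n`,
#'   `degenerate` (TRUE when all differences are zero, in which case the
#'   comparison is reported as non-significant with `p_value = 1`).
#' @export
strain_test <- function(observed_ce, null_means) {
  if (length(observed_ce) != length(null_means))
    stop_param("observed and null vectors differ in length")
  if (length(observed_ce) < 2) stop_param("the strain test needs >= 2 cells")
  diffs <- observed_ce - null_means
  if (sd(diffs) == 0) {
    return(list(p_value = 1, t = NA_real_, df = length(diffs) - 1L,
                mean_difference = mean(diffs), n = length(diffs),
                degenerate = TRUE))
  }
  tt <- t.test(observed_ce, null_means, paired = TRUE)
  list(p_value = tt$p.value, t = unname(tt$statistic),
       df = unname(tt$parameter), mean_difference = mean(diffs),
       n = length(diffs), degenerate = FALSE)
}

#' Full spatial analysis of one cell
#'
#' align -> cylinder fit -> unroll -> nearest neighbours -> Clark-Evans ->
#' randomization null -> ECDF probability, with the same unrolled metric
#' used for the observed and simulated patterns.
#'
#' @param cell a `cell_record`.
#' @param n_sims,cutoff_um,wrap,seed passed to [simulate_null()].
#' @param radius_for_density `"fit"` (default: the fitted-circle radius
#'   sets the surface area for density) or `"radial_mean"` (the mean
#'   radial distance, as used inside the null generator).
#' @return list with `cell_id`, `strain`, `n`, `length_um`, `radius_um`,
#'   `radius_sd_um`, `nnmd_um`, `density_per_um2`, `ce`, `null_mean`,
#'   `null_sd`, `p_lower`, `p_upper`, `p_two_sided`, `asymmetry`,
#'   `excluded` (+ `reason`), and the intermediate objects (`aligned`,
#'   `fit`, `unrolled`, `null`).
#' @export
analyze_cell <- function(cell, n_sims = 1000L, cutoff_um = 0.1,
                         wrap = "circumferential", seed = NULL,
                         radius_for_density = c("fit", "radial_mean")) {
  radius_for_density <- match.arg(radius_for_density)
  if (nrow(cell$puncta) < 2) {
    return(list(cell_id = cell$cell_id, strain = cell$strain,
                n = nrow(cell$puncta), excluded = TRUE,
                reason = "fewer than 2 puncta"))
  }
  aligned <- align_cell(cell)
  fit <- fit_cylinder(aligned)
  u <- unroll(aligned, fit)
  r_density <- if (radius_for_density == "fit") fit$radius_um else mean(aligned$radial_um)
  area <- 2 * pi * r_density * fit$length_um
  ce <- clark_evans(u, area = area, wrap = wrap)
  null <- simulate_null(ce$n, fit$length_um,
                        radial_mean_um = mean(aligned$radial_um),
                        radial_sd_um = sd(aligned$radial_um),
                        n_sims = n_sims, cutoff_um = cutoff_um,
                        wrap = wrap, seed = seed)
  pr <- ecdf_probability(ce$ce, null)
  asym <- asymmetry_ratio(aligned)
  list(cell_id = cell$cell_id, strain = cell$strain,
       n = ce$n, length_um = fit$length_um,
       radius_um = fit$radius_um, radius_sd_um = fit$radius_sd_um,
       nnmd_um = ce$nnmd_um, density_per_um2 = ce$density_per_um2,
       ce = ce$ce, null_mean = null$mean, null_sd = null$sd,
       p_lower = pr$lower, p_upper = pr$upper, p_two_sided = pr$two_sided,
       asymmetry = asym$ratio, excluded = FALSE, reason = NA_character_,
       aligned = aligned, fit = fit, unrolled = u, null = null)
}

#' Triangular lattice on a flat torus
#'
#' Exact hexagonal-packing reference pattern: `ncol` columns at spacing
#' `a` and `nrow` rows at spacing `a sqrt(3)/2`, with alternate rows
#' offset by `a/2`, on a periodic rectangle commensurate with the
#' lattice.  Evaluated with `wrap = "both"`, its Clark-Evans ratio is the
#' closed-form maximum `2 sqrt(2 / sqrt(3))`.
#'
#' @param spacing lattice constant `a` in um.
#' @param ncol,nrow lattice dimensions (`nrow` must be even so the offset
#'   rows tile periodically).
#' @return An `unrolled_points` covering a torus of size
#'   `(nrow a sqrt(3)/2) x (ncol a)`.
#' @export
triangular_lattice <- function(spacing = 0.5, ncol = 5L, nrow = 6L) {
  check_positive(spacing, "spacing")
  if (nrow %% 2 != 0) stop_param("`nrow` must be even for periodic tiling")
  h <- spacing * sqrt(3) / 2
  i <- rep(seq_len(nrow), each = ncol)
  j <- rep(seq_len(ncol), times = nrow)
  x <- (i - 1) * h
  s <- ((j - 1) + 0.5 * (i %% 2)) * spacing
  u <- new_unrolled(x, s, circumference = ncol * spacing,
                    length = nrow * h)
  u
}
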