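# Shared fixtures and independent oracles used across the test files.

# noiseless Gaussian spot frame with known sub-pixel center (px coords)
gaussian_frame <- function(nrow = 64, ncol = 64, cx, cy, amp = 200,
                           sd_px = 1.3, background = 10) {
  j <- matrix(rep(seq_len(ncol), each = nrow), nrow, ncol)
  i <- matrix(rep(seq_len(nrow), times = ncol), nrow, ncol)
  background + amp * exp(-((j - cx)^2 + (i - cy)^2) / (2 * sd_px^2))
}

# random proper rotation matrix in 3D
random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

# rotation within the imaging (XY) plane, optionally composed with a
# small out-of-plane tilt about Y
inplane_rotation <- function(phi, tilt = 0) {
  rz <- matrix(c(cos(phi), sin(phi), 0, -sin(phi), cos(phi), 0, 0, 0, 1), 3, 3)
  ry <- matrix(c(cos(tilt), 0, -sin(tilt), 0, 1, 0, sin(tilt), 0, cos(tilt)), 3, 3)
  rz %*% ry
}

# apply a rigid transform to a cell_record (ends get z = 0 pre-transform,
# matching the 2D end export convention)
transform_cell <- function(cell, rot, shift) {
  p <- as.matrix(cell$puncta) %*% rot
  e <- cbind(cell$ends$x_um, cell$ends$y_um, 0) %*% rot
  structure(list(cell_id = cell$cell_id, strain = cell$strain,
                 puncta = data.frame(x_um = p[, 1] + shift[1],
                                     y_um = p[, 2] + shift[2],
                                     z_um = p[, 3] + shift[3]),
                 ends = data.frame(end_index = 1:2,
                                   x_um = e[, 1] + shift[1],
                                   y_um = e[, 2] + shift[2])),
            class = "cell_record")
}

# brute-force O(n^2) nearest-neighbour oracle on the unrolled rectangle
oracle_nnd <- function(x, s, circ, wrap_x = FALSE, len_x = NULL) {
  n <- length(x)
  nnd <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      dx <- abs(x[i] - x[j])
      if (wrap_x) dx <- min(dx, len_x - dx)
      ds <- abs(s[i] - s[j])
      ds <- min(ds, circ - ds)
      best <- min(best, sqrt(dx^2 + ds^2))
    }
    nnd[i] <- best
  }
  nnd
}

# exhaustive assignment oracle (minimum total cost over all permutations)
oracle_assignment_cost <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  min(vapply(perms(seq_len(n)),
             function(p) sum(cost[cbind(seq_len(n), p)]), numeric(1)))
}

# Brownian positions with localization noise, no rendering
brownian_xy <- function(n_frames, d, sigma_loc, dt) {
  step <- sqrt(2 * d * dt)
  x <- cumsum(c(0, rnorm(n_frames - 1, 0, step))) + rnorm(n_frames, 0, sigma_loc)
  y <- cumsum(c(0, rnorm(n_frames - 1, 0, step))) + rnorm(n_frames, 0, sigma_loc)
  list(x = x, y = y)
}

# canonical representation of a linking result, independent of track ids
canonical_tracks <- function(tr) {
  sp <- split(tr[, c("frame", "x", "y")], tr$track_id)
  sp <- lapply(sp, function(d) d[order(d$frame), , drop = FALSE])
  keys <- vapply(sp, function(d)
    paste(sprintf("%d:%.6f:%.6f", d$frame, d$x, d$y), collapse = "|"),
    character(1))
  sort(unname(keys))
}
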