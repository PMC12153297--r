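test_that("alignment recovers the cell frame and is isometry invariant", {
  # puncta already on the X axis, symmetric: identity-equivalent rotation
  cell <- structure(list(
    cell_id = "c", strain = "s",
    puncta = data.frame(x_um = c(-1.5, -0.5, 0.5, 1.5),
                        y_um = c(0.01, -0.01, 0.01, -0.01),
                        z_um = c(0.01, 0.01, -0.01, -0.01)),
    ends = data.frame(end_index = 1:2, x_um = c(-2, 2), y_um = c(0, 0))),
    class = "cell_record")
  al <- align_cell(cell)
  expect_equal(sort(al$positions$x_um), c(-1.5, -0.5, 0.5, 1.5),
               tolerance = 1e-3)
  expect_equal(al$length_um, 4, tolerance = 1e-4)
  expect_equal(crossprod(al$rotation), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)

  # rigid motion in the imaging plane (the transformations real
  # coordinate exports can differ by) leaves NNMD / CE / asymmetry
  # unchanged to numerical precision
  set.seed(41)
  base <- simulate_cell_puncta("random", 25, 4, radius_mean_um = 0.4,
                               cutoff_um = 0.1, seed = 42)
  a0 <- align_cell(base); f0 <- fit_cylinder(a0)
  ce0 <- clark_evans(unroll(a0, f0))
  as0 <- asymmetry_ratio(a0)
  for (k in 1:5) {
    moved <- transform_cell(base, inplane_rotation(runif(1, 0, 2 * pi)),
                            c(rnorm(2, 0, 5), 0))
    am <- align_cell(moved); fm <- fit_cylinder(am)
    cem <- clark_evans(unroll(am, fm))
    expect_equal(cem$nnmd_um, ce0$nnmd_um, tolerance = 1e-9)
    expect_equal(cem$ce, ce0$ce, tolerance = 1e-9)
    expect_equal(asymmetry_ratio(am)$ratio, as0$ratio)
  }

  # full 3D rotations: the puncta-derived quantities stay exact; the
  # length (recovered from 2D end positions) and hence CE stay within a
  # few percent for moderate out-of-plane tilt
  for (k in 1:5) {
    moved <- transform_cell(base,
                            inplane_rotation(runif(1, 0, 2 * pi),
                                             tilt = runif(1, -0.3, 0.3)),
                            rnorm(3, 0, 5))
    am <- align_cell(moved); fm <- fit_cylinder(am)
    cem <- clark_evans(unroll(am, fm))
    expect_equal(cem$nnmd_um, ce0$nnmd_um, tolerance = 1e-9)
    expect_equal(fm$radius_um, f0$radius_um, tolerance = 1e-9)
    expect_equal(cem$ce, ce0$ce, tolerance = 0.05)
  }

  # generated length recovered within 2%
  expect_equal(f0$length_um, 4, tolerance = 0.02)
})

test_that("asymmetry ratio counts sides with the documented tie rule", {
  mk <- function(x) structure(list(positions = data.frame(x_um = x)),
                              class = "aligned_cell")
  expect_equal(asymmetry_ratio(mk(c(-2, -1, -0.5, 0.5, 1, 2)))$ratio, 1)
  expect_equal(asymmetry_ratio(mk(c(-3, -2, -1, -0.5, -0.1, -0.05, 0.5, 1, 2, 3)))$ratio, 1.5)
  r <- asymmetry_ratio(mk(c(1, 2, 3)))
  expect_true(is.infinite(r$ratio))
  expect_true(r$degenerate)
  # x = 0 counted toward the smaller side
  expect_equal(asymmetry_ratio(mk(c(-1, -2, 0, 1)))$ratio, 1)
})

test_that("position histogram conserves counts and flattens uniform input", {
  mk <- function(x, L) structure(list(positions = data.frame(x_um = x),
                                      length_um = L), class = "aligned_cell")
  # all mass at midcell lands in the middle bin regardless of flips
  h1 <- position_histogram(list(mk(rep(0, 7), 4)), bins = 21, seed = 1)
  expect_equal(sum(h1$counts), 7)
  expect_equal(h1$counts[11], 7)

  # counts conserved over many cells
  set.seed(43)
  cells <- lapply(1:30, function(i) mk(runif(20, -2, 2), 4))
  h <- position_histogram(cells, bins = 21, seed = 2)
  expect_equal(sum(h$counts), 30 * 20)
  # uniform positions: per-bin means equal within Monte-Carlo error
  expect_lt(max(abs(h$mean_per_cell - 20 / 21)), 4 * sqrt(20 / 21) / sqrt(30))
})

test_that("cylinder fit recovers exact and noisy circles", {
  th <- seq(0, 2 * pi, length.out = 26)[-26]
  al <- structure(list(positions = data.frame(x_um = seq(-2, 2, length.out = 25),
                                              y_um = 0.4 * cos(th),
                                              z_um = 0.4 * sin(th)),
                       length_um = 4), class = "aligned_cell")
  f <- fit_cylinder(al)
  expect_equal(f$radius_um, 0.4, tolerance = 1e-9)
  expect_equal(f$radius_sd_um, 0, tolerance = 1e-9)
  expect_equal(f$area_um2, 2 * pi * 0.4 * 4, tolerance = 1e-9)
  expect_equal(f$volume_um3, pi * 0.16 * 4, tolerance = 1e-9)

  set.seed(47)
  aln <- structure(list(positions = data.frame(
    x_um = seq(-2, 2, length.out = 25),
    y_um = (0.4 + rnorm(25, 0, 0.02)) * cos(th),
    z_um = (0.4 + rnorm(25, 0, 0.02)) * sin(th)),
    length_um = 4), class = "aligned_cell")
  expect_lt(abs(fit_cylinder(aln)$radius_um - 0.4), 0.05)
})

test_that("unrolling preserves on-surface geodesic distances", {
  r <- 0.4; circ <- 2 * pi * r
  mkal <- function(x, ang) structure(list(
    positions = data.frame(x_um = x, y_um = r * cos(ang), z_um = r * sin(ang)),
    length_um = 4), class = "aligned_cell")

  # antipodal pair at same x: unrolled wrap separation = pi r
  al <- mkal(c(0, 0, 1), c(0, pi, pi / 3))
  f <- fit_cylinder(al)
  u <- unroll(al, f)
  d <- punctadyn:::unrolled_dist(u, "circumferential")
  expect_equal(d[1, 2], pi * f$radius_um, tolerance = 1e-6)

  # near-cut pair: wrap distance 2 r eps, not r (2 pi - 2 eps)
  eps <- 0.05
  al2 <- mkal(c(0, 0, 1), c(eps, 2 * pi - eps, pi))
  f2 <- fit_cylinder(al2)
  d2 <- punctadyn:::unrolled_dist(unroll(al2, f2), "circumferential")
  expect_equal(d2[1, 2], 2 * f2$radius_um * eps, tolerance = 1e-6)

  # geodesic formula sqrt(dx^2 + (r dtheta_wrapped)^2) for exact points
  set.seed(53)
  ang <- runif(12, 0, 2 * pi); x <- runif(12, -2, 2)
  al3 <- mkal(x, ang)
  f3 <- fit_cylinder(al3)
  u3 <- unroll(al3, f3)
  d3 <- punctadyn:::unrolled_dist(u3, "circumferential")
  for (i in 1:11) for (j in (i + 1):12) {
    dth <- abs(ang[i] - ang[j]); dth <- min(dth, 2 * pi - dth)
    expect_equal(d3[i, j], sqrt((x[i] - x[j])^2 + (f3$radius_um * dth)^2),
                 tolerance = 1e-6)
  }
})

test_that("wrapped nearest-neighbour distances match the brute-force oracle", {
  set.seed(59)
  for (k in 1:100) {
    n <- sample(3:30, 1)
    circ <- runif(1, 1, 4)
    u <- new_unrolled(runif(n, 0, 5), runif(n, 0, circ), circ, length = 5)
    nn <- nn_distances(u)
    expect_equal(nn$nnd, oracle_nnd(u$x_um, u$s_um, circ), tolerance = 1e-12)
    expect_equal(nn$nnmd, mean(nn$nnd))
    # wrap can only shorten distances relative to the cut-open plane
    expect_lte(nn$nnmd, nn_distances(u, wrap = "none")$nnmd + 1e-12)
  }
})

test_that("Clark-Evans ratio hits its closed-form anchors", {
  # coincident points: fully clumped, R = 0
  u0 <- new_unrolled(rep(1, 10), rep(0.3, 10), circumference = 2 * pi * 0.4,
                     length = 4)
  expect_equal(clark_evans(u0, area = 2 * pi * 0.4 * 4)$ce, 0)

  # exact triangular lattice on a torus: R = 2 sqrt(2 / sqrt(3)) ~ 2.1491
  lat <- triangular_lattice(spacing = 0.5, ncol = 5, nrow = 6)
  expect_equal(clark_evans(lat, wrap = "both")$ce, 2 * sqrt(2 / sqrt(3)),
               tolerance = 1e-9)

  # a commensurate grid-patterned cell run through the full pipeline
  a <- 0.5; r <- 2.5 / (2 * pi); L <- 5 * sqrt(3) / 2 * a
  g <- simulate_cell_puncta("grid", 25, L, radius_mean_um = r,
                            grid_jitter_um = 0, cutoff_um = 0, seed = 4)
  ag <- align_cell(g); fg <- fit_cylinder(ag)
  expect_equal(clark_evans(unroll(ag, fg))$ce, 2 * sqrt(2 / sqrt(3)),
               tolerance = 0.01)

  # random patterns center on R = 1 (calibration over 200 cells)
  set.seed(61)
  ces <- replicate(200, {
    circ <- 2 * pi * 0.4
    u <- new_unrolled(runif(25, 0, 4), runif(25, 0, circ), circ, length = 4)
    clark_evans(u, area = 4 * circ)$ce
  })
  expect_lt(abs(mean(ces) - 1), 0.05)
})

test_that("randomization null is reproducible, cutoff-shifted and n-dependent", {
  n1 <- simulate_null(25, 4, 0.4, 0.02, n_sims = 300, cutoff_um = 0.1, seed = 67)
  n2 <- simulate_null(25, 4, 0.4, 0.02, n_sims = 300, cutoff_um = 0.1, seed = 67)
  expect_identical(n1$ce, n2$ce)
  expect_equal(length(n1$ce), 300L)

  # resolution cutoff slightly raises the null mean above the cutoff-free one
  n0 <- simulate_null(25, 4, 0.4, 0.02, n_sims = 300, cutoff_um = 0, seed = 67)
  expect_gt(n1$mean, n0$mean)

  # null CE spread shrinks with punctum count
  sds <- vapply(c(5, 15, 45), function(n)
    simulate_null(n, 4, 0.4, 0, n_sims = 300, cutoff_um = 0, seed = 71)$sd,
    numeric(1))
  expect_true(all(diff(sds) < 0))

  expect_error(simulate_null(30, 1, 0.1, 0, n_sims = 5, cutoff_um = 0.2,
                             max_attempts = 5, seed = 1), "attempts")
})

test_that("ECDF probability reports calibrated tail areas", {
  null <- simulate_null(20, 4, 0.4, 0, n_sims = 500, cutoff_um = 0, seed = 73)
  pr_low <- ecdf_probability(min(null$ce) - 1, null)
  expect_equal(pr_low$lower, 0)
  expect_equal(pr_low$two_sided, 0)
  pr_med <- ecdf_probability(median(null$ce), null)
  expect_gt(pr_med$two_sided, 0.9)
})

test_that("paired strain test separates gridded from random patterns", {
  # degenerate: observed identical to null means
  st0 <- strain_test(c(1, 1.1, 0.9), c(1, 1.1, 0.9))
  expect_true(st0$degenerate)
  expect_equal(st0$p_value, 1)
  expect_error(strain_test(1, 1), "2 cells")

  # gridded strain: significantly non-random (power check)
  set.seed(79)
  a <- 0.5; r <- 2.5 / (2 * pi); L <- 5 * sqrt(3) / 2 * a
  obs <- numeric(12); nul <- numeric(12)
  for (i in 1:12) {
    g <- simulate_cell_puncta("grid", 25, L, radius_mean_um = r,
                              grid_jitter_um = 0.05, cutoff_um = 0,
                              seed = 1000 + i)
    ag <- align_cell(g); fg <- fit_cylinder(ag)
    obs[i] <- clark_evans(unroll(ag, fg))$ce
    nul[i] <- simulate_null(25, L, r, 0, n_sims = 200, cutoff_um = 0,
                            seed = 2000 + i)$mean
  }
  expect_lt(strain_test(obs, nul)$p_value, 0.05)
})

test_that("cell-level analysis flags degenerate cells instead of failing", {
  lone <- structure(list(cell_id = "solo", strain = "s",
                         puncta = data.frame(x_um = 1, y_um = 0.4, z_um = 0),
                         ends = data.frame(end_index = 1:2,
                                           x_um = c(0, 3), y_um = c(0, 0))),
                    class = "cell_record")
  res <- analyze_cell(lone, n_sims = 10)
  expect_true(res$excluded)
  expect_match(res$reason, "fewer than 2")
})
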