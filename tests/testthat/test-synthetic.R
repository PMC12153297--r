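test_that("Brownian track generator obeys the closed-form MSD", {
  # degenerate stationary case: nothing moves
  ts0 <- simulate_tracks(3, 10, d = 0, sigma_loc = 0, dt = 0.25, seed = 1)
  for (p in 1:3) {
    pp <- ts0$positions[ts0$positions$particle == p, ]
    expect_equal(diff(range(pp$x_um)), 0)
    expect_equal(diff(range(pp$y_um)), 0)
  }

  # lag-1 MSD of a pure Brownian walk matches 4 D dt within 3 SE
  d <- 0.01; dt <- 0.25
  ts <- simulate_tracks(1, 1e5 + 1, d = d, sigma_loc = 0, dt = dt, seed = 42)
  dx <- diff(ts$positions$x_um); dy <- diff(ts$positions$y_um)
  sq <- dx^2 + dy^2
  se <- sd(sq) / sqrt(length(sq))
  expect_lt(abs(mean(sq) - 4 * d * dt), 3 * se)

  # localization noise shifts the MSD intercept: lag-1 MSD ~ 4 D dt + 4 s^2
  s <- 0.02
  tsn <- simulate_tracks(1, 1e5 + 1, d = d, sigma_loc = s, dt = dt, seed = 43)
  sqn <- diff(tsn$positions$x_um)^2 + diff(tsn$positions$y_um)^2
  sen <- sd(sqn) / sqrt(length(sqn))
  expect_lt(abs(mean(sqn) - (4 * d * dt + 4 * s^2)), 3 * sen)
})

test_that("track generator is deterministic under a seed and validates input", {
  a <- simulate_tracks(4, 30, d = 0.005, sigma_loc = 0.02, dt = 0.25, seed = 7)
  b <- simulate_tracks(4, 30, d = 0.005, sigma_loc = 0.02, dt = 0.25, seed = 7)
  expect_identical(a, b)
  expect_error(simulate_tracks(1, 10, d = -1, sigma_loc = 0, dt = 0.25), "non-negative")
  expect_error(simulate_tracks(1, 10, d = 0, sigma_loc = -1, dt = 0.25), "sigma_loc")
  expect_error(simulate_tracks(1, 10, d = 0, sigma_loc = 0, dt = -0.1), "dt")
  expect_error(simulate_tracks(1, 1, d = 0, sigma_loc = 0, dt = 0.25), "n_frames")
})

test_that("movie renderer places spots at the true positions", {
  # zero particles is impossible (a track set has >= 1), so check the
  # noise-free background via a spot of amplitude 0
  ts <- simulate_tracks(1, 3, d = 0, sigma_loc = 0, dt = 0.25,
                        origin_x = 2, origin_y = 2, seed = 1)
  mv0 <- render_movie(ts, 40, 40, pixel_size_um = 0.1, amplitude = 0,
                      background = 7, poisson_noise = FALSE,
                      read_noise_sd = 0, cell_intensity = 0)
  expect_true(all(mv0$frames == 7))

  # one stationary spot, no noise: per-frame argmax within 1 px of truth
  mv <- render_movie(ts, 40, 40, pixel_size_um = 0.1,
                     poisson_noise = FALSE, read_noise_sd = 0,
                     cell_intensity = 0)
  for (f in 1:3) {
    idx <- which(mv$frames[, , f] == max(mv$frames[, , f]), arr.ind = TRUE)[1, ]
    expect_lt(abs(idx["col"] - mv$truth$x_px[mv$truth$frame == f]), 1)
    expect_lt(abs(idx["row"] - mv$truth$y_px[mv$truth$frame == f]), 1)
  }

  # ground-truth table bookkeeping: n rows per frame
  ts5 <- simulate_tracks(5, 4, d = 0, sigma_loc = 0, dt = 0.25,
                         origin_x = seq(0.8, 3.2, length.out = 5),
                         origin_y = 2, seed = 2)
  mv5 <- render_movie(ts5, 40, 40, pixel_size_um = 0.1, seed = 3)
  expect_equal(unname(table(mv5$truth$frame)), rep(5L, 4L), ignore_attr = TRUE)

  # out-of-field particles are an error, not a silent crop
  far <- simulate_tracks(1, 3, d = 0, sigma_loc = 0, dt = 0.25,
                         origin_x = 99, origin_y = 2, seed = 1)
  expect_error(render_movie(far, 40, 40, pixel_size_um = 0.1), "field")
})

test_that("puncta generator enforces the minimum-separation cutoff", {
  cl <- simulate_cell_puncta("random", 25, 4, radius_mean_um = 0.4,
                             cutoff_um = 0.1, seed = 5)
  al <- align_cell(cl)
  f <- fit_cylinder(al)
  nn <- nn_distances(unroll(al, f))
  expect_gt(min(nn$nnd), 0.1)

  # n = 1: no rejection possible, a single surface punctum at the radius
  one <- simulate_cell_puncta("random", 1, 4, radius_mean_um = 0.4, seed = 1)
  expect_equal(nrow(one$puncta), 1L)
  expect_equal(sqrt(one$puncta$y_um^2 + one$puncta$z_um^2), one$radius_um)

  # infeasible density names the cutoff in the error
  expect_error(
    simulate_cell_puncta("random", 400, 1, radius_mean_um = 0.2,
                         cutoff_um = 0.1, seed = 1),
    "cutoff")
  # a feasible-looking but practically unplaceable request errors out
  # instead of hanging (bounded rejection loop)
  expect_error(
    simulate_cell_puncta("random", 60, 1, radius_mean_um = 0.15,
                         cutoff_um = 0.1, max_attempts = 5, seed = 1),
    "attempts|cutoff")

  # determinism
  a <- simulate_cell_puncta("clumped", 20, 4, cutoff_um = 0.05, seed = 9)
  b <- simulate_cell_puncta("clumped", 20, 4, cutoff_um = 0.05, seed = 9)
  expect_identical(a, b)
})

test_that("FRAP simulator conserves labeled fluorescence under exchange", {
  fs <- simulate_frap("exchange", k = 0.2, noise_sd = 0, seed = 1)
  corr <- subtract_background(fs$data)
  pool <- corr[corr$category %in% c("targeted", "same_cell"), ]
  totals <- tapply(pool$intensity, pool$time_min, sum)
  post <- totals[names(totals) != "0"]
  expect_equal(max(post) - min(post), 0, tolerance = 1e-9)

  # closed-form exponential relaxation of the targeted category
  d <- fs$bleach_depth; k <- fs$k
  fbar <- mean(c(rep(1 - d, 10), rep(1, 10)))
  t_post <- setdiff(unique(fs$data$time_min), 0)
  for (tp in t_post) {
    expected <- fbar + ((1 - d) - fbar) * exp(-k * tp)
    got <- mean(corr$intensity[corr$category == "targeted" &
                                 corr$time_min == tp]) / fs$amplitude
    expect_equal(got, expected, tolerance = 1e-9)
  }

  # full-depth static bleach: targeted pinned at 0 after the bleach
  st <- simulate_frap("static", k = 0, bleach_depth = 1, noise_sd = 0)
  cs <- subtract_background(st$data)
  expect_true(all(cs$intensity[cs$category == "targeted" & cs$time_min > 0] == 0))

  # near-complete mixing: all puncta converge to the same labeled fraction
  fast <- simulate_frap("exchange", k = 50, noise_sd = 0)
  cf <- subtract_background(fast$data)
  last <- cf[cf$time_min == max(cf$time_min) &
               cf$category %in% c("targeted", "same_cell"), ]
  expect_lt(diff(range(last$intensity)), 1e-6)

  expect_error(simulate_frap("static", k = 0.5), "k = 0")
  expect_error(simulate_frap("exchange", k = 0.1, time_min = c(0, 5, 5)),
               "increasing")
})
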