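test_that("rolling segmentation arithmetic matches the window contract", {
  expect_equal(segment_starts(20), 1L)
  expect_equal(segment_starts(25), 1:6)
  expect_equal(length(segment_starts(240)), 221L)
  expect_equal(segment_starts(28, stride = 4), c(1L, 5L, 9L))
  expect_error(segment_starts(19), "shorter")
})

test_that("segment MSD averages overlapping displacements per lag", {
  # stationary: all MSDs zero, n column is L - i
  m0 <- segment_msd(rep(1, 20), rep(2, 20), dt = 0.25)
  expect_true(all(m0$msd == 0))
  expect_equal(m0$n, 20 - m0$lag)
  expect_equal(m0$tau, m0$lag * 0.25)

  # linear 1D walk x = 0..19 um: every lag-i displacement is i, MSD_i = i^2
  m1 <- segment_msd(0:19, rep(0, 20), dt = 0.25)
  expect_equal(m1$msd, m1$lag^2)
})

test_that("Dapp estimator is exact on affine MSD tables and matches a WLS oracle", {
  # exact on its own model for any intercept and segment length
  for (L in c(3, 5, 20)) {
    for (c0 in c(0, 1e-3, 0.5)) {
      lag <- seq_len(L - 1)
      tab <- data.frame(tau = lag * 0.25, msd = 4 * 0.01 * lag * 0.25 + c0,
                        n = L - lag)
      est <- estimate_dapp(tab)
      expect_equal(est$dapp, 0.01, tolerance = 1e-12)
      expect_equal(est$intercept, c0, tolerance = 1e-12)
    }
  }

  # constant MSD (pure localization noise): zero slope
  tabc <- data.frame(tau = (1:19) * 0.25, msd = 0.002, n = 19:1)
  expect_equal(estimate_dapp(tabc)$dapp, 0)

  # random tables: agree with a generic weighted-least-squares solver
  set.seed(13)
  for (k in 1:25) {
    L <- sample(5:30, 1)
    lag <- seq_len(L - 1)
    tab <- data.frame(tau = lag * 0.25, msd = abs(rnorm(L - 1, 0.01, 0.01)),
                      n = L - lag)
    fit <- lm(msd ~ tau, data = tab, weights = n)
    expect_equal(estimate_dapp(tab)$dapp, unname(coef(fit)[2]) / 4,
                 tolerance = 1e-10)
  }

  expect_error(estimate_dapp(data.frame(tau = 1, msd = 1, n = 1)), "lags")
})

test_that("fast rolling-Dapp path equals the per-segment reference", {
  set.seed(17)
  x <- cumsum(rnorm(60, 0, 0.05)); y <- cumsum(rnorm(60, 0, 0.05))
  fast <- punctadyn:::rolling_dapp(x, y, dt = 0.25)
  for (k in seq_along(fast$start)) {
    idx <- fast$start[k]:(fast$start[k] + 19)
    ref <- estimate_dapp(segment_msd(x[idx], y[idx], 0.25))
    expect_equal(fast$dapp[k], ref$dapp, tolerance = 1e-12)
    expect_equal(fast$intercept[k], ref$intercept, tolerance = 1e-12)
  }
})

test_that("mobility call applies the threshold-and-fraction rule", {
  # perfectly still: stationary
  still <- classify_track(rep(0, 40), rep(0, 40), dt = 0.25)
  expect_equal(still$label, "stationary")
  expect_equal(still$fraction_mobile, 0)

  # exactly 1 of 10 segments above threshold sits on the >= 10% boundary:
  # a single jump between frames 1 and 2 of a 29-frame track is seen by
  # segment 1 only
  x <- c(0, rep(1, 28))
  call <- classify_track(x, rep(0, 29), dt = 0.25)
  expect_equal(call$n_segments, 10L)
  expect_equal(call$fraction_mobile, 0.1)
  expect_equal(call$label, "mobile")

  # clearly diffusing track is called mobile
  set.seed(19)
  b <- brownian_xy(240, d = 0.003, sigma_loc = 0.02, dt = 0.25)
  expect_equal(classify_track(b$x, b$y, dt = 0.25)$label, "mobile")

  # negative Dapp estimates are kept, not clipped
  set.seed(23)
  n <- brownian_xy(60, d = 0, sigma_loc = 0.05, dt = 0.25)
  dapp <- classify_track(n$x, n$y, dt = 0.25)$dapp
  expect_true(any(dapp < 0))
})

test_that("percent mobile rises with the true diffusion coefficient", {
  # the 0.0003 um^2/s floor sits between the first two D values: calls
  # rise from rare (below the floor) to certain (well above it)
  set.seed(29)
  frac <- vapply(c(1e-4, 5e-4, 1e-3, 5e-3), function(d) {
    mean(replicate(60, {
      b <- brownian_xy(240, d = d, sigma_loc = 0.02, dt = 0.25)
      classify_track(b$x, b$y, dt = 0.25)$label == "mobile"
    }))
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_gt(frac[4], frac[1])
  expect_lt(frac[1], 0.5)
  expect_equal(frac[4], 1)
})

test_that("movie summary counts, QC-flags and percentages are consistent", {
  mk <- function(id, d, seed) {
    set.seed(seed)
    b <- brownian_xy(60, d = d, sigma_loc = 0.01, dt = 0.25)
    data.frame(track_id = id, frame = 1:60, x_um = b$x, y_um = b$y)
  }
  tracks <- do.call(rbind, c(
    lapply(1:19, function(i) mk(i, 0, 100 + i)),
    list(mk(20, 0.01, 999),
         data.frame(track_id = 21, frame = 1:10, x_um = 0, y_um = 0))))
  s <- summarize_movie(tracks, dt = 0.25)
  expect_equal(s$n_tracks_total, 21L)
  expect_equal(s$n_tracks_short, 1L)   # 10-frame track excluded, counted
  expect_equal(s$n_tracks_scored, 20L)
  expect_equal(s$percent_mobile, 100 * s$n_mobile / 20)
  expect_true(s$qc_pass)
  expect_equal(s$n_mobile, 1L)
  expect_equal(s$percent_mobile, 5)

  # all stationary
  s0 <- summarize_movie(do.call(rbind, lapply(1:5, function(i) mk(i, 0, i))),
                        dt = 0.25)
  expect_equal(s0$percent_mobile, 0)

  # single scoreable track: flagged, not dropped
  s1 <- summarize_movie(mk(1, 0, 1), dt = 0.25)
  expect_false(s1$qc_pass)
  expect_equal(s1$n_tracks_scored, 1L)
})
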