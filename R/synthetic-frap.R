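#' Simulate a FRAP intensity series with known ground truth
#'
#' Models photobleaching of a subset of puncta followed by either no
#' subunit exchange (`regime = "static"`: a structural, non-exchanging
#' complex) or first-order exchange through a shared well-mixed pool
#' (`regime = "exchange"`: each punctum's labeled fraction relaxes
#' exponentially at rate `k` toward the common mean, conserving total
#' labeled fluorescence).  Three ROI categories are produced - bleached
#' (`targeted`), unbleached in the same cell (`same_cell`, which shares
#' the exchange pool with the targets) and unbleached in a separate cell
#' (`separate_cell`) - plus field-`background` ROIs, mirroring the layout
#' of a redistribution experiment.
#'
#' @param regime `"static"` or `"exchange"`.
#' @param k exchange rate in 1/min; must be 0 iff `regime = "static"`.
#' @param n_per_category ROIs per punctum category (default 10).
#' @param bleach_depth fraction of the targeted fluorescence removed by the
#'   bleach, in `[0, 1]`.
#' @param time_min strictly increasing time points in minutes; the first
#'   is the single pre-bleach observation, the bleach occurs immediately
#'   after it.
#' @param amplitude original per-punctum fluorescence in counts.
#' @param background constant background level in counts.
#' @param noise_sd Gaussian measurement noise sd in counts.
#' @param replicate replicate identifier carried into the output rows.
#' @param seed RNG seed.
#'
#' @return A `frap_series`: list with `data` (data.frame `replicate`,
#'   `category`, `roi_id`, `time_min`, `intensity`) and `truth` (noise-free
#'   labeled fractions per category and time point).
#' @export
simulate_frap <- function(regime = c("static", "exchange"), k = 0,
                          n_per_category = 10, bleach_depth = 0.9,
                          time_min = c(0, 0.1, 10, 20),
                          amplitude = 100, background = 20, noise_sd = 0,
                          replicate = 1L, seed = NULL) {
  regime <- match.arg(regime)
  check_nonneg(k, "k")
  if (regime == "static" && k != 0)
    stop_param("static regime requires k = 0")
  if (regime == "exchange" && k == 0)
    stop_param("exchange regime requires k > 0")
  if (bleach_depth < 0 || bleach_depth > 1)
    stop_param("`bleach_depth` must lie in [0, 1]")
  if (length(time_min) < 2 || any(diff(time_min) <= 0))
    stop_param("`time_min` must be strictly increasing with a pre-bleach first point")
  if (n_per_category < 1) stop_param("`n_per_category` must be >= 1")

  t0 <- time_min[1]
  post <- time_min[-1] - t0
  n <- n_per_category

  # pool A: targeted + same-cell puncta exchange through one pool;
  # pool B: separate-cell puncta (nothing bleached there).
  f0_a <- c(rep(1 - bleach_depth, n), rep(1, n))
  fbar_a <- mean(f0_a)
  frac_at <- function(f0, fbar, tau) fbar + (f0 - fbar) * exp(-k * tau)

  cat_a <- c(rep("targeted", n), rep("same_cell", n))
  rows <- list()
  truth <- list()
  # pre-bleach row block: everything at labeled fraction 1
  add_block <- function(tp, cats, ids, frac) {
    data.frame(replicate = replicate, category = cats, roi_id = ids,
               time_min = tp, intensity = background + amplitude * frac)
  }
  ids_a <- c(seq_len(n), seq_len(n))
  rows[[1]] <- add_block(t0, cat_a, ids_a, rep(1, 2 * n))
  rows[[2]] <- add_block(t0, rep("separate_cell", n), seq_len(n), rep(1, n))
  rows[[3]] <- add_block(t0, rep("background", n), seq_len(n), rep(0, n))
  truth[[1]] <- data.frame(time_min = t0, category = c(cat_a, rep("separate_cell", n)),
                           roi_id = c(ids_a, seq_len(n)),
                           labeled_fraction = 1)
  for (i in seq_along(post)) {
    f_a <- frac_at(f0_a, fbar_a, post[i])
    tp <- time_min[i + 1]
    rows[[length(rows) + 1L]] <- add_block(tp, cat_a, ids_a, f_a)
    rows[[length(rows) + 1L]] <- add_block(tp, rep("separate_cell", n),
                                           seq_len(n), rep(1, n))
    rows[[length(rows) + 1L]] <- add_block(tp, rep("background", n),
                                           seq_len(n), rep(0, n))
    truth[[length(truth) + 1L]] <-
      data.frame(time_min = tp, category = c(cat_a, rep("separate_cell", n)),
                 roi_id = c(ids_a, seq_len(n)),
                 labeled_fraction = c(f_a, rep(1, n)))
  }
  data <- do.call(rbind, rows)
  data$intensity <- with_seed(seed, {
    if (noise_sd > 0) data$intensity + rnorm(nrow(data), 0, noise_sd)
    else data$intensity
  })
  data$intensity <- pmax(data$intensity, 0)
  structure(list(data = data, truth = do.call(rbind, truth),
                 regime = regime, k = k, bleach_depth = bleach_depth,
                 amplitude = amplitude, background = background,
                 seed = seed),
            class = "frap_series")
}

#' @export
print.frap_series <- function(x, ...) {
  cat(sprintf("frap_series: regime = %s, k = %g /min, depth = %g, %d time points\n",
              x$regime, x$k, x$bleach_depth, length(unique(x$data$time_min))))
  invisible(x)
}
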