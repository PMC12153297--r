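#' Cell mask from the time-averaged movie
#'
#' Thresholds the time average of all frames to exclude regions without
#' cells from detection.  The threshold is either an explicit intensity or
#' Otsu's method applied to the rescaled time average.
#'
#' @param movie a `movie` object.
#' @param method `"otsu"` or `"value"`.  Otsu is applied on a log scale:
#'   fluorescence time averages are typically trimodal (background, cell
#'   body, bright puncta) and a linear Otsu can latch onto the punctum
#'   mode instead of the cell outline.
#' @param value explicit threshold (required for `method = "value"`).
#' @return A logical matrix of the frame shape (class `cell_mask`).
#' @export
compute_cell_mask <- function(movie, method = c("otsu", "value"),
                              value = NULL) {
  stopifnot(inherits(movie, "movie"))
  method <- match.arg(method)
  avg <- apply(movie$frames, c(1, 2), mean)
  if (method == "value") {
    if (is.null(value)) stop_param("method = \"value\" requires `value`")
    thr <- value
  } else {
    lavg <- log1p(pmax(avg, 0))
    rng <- range(lavg)
    if (diff(rng) == 0)
      stop_param("time-averaged movie is constant; automatic thresholding is undefined")
    scaled <- (lavg - rng[1]) / diff(rng)
    thr_scaled <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    thr <- expm1(rng[1] + thr_scaled * diff(rng))
  }
  structure(avg >= thr, class = c("cell_mask", "matrix"))
}

# Scale-normalized Laplacian-of-Gaussian response, sign-flipped so bright
# blobs of scale ~ sigma give positive peaks.  Convolution via EBImage
# (FFT, circular boundary); kernel support 4 sigma.
log_response <- function(frame, sigma) {
  half <- max(2L, ceiling(4 * sigma))
  u <- seq(-half, half)
  g <- exp(-u^2 / (2 * sigma^2))
  g <- g / sum(g)
  # 1D second derivative of the Gaussian (unnormalized shape)
  g2 <- (u^2 / sigma^4 - 1 / sigma^2) * exp(-u^2 / (2 * sigma^2))
  g2 <- g2 - mean(g2) * 0  # keep shape; normalization below
  # separable LoG: G''(x) G(y) + G(x) G''(y), scale-normalized by sigma^2
  kx <- outer(g, g2)   # rows = y (Gaussian), cols = x (2nd derivative)
  ky <- outer(g2, g)
  kern <- -(kx + ky) * sigma^2
  kern <- kern - mean(kern)  # zero-mean: flat regions respond 0
  as.matrix(EBImage::filter2(EBImage::Image(frame), kern, boundary = "replicate"))
}

#' Detect diffraction-limited spots in one frame
#'
#' Applies a Laplacian-of-Gaussian blob filter and keeps local maxima of
#' the response whose underlying frame intensity exceeds
#' `mean + k_sd * sd` of the frame, with the statistics computed either
#' within the cell mask (default) or over the whole frame.  Detections
#' outside the mask are discarded.
#'
#' @param frame numeric matrix (one movie frame).
#' @param mask a [compute_cell_mask()] result, or `NULL` for no masking.
#' @param log_sigma LoG scale in px; match to the spot radius (~2 px for a
#'   diffraction-limited punctum at ~0.1 um/px).
#' @param k_sd threshold multiplier on the frame sd (default 1).
#' @param stats_in_mask compute the intensity statistics within the mask
#'   (default) or over the whole frame.
#' @return data.frame with `x`, `y` (px, pixel-level at this stage) and
#'   `response`; zero rows when nothing passes.  A zero-variance frame
#'   yields zero detections.
#' @export
detect_spots <- function(frame, mask = NULL, log_sigma = 2, k_sd = 1,
                         stats_in_mask = TRUE) {
  check_positive(log_sigma, "log_sigma")
  if (!all(is.finite(frame))) stop_param("frame contains non-finite values")
  if (!is.null(mask) && !all(dim(mask) == dim(frame)))
    stop_param("mask shape does not match frame shape")
  px <- if (!is.null(mask) && stats_in_mask) frame[mask] else as.vector(frame)
  if (length(px) < 2 || sd(px) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), response = numeric(0)))
  }
  thr <- mean(px) + k_sd * sd(px)
  resp <- log_response(frame, log_sigma)
  nr <- nrow(frame); nc <- ncol(frame)
  # strict local maxima over the 8-neighbourhood, excluding the 1-px border
  ok <- matrix(FALSE, nr, nc)
  core_i <- 2:(nr - 1); core_j <- 2:(nc - 1)
  m <- resp[core_i, core_j]
  is_max <- m > 0 &
    m >= resp[core_i - 1, core_j] & m >= resp[core_i + 1, core_j] &
    m >= resp[core_i, core_j - 1] & m >= resp[core_i, core_j + 1] &
    m >= resp[core_i - 1, core_j - 1] & m >= resp[core_i - 1, core_j + 1] &
    m >= resp[core_i + 1, core_j - 1] & m >= resp[core_i + 1, core_j + 1]
  ok[core_i, core_j] <- is_max
  ok <- ok & frame > thr
  if (!is.null(mask)) ok <- ok & mask
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), response = numeric(0)))
  out <- data.frame(x = as.numeric(idx[, 2]), y = as.numeric(idx[, 1]),
                    response = resp[idx])
  out[order(out$x, out$y), , drop = FALSE]
}

#' Sub-pixel localization by radial symmetry
#'
#' Refines a pixel-level detection to sub-pixel precision using the
#' radial-symmetry-center method: intensity gradients around a symmetric
#' spot all point through its center, so the center is the least-squares
#' point minimizing summed weighted distances to the gradient lines.
#' Closed-form, no fitting iterations.  Falls back to the intensity
#' centroid (with a warning) when the gradient system is singular, e.g. on
#' a flat window.
#'
#' @param frame numeric matrix.
#' @param x,y pixel-level detection coordinates (column, row).
#' @param window odd window size in px (default 7); clipped at frame
#'   borders.
#' @return list with refined `x`, `y` (guaranteed inside the window) and
#'   `method` (`"radial"` or `"centroid"`).
#' @export
refine_centroid <- function(frame, x, y, window = 7L) {
  if (window %% 2 == 0) stop_param("`window` must be odd")
  half <- (window - 1L) %/% 2L
  i0 <- max(1L, round(y) - half); i1 <- min(nrow(frame), round(y) + half)
  j0 <- max(1L, round(x) - half); j1 <- min(ncol(frame), round(x) + half)
  w <- frame[i0:i1, j0:j1, drop = FALSE]
  res <- radial_center(w)
  if (is.null(res)) {
    warning("flat or singular window; falling back to intensity centroid")
    tot <- sum(w)
    if (tot <= 0) {
      res <- c((ncol(w) + 1) / 2, (nrow(w) + 1) / 2)
    } else {
      res <- c(sum(col(w) * w) / tot, sum(row(w) * w) / tot)
    }
    method <- "centroid"
  } else {
    method <- "radial"
  }
  list(x = j0 - 1 + min(max(res[1], 1), ncol(w)),
       y = i0 - 1 + min(max(res[2], 1), nrow(w)),
       method = method)
}

# Radial-symmetry center of a window; returns c(x, y) in window pixel
# coordinates (1-based pixel centers) or NULL when singular.
radial_center <- function(w) {
  ny <- nrow(w); nx <- ncol(w)
  if (ny < 3 || nx < 3) return(NULL)
  # gradients on the dual (half-integer) lattice, 45-degree differences
  xm <- matrix(rep(seq_len(nx - 1) + 0.5, each = ny - 1), ny - 1, nx - 1)
  ym <- matrix(rep(seq_len(ny - 1) + 0.5, times = nx - 1), ny - 1, nx - 1)
  dIdu <- w[1:(ny - 1), 2:nx] - w[2:ny, 1:(nx - 1)]
  dIdv <- w[1:(ny - 1), 1:(nx - 1)] - w[2:ny, 2:nx]
  # 3x3 boxcar smoothing of the gradient fields
  sm <- function(m) {
    p <- rbind(m[1, ], m, m[nrow(m), ])
    p <- cbind(p[, 1], p, p[, ncol(p)])
    (p[1:nrow(m), 1:ncol(m)] + p[1:nrow(m), 2:(ncol(m) + 1)] + p[1:nrow(m), 3:(ncol(m) + 2)] +
     p[2:(nrow(m) + 1), 1:ncol(m)] + p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] + p[2:(nrow(m) + 1), 3:(ncol(m) + 2)] +
     p[3:(nrow(m) + 2), 1:ncol(m)] + p[3:(nrow(m) + 2), 2:(ncol(m) + 1)] + p[3:(nrow(m) + 2), 3:(ncol(m) + 2)]) / 9
  }
  du <- sm(dIdu); dv <- sm(dIdv)
  mag2 <- du^2 + dv^2
  if (sum(mag2) == 0) return(NULL)
  denom <- du - dv
  slope <- -(dv + du) / denom
  bad <- !is.finite(slope)
  slope[bad] <- 0  # weight zeroed below
  b <- ym - slope * xm
  # weights: gradient magnitude over distance to the magnitude centroid
  xc <- sum(xm * mag2) / sum(mag2)
  yc <- sum(ym * mag2) / sum(mag2)
  dc <- sqrt((xm - xc)^2 + (ym - yc)^2)
  dc[dc < 1e-6] <- 1e-6
  wgt <- mag2 / dc
  wgt[bad | denom == 0] <- 0
  wm <- wgt / (slope^2 + 1)
  sw <- sum(wm); smw <- sum(slope * wm); smmw <- sum(slope^2 * wm)
  sbw <- sum(b * wm); smbw <- sum(slope * b * wm)
  det <- smw^2 - smmw * sw
  if (!is.finite(det) || abs(det) < 1e-12) return(NULL)
  xcen <- (smbw * sw - smw * sbw) / det
  ycen <- (smbw * smw - smmw * sbw) / det
  if (!is.finite(xcen) || !is.finite(ycen)) return(NULL)
  c(xcen, ycen)
}

#' Detect and refine spots in every frame of a movie
#'
#' Convenience wrapper running [detect_spots()] then [refine_centroid()]
#' per frame.
#'
#' @inheritParams detect_spots
#' @param movie a `movie` object.
#' @param window refinement window in px.
#' @return data.frame with `frame`, `x`, `y` (sub-pixel px) and `response`.
#' @export
detect_movie <- function(movie, mask = NULL, log_sigma = 2, k_sd = 1,
                         stats_in_mask = TRUE, window = 7L) {
  stopifnot(inherits(movie, "movie"))
  n <- dim(movie$frames)[3]
  out <- vector("list", n)
  for (f in seq_len(n)) {
    fr <- movie$frames[, , f]
    det <- detect_spots(fr, mask, log_sigma = log_sigma, k_sd = k_sd,
                        stats_in_mask = stats_in_mask)
    if (nrow(det)) {
      for (k in seq_len(nrow(det))) {
        ref <- refine_centroid(fr, det$x[k], det$y[k], window = window)
        det$x[k] <- ref$x; det$y[k] <- ref$y
      }
      det$frame <- f
      out[[f]] <- det[, c("frame", "x", "y", "response")]
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      response = numeric(0))
  rownames(out) <- NULL
  out
}
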