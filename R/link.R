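# Exact solver for the rectangular assignment problem (Hungarian method,
# shortest-augmenting-path formulation, O(n^3)).  cost is an n x m matrix
# with n <= m; returns an integer vector a with a[i] = column assigned to
# row i.  Forbidden pairings are encoded by the caller as large costs.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  if (n == 0L) return(integer(0))
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)          # p[j+1] = row matched to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}

#' Link per-frame detections into tracks
#'
#' Frame-to-frame linking between consecutive frames only (no gap
#' closing).  For each frame pair, the assignment between active track
#' heads and new detections is the globally distance-minimizing matching
#' restricted to pairs within `search_radius`; unmatched detections start
#' new tracks and unmatched heads terminate.  Detections are sorted within
#' each frame before assignment, so results do not depend on input
#' ordering.
#'
#' @param detections data.frame with columns `frame`, `x`, `y` (px; any
#'   extra columns are carried along).
#' @param search_radius maximum link distance in px (default 3).
#' @return data.frame of the input rows plus a `track_id` column, ordered
#'   by (`track_id`, `frame`); every detection belongs to exactly one
#'   track and frames within a track are strictly consecutive.
#' @export
link_tracks <- function(detections, search_radius = 3) {
  check_columns(detections, c("frame", "x", "y"), "detections")
  check_positive(search_radius, "search_radius")
  if (nrow(detections) == 0) {
    detections$track_id <- integer(0)
    return(detections)
  }
  detections <- detections[order(detections$frame, detections$x, detections$y), ,
                           drop = FALSE]
  rownames(detections) <- NULL
  detections$track_id <- NA_integer_

  frames <- sort(unique(detections$frame))
  next_id <- 0L
  prev_rows <- integer(0)   # row indices of the previous frame's detections
  prev_frame <- NA_integer_
  BIG <- 1e9
  for (f in frames) {
    cur_rows <- which(detections$frame == f)
    linked <- rep(FALSE, length(cur_rows))
    if (length(prev_rows) && !is.na(prev_frame) && f == prev_frame + 1L) {
      px <- detections$x[prev_rows]; py <- detections$y[prev_rows]
      cx <- detections$x[cur_rows]; cy <- detections$y[cur_rows]
      dmat <- sqrt(outer(px, cx, "-")^2 + outer(py, cy, "-")^2)
      cost <- ifelse(dmat <= search_radius, dmat, BIG)
      transposed <- length(prev_rows) > length(cur_rows)
      a <- if (transposed) solve_assignment(t(cost)) else solve_assignment(cost)
      if (transposed) {
        for (j in seq_along(a)) {
          i <- a[j]
          if (dmat[i, j] <= search_radius) {
            detections$track_id[cur_rows[j]] <- detections$track_id[prev_rows[i]]
            linked[j] <- TRUE
          }
        }
      } else {
        for (i in seq_along(a)) {
          j <- a[i]
          if (dmat[i, j] <= search_radius) {
            detections$track_id[cur_rows[j]] <- detections$track_id[prev_rows[i]]
            linked[j] <- TRUE
          }
        }
      }
    }
    for (j in which(!linked)) {
      next_id <- next_id + 1L
      detections$track_id[cur_rows[j]] <- next_id
    }
    prev_rows <- cur_rows
    prev_frame <- f
  }
  detections <- detections[order(detections$track_id, detections$frame), ,
                           drop = FALSE]
  rownames(detections) <- NULL
  detections
}

#' Track a movie end to end
#'
#' Mask, detect, refine and link in one call; attaches physical
#' coordinates in micrometers.
#'
#' @param movie a `movie` object.
#' @param mask optional precomputed [compute_cell_mask()]; `NULL` computes
#'   one with Otsu (set `mask = FALSE` to skip masking).
#' @inheritParams detect_spots
#' @inheritParams link_tracks
#' @param window refinement window (px).
#' @return data.frame with `track_id`, `frame`, `x_px`, `y_px`, `x_um`,
#'   `y_um`.
#' @export
track_movie <- function(movie, mask = NULL, log_sigma = 2, k_sd = 1,
                        search_radius = 3, window = 7L,
                        stats_in_mask = TRUE) {
  stopifnot(inherits(movie, "movie"))
  if (is.null(mask)) mask <- compute_cell_mask(movie)
  if (identical(mask, FALSE)) mask <- NULL
  det <- detect_movie(movie, mask, log_sigma = log_sigma, k_sd = k_sd,
                      stats_in_mask = stats_in_mask, window = window)
  tr <- link_tracks(det, search_radius = search_radius)
  data.frame(track_id = tr$track_id, frame = tr$frame,
             x_px = tr$x, y_px = tr$y,
             x_um = px_to_um(tr$x, movie$pixel_size_um),
             y_um = px_to_um(tr$y, movie$pixel_size_um))
}
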