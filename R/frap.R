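#' Background-correct a FRAP intensity table
#'
#' Subtracts, per replicate and time point, the mean of the field
#' background ROIs from every punctum intensity.  Negative corrected
#' values are clamped to zero and counted in the `n_clamped` attribute.
#'
#' @param data data.frame with columns `replicate`, `category`
#'   (`targeted`, `same_cell`, `separate_cell`, `background`), `roi_id`,
#'   `time_min`, `intensity` (a [simulate_frap()] `$data`, or read from
#'   CSV).
#' @return The punctum rows (background rows removed) with `intensity`
#'   corrected; attribute `n_clamped` gives the number of clamped values.
#' @export
subtract_background <- function(data) {
  check_columns(data, c("replicate", "category", "roi_id", "time_min",
                        "intensity"), "FRAP table")
  bg <- data[data$category == "background", , drop = FALSE]
  px <- data[data$category != "background", , drop = FALSE]
  if (nrow(bg) == 0) stop_param("no background ROIs in the table")
  key <- function(d) paste(d$replicate, d$time_min, sep = "\r")
  bg_mean <- tapply(bg$intensity, key(bg), mean)
  missing <- setdiff(unique(key(px)), names(bg_mean))
  if (length(missing))
    stop_param("background ROIs missing for %d replicate/time combination(s)",
               length(missing))
  corrected <- px$intensity - as.numeric(bg_mean[key(px)])
  n_clamped <- sum(corrected < 0)
  px$intensity <- pmax(corrected, 0)
  rownames(px) <- NULL
  attr(px, "n_clamped") <- n_clamped
  px
}

#' Percent-of-original fluorescence per ROI category
#'
#' For each replicate and category, averages the ROI intensities at each
#' time point and expresses the average as a percentage of that
#' category's pre-bleach (first time point) average; replicate means are
#' then pooled (mean and sd across replicates).  An alternative mode
#' normalizes each ROI individually before averaging.
#'
#' @param corrected background-corrected table from
#'   [subtract_background()].
#' @param mode `"average_then_normalize"` (default) or
#'   `"normalize_then_average"`.
#' @return A `frap_summary`: data.frame with `category`, `time_min`,
#'   `percent` (mean over replicates) and `sd` (across replicates; 0 with
#'   a single replicate).  The pre-bleach percent is 100 by construction.
#' @export
percent_of_original <- function(corrected,
                                mode = c("average_then_normalize",
                                         "normalize_then_average")) {
  mode <- match.arg(mode)
  check_columns(corrected, c("replicate", "category", "roi_id", "time_min",
                             "intensity"), "corrected FRAP table")
  t0 <- min(corrected$time_min)
  out <- list()
  for (rep_id in unique(corrected$replicate)) {
    d <- corrected[corrected$replicate == rep_id, , drop = FALSE]
    for (cat in unique(d$category)) {
      dc <- d[d$category == cat, , drop = FALSE]
      if (mode == "average_then_normalize") {
        m <- tapply(dc$intensity, dc$time_min, mean)
        pre <- m[[as.character(t0)]]
        if (is.null(pre) || !is.finite(pre) || pre <= 0)
          stop_param("pre-bleach mean for category '%s' is zero or missing", cat)
        pct <- 100 * m / pre
        out[[length(out) + 1L]] <-
          data.frame(replicate = rep_id, category = cat,
                     time_min = as.numeric(names(m)), percent = as.numeric(pct))
      } else {
        pre <- dc$intensity[dc$time_min == t0][match(dc$roi_id, dc$roi_id[dc$time_min == t0])]
        if (any(!is.finite(pre)) || any(pre <= 0))
          stop_param("zero pre-bleach intensity in category '%s'", cat)
        pct_roi <- 100 * dc$intensity / pre
        m <- tapply(pct_roi, dc$time_min, mean)
        out[[length(out) + 1L]] <-
          data.frame(replicate = rep_id, category = cat,
                     time_min = as.numeric(names(m)), percent = as.numeric(m))
      }
    }
  }
  per_rep <- do.call(rbind, out)
  agg_mean <- aggregate(percent ~ category + time_min, per_rep, mean)
  agg_sd <- aggregate(percent ~ category + time_min, per_rep,
                      function(v) if (length(v) > 1) sd(v) else 0)
  res <- merge(agg_mean, agg_sd, by = c("category", "time_min"),
               suffixes = c("", "_sd"))
  names(res)[names(res) == "percent_sd"] <- "sd"
  res <- res[order(res$category, res$time_min), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("frap_summary", "data.frame")
  res
}

#' Net recovery score per category
#'
#' Difference between the last and the first post-bleach percent of
#' original fluorescence; positive for the targeted category indicates
#' recovery (subunit exchange), near zero indicates a static complex.
#'
#' @param summary a [percent_of_original()] `frap_summary`.
#' @return named numeric vector, one score per category.
#' @export
recovery_score <- function(summary) {
  stopifnot(inherits(summary, "frap_summary") || is.data.frame(summary))
  check_columns(summary, c("category", "time_min", "percent"), "FRAP summary")
  t0 <- min(summary$time_min)
  post <- summary[summary$time_min > t0, , drop = FALSE]
  if (length(unique(post$time_min)) < 2)
    stop_param("recovery score needs >= 2 post-bleach time points")
  vapply(split(post, post$category), function(d) {
    d <- d[order(d$time_min), , drop = FALSE]
    d$percent[nrow(d)] - d$percent[1]
  }, numeric(1))
}

#' @importFrom stats aggregate
NULL
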