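#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rpois sd var ecdf t.test dist
#' @importFrom utils read.csv write.csv head tail
NULL

# Run code under a fixed RNG seed without disturbing the caller's stream.
# All stochastic operations in the package funnel through this so that a
# seed argument makes them bitwise-reproducible.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_param("`%s` must be a single positive finite number", name)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop_param("`%s` must be a single non-negative finite number", name)
  invisible(x)
}

# Validate a data.frame read from CSV against a required schema, reporting
# the file and every missing column by name.
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_param("%s is missing required column(s): %s",
               what, paste(missing, collapse = ", "))
  invisible(df)
}

# Convert between continuous pixel coordinates and micrometers.  Pixel i
# (1-based) has its center at coordinate i; physical origin is the outer
# edge of the first pixel, so x_px = x_um / pixel_size + 0.5.
um_to_px <- function(x_um, pixel_size_um) x_um / pixel_size_um + 0.5
px_to_um <- function(x_px, pixel_size_um) (x_px - 0.5) * pixel_size_um
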