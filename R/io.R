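#' Write a movie as a multi-frame TIFF
#'
#' Intensities are stored as 32-bit floats scaled to `[0, 1]` by
#' `scale_max` so they round-trip losslessly through [read_movie()].
#'
#' @param movie a `movie` object.
#' @param path output file.
#' @param scale_max full-scale intensity (default: the movie maximum).
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, scale_max = NULL) {
  stopifnot(inherits(movie, "movie"))
  scale_max <- scale_max %||% max(movie$frames)
  if (scale_max <= 0) scale_max <- 1
  n <- dim(movie$frames)[3]
  frames <- lapply(seq_len(n), function(f) {
    pmax(movie$frames[, , f], 0) / scale_max
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a multi-frame TIFF as a movie
#'
#' @param path TIFF file.
#' @param pixel_size_um pixel size in um/px (required: physical units are
#'   never guessed from file metadata).
#' @param dt frame interval in seconds (required).
#' @param scale_max intensity full scale used at write time (default 1).
#' @return A `movie` object.
#' @export
read_movie <- function(path, pixel_size_um, dt, scale_max = 1) {
  check_positive(pixel_size_um, "pixel_size_um")
  check_positive(dt, "dt")
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) if (length(dim(f)) == 3) f[, , 1] else f)
  arr <- array(0, dim = c(nrow(frames[[1]]), ncol(frames[[1]]), length(frames)))
  for (f in seq_along(frames)) arr[, , f] <- frames[[f]] * scale_max
  new_movie(arr, pixel_size_um, dt)
}

#' Write per-cell puncta and cell-end tables as CSV
#'
#' Schemas match the import side of the spatial pipeline: puncta with
#' `cell_id`, `strain`, `x_um`, `y_um`, `z_um`; ends with `cell_id`,
#' `end_index`, `x_um`, `y_um`.
#'
#' @param cells list of `cell_record`s.
#' @param puncta_path,ends_path output files.
#' @return invisibly, a list with both data.frames.
#' @export
write_cells <- function(cells, puncta_path, ends_path) {
  puncta <- do.call(rbind, lapply(cells, function(cl)
    data.frame(cell_id = cl$cell_id, strain = cl$strain, cl$puncta)))
  ends <- do.call(rbind, lapply(cells, function(cl)
    data.frame(cell_id = cl$cell_id, cl$ends)))
  write.csv(puncta, puncta_path, row.names = FALSE)
  write.csv(ends, ends_path, row.names = FALSE)
  invisible(list(puncta = puncta, ends = ends))
}

#' Read puncta and cell-end CSVs into cell records
#'
#' @param puncta_path CSV with `cell_id`, `x_um`, `y_um`, `z_um` and
#'   optionally `strain`.
#' @param ends_path CSV with `cell_id`, `end_index`, `x_um`, `y_um`.
#' @return list of `cell_record`s; cells missing either end raise an
#'   error naming the cell.
#' @export
read_cells <- function(puncta_path, ends_path) {
  puncta <- read.csv(puncta_path)
  ends <- read.csv(ends_path)
  check_columns(puncta, c("cell_id", "x_um", "y_um", "z_um"),
                basename(puncta_path))
  check_columns(ends, c("cell_id", "end_index", "x_um", "y_um"),
                basename(ends_path))
  if (is.null(puncta$strain)) puncta$strain <- "unspecified"
  lapply(unique(puncta$cell_id), function(id) {
    p <- puncta[puncta$cell_id == id, , drop = FALSE]
    e <- ends[ends$cell_id == id, , drop = FALSE]
    if (nrow(e) != 2)
      stop_param("cell '%s' must have exactly 2 end positions, found %d",
                 id, nrow(e))
    structure(list(cell_id = id, strain = p$strain[1],
                   puncta = p[, c("x_um", "y_um", "z_um")],
                   ends = e[, c("end_index", "x_um", "y_um")]),
              class = "cell_record")
  })
}
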