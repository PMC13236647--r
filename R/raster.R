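#' Lightweight planar raster container
#'
#' A minimal in-memory grid used for class rasters, reflectance bands and
#' density surfaces: a numeric matrix plus an origin (lower-left corner, in
#' meters), a square cell size, and a nodata code. Row 1 of the matrix is
#' the northernmost row, matching the ESRI ASCII grid layout.
#'
#' @param values Numeric or integer matrix; row 1 is the top (north) row.
#' @param origin Length-2 numeric, the (x, y) of the lower-left corner in
#'   meters.
#' @param cell_size Cell edge length in meters.
#' @param nodata Value marking missing cells (default -9999).
#' @return A `gm_raster` object.
#' @export
#' @examples
#' r <- gm_raster(matrix(1:6, 2, 3), origin = c(0, 0), cell_size = 10)
#' raster_cells(r)
gm_raster <- function(values, origin = c(0, 0), cell_size = 1, nodata = -9999) {
  if (!is.matrix(values)) abort("`values` must be a matrix.")
  check_number(cell_size, "cell_size", positive = TRUE)
  if (length(origin) != 2 || !is.numeric(origin)) {
    abort("`origin` must be a numeric vector of length 2.")
  }
  structure(
    list(
      values = values,
      origin = as.numeric(origin),
      cell_size = as.numeric(cell_size),
      nodata = nodata
    ),
    class = "gm_raster"
  )
}

#' @export
print.gm_raster <- function(x, ...) {
  cat(sprintf(
    "<gm_raster> %d x %d cells, cell size %g m, origin (%g, %g)\n",
    nrow(x$values), ncol(x$values), x$cell_size, x$origin[1], x$origin[2]
  ))
  invisible(x)
}

#' @export
dim.gm_raster <- function(x) dim(x$values)

#' Cell-center coordinates and values of a raster
#'
#' @param r A [gm_raster()].
#' @param drop_nodata Drop cells equal to the nodata code?
#' @return A tibble with columns `x`, `y`, `value` (one row per cell).
#' @export
raster_cells <- function(r, drop_nodata = FALSE) {
  stopifnot(inherits(r, "gm_raster"))
  nr <- nrow(r$values)
  nc <- ncol(r$values)
  cs <- r$cell_size
  # column j -> x, row i (from top) -> y
  xs <- r$origin[1] + (seq_len(nc) - 0.5) * cs
  ys <- r$origin[2] + (nr - seq_len(nr) + 0.5) * cs
  out <- tibble(
    x = rep(xs, each = nr),
    y = rep(ys, times = nc),
    value = as.vector(r$values)
  )
  if (drop_nodata) out <- out[out$value != r$nodata, , drop = FALSE]
  out
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster exchange format: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of cell
#' values from north to south.
#'
#' @param path File path.
#' @param r A [gm_raster()].
#' @param digits Significant digits written for numeric grids.
#' @return `read_ascii_grid()` returns a `gm_raster`;
#'   `write_ascii_grid()` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- lapply(strsplit(trimws(hdr), "\\s+"), function(p) {
    setNames(as.numeric(p[2]), tolower(p[1]))
  })
  kv <- unlist(kv)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = kv[["nrows"]], ncol = kv[["ncols"]], byrow = TRUE)
  gm_raster(
    m,
    origin = c(kv[["xllcorner"]], kv[["yllcorner"]]),
    cell_size = kv[["cellsize"]],
    nodata = kv[["nodata_value"]]
  )
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(r, path, digits = 10) {
  stopifnot(inherits(r, "gm_raster"))
  hdr <- c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.10g", r$origin[1]),
    sprintf("yllcorner %.10g", r$origin[2]),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %g", r$nodata)
  )
  body <- apply(r$values, 1, function(row) {
    paste(formatC(row, digits = digits, format = "g"), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @export
autoplot.gm_raster <- function(object, ...) {
  cells <- raster_cells(object, drop_nodata = TRUE)
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}
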