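#' Gridded surface raster
#'
#' Minimal single-band raster container used for DSM/DTM/CHM, intensity and
#' thermal surfaces. Values are stored as a matrix with row 1 at the top
#' (northern) edge; `origin` is the field coordinate of the top-left corner.
#' Missing cells are encoded as `NA`.
#'
#' @param values numeric matrix of cell values (row 1 = top)
#' @param cell_size cell edge length in metres (> 0)
#' @param origin numeric length-2, field coordinates (x, y) of the top-left
#'   raster corner
#' @return an object of class `surface_raster`
#' @export
surface_raster <- function(values, cell_size = 0.03, origin = c(0, 0)) {
  stopifnot(is.matrix(values), is.numeric(cell_size), cell_size > 0,
            length(origin) == 2)
  structure(list(values = values, cell_size = cell_size,
                 origin = as.numeric(origin)),
            class = "surface_raster")
}

#' @export
print.surface_raster <- function(x, ...) {
  cat(sprintf("<surface_raster> %d x %d cells @ %.3g m, origin (%.2f, %.2f), %d nodata\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2], sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.surface_raster <- function(x) dim(x$values)

# point coordinates -> (row, col) cell indices; points on the shared edge of
# two cells belong to the cell with the larger index (half-open cells)
xy_to_rc <- function(r, x, y) {
  col <- floor((x - r$origin[1]) / r$cell_size) + 1L
  row <- floor((r$origin[2] - y) / r$cell_size) + 1L
  cbind(row = as.integer(row), col = as.integer(col))
}

# cell centres of a raster, as a data.frame aligned with as.vector(values)
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- rep(seq_len(nc), each = nr)
  row <- rep(seq_len(nr), times = nc)
  data.frame(x = r$origin[1] + (col - 0.5) * r$cell_size,
             y = r$origin[2] - (row - 0.5) * r$cell_size)
}

rasters_aligned <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Write / read a surface raster as plain text
#'
#' The raster matrix goes to a headerless CSV; grid metadata (cell size,
#' origin) goes to a JSON side-car named `<path>.json`.
#'
#' @param r a `surface_raster`
#' @param path CSV file path
#' @return `path`, invisibly (`write_surface_csv`); a `surface_raster`
#'   (`read_surface_csv`)
#' @export
write_surface_csv <- function(r, path) {
  utils::write.table(r$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(cell_size = r$cell_size, origin = r$origin),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surface_csv
#' @export
read_surface_csv <- function(path) {
  v <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(v) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  surface_raster(v, cell_size = meta$cell_size, origin = meta$origin)
}
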