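#' Statistical outlier removal for point clouds
#'
#' Computes each point's mean distance to its `k_neighbors` nearest
#' neighbours and removes points whose mean distance exceeds the global mean
#' plus `sigma_mult` standard deviations — the classic filter for isolated
#' returns in low-density regions. At most `cap_fraction` of the cloud is
#' ever removed (the worst offenders are dropped first).
#'
#' @param points data.frame with x, y, z columns (any extra columns kept)
#' @param k_neighbors number of neighbours (>= 1)
#' @param sigma_mult threshold multiplier on the distance sd
#' @param cap_fraction maximum fraction of points that may be removed
#' @return the filtered point data.frame
#' @export
remove_outliers <- function(points, k_neighbors = 8, sigma_mult = 3,
                            cap_fraction = 0.1) {
  if (k_neighbors < 1) stop("k_neighbors must be >= 1")
  n <- nrow(points)
  if (n < k_neighbors + 1) stop("need at least k_neighbors + 1 points")
  if (!is.finite(sigma_mult)) return(points)
  xyz <- as.matrix(points[, c("x", "y", "z")])
  kd <- FNN::get.knn(xyz, k = k_neighbors)
  md <- rowMeans(kd$nn.dist)
  thr <- mean(md) + sigma_mult * sd(md)
  out <- which(md > thr)
  cap <- floor(cap_fraction * n)
  if (length(out) > cap) out <- out[order(md[out], decreasing = TRUE)][seq_len(cap)]
  if (length(out)) points[-out, , drop = FALSE] else points
}

# shared gridding: snap the grid to `origin` (top-left) if given, else to the
# point bounding box; returns raster geometry + each point's cell index
point_grid <- function(points, cell_size, origin = NULL, dims = NULL) {
  if (is.null(origin)) {
    origin <- c(floor(min(points$x) / cell_size) * cell_size,
                ceiling(max(points$y) / cell_size) * cell_size)
  }
  if (is.null(dims)) {
    nc <- max(1L, ceiling((max(points$x) - origin[1]) / cell_size - 1e-9))
    nr <- max(1L, ceiling((origin[2] - min(points$y)) / cell_size - 1e-9))
    dims <- c(nr, nc)
  }
  tmp <- surface_raster(matrix(NA_real_, dims[1], dims[2]), cell_size, origin)
  rc <- xy_to_rc(tmp, points$x, points$y)
  keep <- rc[, 1] >= 1 & rc[, 1] <= dims[1] & rc[, 2] >= 1 & rc[, 2] <= dims[2]
  list(raster = tmp, lin = rc[keep, 1] + (rc[keep, 2] - 1L) * dims[1],
       keep = keep)
}

#' Rasterize non-ground points into a digital surface model
#'
#' Each cell takes the maximum z of the non-ground points it contains
#' (canopy top); cells without points are nodata.
#'
#' @param points point data.frame; rows with `ground == TRUE` are dropped if
#'   a `ground` column is present
#' @param cell_size cell size, m (default 0.03 to match the imagery grid)
#' @param origin optional top-left grid origin for alignment with imagery
#' @param dims optional c(nrows, ncols)
#' @return a `surface_raster`
#' @export
rasterize_dsm <- function(points, cell_size = 0.03, origin = NULL, dims = NULL) {
  if (cell_size <= 0) stop("cell_size must be > 0")
  if ("ground" %in% names(points)) points <- points[!points$ground, , drop = FALSE]
  g_all <- point_grid_or_empty(points, cell_size, origin, dims,
                               "no non-ground points: DSM is all nodata")
  if (is.null(g_all)) return(empty_like(cell_size, origin, dims))
  g <- g_all
  r <- g$raster
  z <- points$z[g$keep]
  agg <- tapply(z, g$lin, max)
  r$values[as.integer(names(agg))] <- as.numeric(agg)
  r
}

point_grid_or_empty <- function(points, cell_size, origin, dims, msg) {
  if (nrow(points) == 0) { warning(msg); return(NULL) }
  point_grid(points, cell_size, origin, dims)
}

empty_like <- function(cell_size, origin, dims) {
  surface_raster(matrix(NA_real_, dims[1] %||% 1, dims[2] %||% 1),
                 cell_size, origin %||% c(0, 0))
}

#' Rasterize ground points into a digital terrain model
#'
#' Cells containing ground points take their minimum z (the lowest return
#' best approximates bare earth). Void cells are filled by linear
#' interpolation over the Delaunay triangulation of the ground points (the
#' TIN method); cells outside the convex hull take the value of the nearest
#' ground point.
#'
#' @param points point data.frame; rows with `ground == FALSE` are dropped
#'   if a `ground` column is present
#' @inheritParams rasterize_dsm
#' @return a `surface_raster` with no nodata cells
#' @export
rasterize_dtm <- function(points, cell_size = 0.03, origin = NULL, dims = NULL) {
  if (cell_size <= 0) stop("cell_size must be > 0")
  if ("ground" %in% names(points)) points <- points[points$ground, , drop = FALSE]
  if (nrow(points) < 3) stop("need at least 3 ground points")
  xy <- cbind(points$x, points$y)
  if (qr(sweep(xy, 2, colMeans(xy)))$rank < 2)
    stop("ground points are collinear; TIN interpolation is undefined")
  g <- point_grid(points, cell_size, origin, dims)
  r <- g$raster
  z <- points$z[g$keep]
  agg <- tapply(z, g$lin, min)
  r$values[as.integer(names(agg))] <- as.numeric(agg)
  void <- which(is.na(r$values))
  if (length(void)) {
    cc <- cell_centers(r)
    # deduplicate planimetric locations (keep the lowest return) for the TIN
    key <- paste(round(points$x, 9), round(points$y, 9))
    o <- order(key, points$z)
    first <- !duplicated(key[o])
    px <- points$x[o][first]; py <- points$y[o][first]; pz <- points$z[o][first]
    ti <- interp::interpp(px, py, pz, xo = cc$x[void], yo = cc$y[void])
    fill <- ti$z
    outside <- is.na(fill)
    if (any(outside)) {
      nn <- FNN::get.knnx(cbind(px, py),
                          cbind(cc$x[void][outside], cc$y[void][outside]), k = 1)
      fill[outside] <- pz[nn$nn.index[, 1]]
    }
    r$values[void] <- fill
  }
  r
}

#' Canopy height model
#'
#' CHM = DSM - DTM on aligned grids; negative differences are clipped to
#' zero and nodata propagates from either input.
#'
#' @param dsm,dtm aligned `surface_raster`s
#' @return a `surface_raster`
#' @export
canopy_height <- function(dsm, dtm) {
  if (!rasters_aligned(dsm, dtm)) stop("DSM and DTM grids do not match")
  v <- pmax(dsm$values - dtm$values, 0)
  surface_raster(v, dsm$cell_size, dsm$origin)
}

#' Rasterize LiDAR intensity
#'
#' Like the DSM, but each cell records the intensity attribute of its
#' highest non-ground point (`rule = "max_height"`, the default) or the
#' maximum intensity in the cell (`rule = "max_intensity"`).
#'
#' @inheritParams rasterize_dsm
#' @param rule which point's intensity a cell takes
#' @return a `surface_raster`
#' @export
rasterize_intensity <- function(points, cell_size = 0.03, origin = NULL,
                                dims = NULL,
                                rule = c("max_height", "max_intensity")) {
  rule <- match.arg(rule)
  if (cell_size <= 0) stop("cell_size must be > 0")
  if ("ground" %in% names(points)) points <- points[!points$ground, , drop = FALSE]
  g <- point_grid_or_empty(points, cell_size, origin, dims,
                           "no non-ground points: intensity raster is all nodata")
  if (is.null(g)) return(empty_like(cell_size, origin, dims))
  r <- g$raster
  key <- if (rule == "max_height") points$z[g$keep] else points$intensity[g$keep]
  o <- order(g$lin, key)                     # last within each cell = max key
  lin_o <- g$lin[o]
  last <- !duplicated(lin_o, fromLast = TRUE)
  r$values[lin_o[last]] <- points$intensity[g$keep][o][last]
  r
}

#' Full point-cloud-to-surfaces workflow
#'
#' Outlier filter, DSM, DTM and CHM plus the intensity raster on a shared
#' grid (snapped to `origin` when given so LiDAR surfaces align with the
#' imagery without resampling).
#'
#' @param points classified point data.frame (`ground` logical column)
#' @inheritParams rasterize_dsm
#' @param k_neighbors,sigma_mult see [remove_outliers()]
#' @return list with `dsm`, `dtm`, `chm`, `intensity` rasters
#' @export
lidar_surfaces <- function(points, cell_size = 0.03, origin = NULL, dims = NULL,
                           k_neighbors = 8, sigma_mult = 3) {
  pts <- remove_outliers(points, k_neighbors, sigma_mult)
  dsm <- rasterize_dsm(pts, cell_size, origin, dims)
  if (is.null(dims)) dims <- dim(dsm$values)
  if (is.null(origin)) origin <- dsm$origin
  dtm <- rasterize_dtm(pts, cell_size, origin, dims)
  list(dsm = dsm, dtm = dtm, chm = canopy_height(dsm, dtm),
       intensity = rasterize_intensity(pts, cell_size, origin, dims))
}
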