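#' Pixel window covering a plot polygon
#'
#' Returns the axis-aligned pixel window (0-based half-open in concept,
#' returned as 1-based inclusive index ranges) covering the polygon plus a
#' margin, clipped at the raster edge.
#'
#' @param raster a `surface_raster` defining the grid
#' @param polygon one row of a `plot_design` (columns xmin/xmax/ymin/ymax)
#' @param margin margin in pixels added on every side
#' @return list with integer vectors `rows` and `cols`
#' @export
polygon_window <- function(raster, polygon, margin = 0) {
  cs <- raster$cell_size; x0 <- raster$origin[1]; y0 <- raster$origin[2]
  eps <- 1e-9
  c_lo <- floor((polygon$xmin - x0) / cs + eps) + 1L
  c_hi <- ceiling((polygon$xmax - x0) / cs - eps)
  r_lo <- floor((y0 - polygon$ymax) / cs + eps) + 1L
  r_hi <- ceiling((y0 - polygon$ymin) / cs - eps)
  c_lo <- c_lo - margin; c_hi <- c_hi + margin
  r_lo <- r_lo - margin; r_hi <- r_hi + margin
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  if (c_hi < 1 || r_hi < 1 || c_lo > nc || r_lo > nr)
    stop("polygon does not overlap the raster extent")
  list(rows = seq(max(1L, r_lo), min(nr, r_hi)),
       cols = seq(max(1L, c_lo), min(nc, c_hi)))
}

#' Extract a plot chip from a raster
#'
#' @inheritParams polygon_window
#' @return list with `values` (matrix) and the `rows`/`cols` window indices
#' @export
extract_chip <- function(raster, polygon, margin = 0) {
  w <- polygon_window(raster, polygon, margin)
  list(values = raster$values[w$rows, w$cols, drop = FALSE],
       rows = w$rows, cols = w$cols)
}

#' All modality chips for one plot
#'
#' @param scene a `field_scene`
#' @param plot_id plot identifier
#' @param margin window margin in pixels
#' @return list with `hyper` (rows x cols x bands), `height`, `intensity`,
#'   `thermal` matrices, `wavelengths`, and the pixel window
#' @export
chip_set <- function(scene, plot_id, margin = 5) {
  i <- match(plot_id, scene$plots$plot_id)
  if (is.na(i)) stop("unknown plot_id: ", plot_id)
  grid <- scene_raster(scene, "height")
  w <- polygon_window(grid, scene$plots[i, ], margin = margin)
  list(hyper = scene$hyperspectral[w$rows, w$cols, , drop = FALSE],
       height = scene$height[w$rows, w$cols, drop = FALSE],
       intensity = scene$intensity[w$rows, w$cols, drop = FALSE],
       thermal = scene$thermal[w$rows, w$cols, drop = FALSE],
       wavelengths = scene$wavelengths, rows = w$rows, cols = w$cols)
}

# k-means++ seeding (Arthur & Vassilvitskii): subsequent centers drawn with
# probability proportional to the squared distance to the nearest chosen one
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) idx <- sample.int(n, 1)
    else idx <- sample.int(n, 1, prob = d2)
    centers[j + 1, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j + 1, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

#' Segment vegetation pixels of a multimodal plot chip
#'
#' Clusters per-pixel feature vectors (all spectral bands plus height,
#' intensity and thermal, each z-scored across the chip) with k-means using
#' k-means++ initialization. The cluster whose pixels have the higher mean
#' raw NIR reflectance (750-1000 nm) is labelled vegetation, so the mask is
#' invariant to cluster indexing. A degenerate chip (all pixels identical)
#' is labelled entirely vegetation with a warning.
#'
#' @param chips a chip list from [chip_set()] (or any list with `hyper`,
#'   `height`, `intensity`, `thermal`, `wavelengths`)
#' @param k number of clusters (2 = vegetation / non-vegetation)
#' @param seed integer seed (k-means++ seeding is stochastic)
#' @param n_restarts k-means++ restarts; the solution with the smallest
#'   total within-cluster sum of squares wins (guards against bad seeds)
#' @return logical matrix, TRUE = vegetation
#' @export
segment_vegetation <- function(chips, k = 2, seed = 1, n_restarts = 5) {
  dm <- dim(chips$hyper)
  npix <- dm[1] * dm[2]
  if (npix < k) stop("chip has fewer pixels than clusters")
  feats <- cbind(matrix(chips$hyper, npix, dm[3]),
                 as.vector(chips$height), as.vector(chips$intensity),
                 as.vector(chips$thermal))
  mu <- colMeans(feats); sdv <- apply(feats, 2, sd)
  z <- sweep(feats, 2, mu)
  pos <- sdv > 0
  z[, pos] <- sweep(z[, pos, drop = FALSE], 2, sdv[pos], "/")
  if (!any(pos)) {
    warning("degenerate chip: all pixels identical; labelling all vegetation")
    return(matrix(TRUE, dm[1], dm[2]))
  }
  set.seed(substream_seed(seed, "segment"))
  km <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- kmeanspp_centers(z, k)
    cand <- suppressWarnings(stats::kmeans(z, centers = centers,
                                           iter.max = 100,
                                           algorithm = "Lloyd"))
    if (is.null(km) || cand$tot.withinss < km$tot.withinss) km <- cand
  }
  nir <- which(chips$wavelengths >= 750)
  nir_mean <- vapply(seq_len(k), function(cl) {
    px <- km$cluster == cl
    if (!any(px)) return(-Inf)
    mean(matrix(chips$hyper, npix, dm[3])[px, nir, drop = FALSE])
  }, numeric(1))
  matrix(km$cluster == which.max(nir_mean), dm[1], dm[2])
}

#' Mean of a chip band over a vegetation mask
#'
#' @param chip_band numeric matrix (one band of a chip)
#' @param mask logical matrix of the same shape
#' @return scalar mean over masked, non-missing pixels
#' @export
masked_mean <- function(chip_band, mask) {
  stopifnot(identical(dim(chip_band), dim(mask)))
  if (!any(mask)) stop("empty vegetation mask")
  mean(chip_band[mask], na.rm = TRUE)
}

#' Segment every plot of a scene and assemble the plot-wise band means
#'
#' Runs [segment_vegetation()] on each plot chip (restricted to the polygon
#' interior as a validity mask), then computes the plot-wise mean of every
#' spectral band and of the height, intensity and thermal rasters over the
#' vegetation mask. The mean table is the input to NDSI screening and to the
#' handcrafted feature library.
#'
#' @param scene a `field_scene`
#' @param margin chip window margin in pixels
#' @param seed integer seed for the per-plot segmentations
#' @param use_truth_mask use the generator's ground-truth masks instead of
#'   running k-means (useful for isolating downstream stages)
#' @param drop_band optional index of one spectral band to exclude from the
#'   band-mean table (e.g. to work with a 269-band set from a 270-band cube)
#' @return list of class `plot_prep`: `masks` (per plot, over the window),
#'   `windows`, `margin`, `band_stack` (list with matrix `M`, numeric
#'   `wavelengths` per spectral column, character `labels`), `accuracy`
#'   (per-plot pixel agreement with the truth masks), plus the design and
#'   phenotypes carried through
#' @export
prep_plots <- function(scene, margin = 5, seed = 1, use_truth_mask = FALSE,
                       drop_band = NULL) {
  d <- scene$plots
  n <- nrow(d)
  nb <- length(scene$wavelengths)
  keep <- setdiff(seq_len(nb), drop_band)
  grid <- scene_raster(scene, "height")
  masks <- vector("list", n); windows <- vector("list", n)
  acc <- numeric(n)
  M <- matrix(NA_real_, n, length(keep) + 3)
  for (i in seq_len(n)) {
    cs <- chip_set(scene, d$plot_id[i], margin = margin)
    w <- list(rows = cs$rows, cols = cs$cols)
    inside <- polygon_window(grid, d[i, ], margin = 0)
    valid <- matrix(FALSE, length(cs$rows), length(cs$cols))
    valid[match(inside$rows, cs$rows), match(inside$cols, cs$cols)] <- TRUE
    truth <- truth_mask(scene, d$plot_id[i], margin = margin)
    if (use_truth_mask) mask <- truth
    else mask <- segment_vegetation(cs, seed = seed + i)
    acc[i] <- mean(mask == truth)
    mask_use <- mask & valid
    if (!any(mask_use)) mask_use <- mask   # fall back to the full-window mask
    for (b in seq_along(keep))
      M[i, b] <- masked_mean(cs$hyper[, , keep[b]], mask_use)
    M[i, length(keep) + 1] <- masked_mean(cs$height, mask_use)
    M[i, length(keep) + 2] <- masked_mean(cs$intensity, mask_use)
    M[i, length(keep) + 3] <- masked_mean(cs$thermal, mask_use)
    masks[[i]] <- mask; windows[[i]] <- w
  }
  labels <- c(sprintf("%.1fnm", scene$wavelengths[keep]),
              "height", "intensity", "thermal")
  colnames(M) <- labels
  structure(list(masks = masks, windows = windows, margin = margin,
                 band_stack = list(M = M,
                                   wavelengths = scene$wavelengths[keep],
                                   labels = labels,
                                   n_spectral = length(keep)),
                 accuracy = acc, design = d, phenotypes = scene$phenotypes,
                 scene = scene),
            class = "plot_prep")
}

#' Fit a column-wise z-score scaler on a training subset
#'
#' Means and standard deviations are computed from `fit_rows` only, then
#' applied to the whole table, so validation/test rows can never leak into
#' the scaling. Works for feature tables and for trait targets alike.
#'
#' @param table numeric matrix or data.frame
#' @param fit_rows integer/logical index of training rows (default: all)
#' @return list with `scaled` (matrix) and `scaler` (means, sds, names)
#' @export
standardize <- function(table, fit_rows = seq_len(nrow(table))) {
  x <- as.matrix(table)
  mu <- colMeans(x[fit_rows, , drop = FALSE])
  sdv <- apply(x[fit_rows, , drop = FALSE], 2, sd)
  if (any(sdv == 0))
    stop("zero-variance column(s) in fit rows: ",
         paste(colnames(x)[sdv == 0], collapse = ", "))
  scaler <- list(mean = mu, sd = sdv, names = colnames(x))
  list(scaled = apply_scaler(scaler, x), scaler = scaler)
}

#' Apply / invert a fitted scaler
#' @param scaler a scaler from [standardize()]
#' @param table matrix/data.frame with the scaler's columns
#' @return transformed matrix
#' @export
apply_scaler <- function(scaler, table) {
  x <- as.matrix(table)
  sweep(sweep(x, 2, scaler$mean[colnames(x) %||% seq_len(ncol(x))]), 2,
        scaler$sd[colnames(x) %||% seq_len(ncol(x))], "/")
}

#' @rdname apply_scaler
#' @export
invert_scaler <- function(scaler, table) {
  x <- as.matrix(table)
  sweep(sweep(x, 2, scaler$sd[colnames(x) %||% seq_len(ncol(x))], "*"), 2,
        scaler$mean[colnames(x) %||% seq_len(ncol(x))], "+")
}
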