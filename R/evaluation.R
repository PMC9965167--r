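#' Regression metrics: R-squared, RMSE, MAE
#'
#' `R2 = 1 - SSE/SST`; `MAE = mean(|y - yhat|)`. The default RMSE follows
#' the printed convention `sqrt(SSE / (n - 1))`; `rmse_denom = "n"` selects
#' the conventional `sqrt(SSE / n)` (strictly smaller for the same
#' residuals).
#'
#' @param y measured values
#' @param yhat predicted values
#' @param rmse_denom "n-1" (default) or "n"
#' @return named list with `r2`, `rmse`, `mae`, `n`
#' @export
regression_metrics <- function(y, yhat, rmse_denom = c("n-1", "n")) {
  rmse_denom <- match.arg(rmse_denom)
  stopifnot(length(y) == length(yhat))
  n <- length(y)
  if (n < 2) stop("need at least 2 observations")
  if (sd(y) == 0) stop("R-squared undefined for a constant target")
  sse <- sum((yhat - y)^2)
  sst <- sum((y - mean(y))^2)
  den <- if (rmse_denom == "n-1") n - 1 else n
  list(r2 = 1 - sse / sst, rmse = sqrt(sse / den),
       mae = mean(abs(y - yhat)), n = n)
}

#' Descriptive statistics table for a trait data.frame
#'
#' One row per trait: count, mean, sd, cv% (100 * sd/mean), min, quartiles
#' (linear interpolation) and max — the standard end-of-season summary of a
#' phenotype table.
#'
#' @param traits data.frame of numeric trait columns
#' @return data.frame with columns trait, count, mean, sd, cv_pct, min, q25,
#'   q50, q75, max; `cv_pct` is `NA` for a zero-mean trait
#' @export
describe_traits <- function(traits) {
  stopifnot(nrow(traits) >= 2)
  rows <- lapply(names(traits), function(tn) {
    v <- traits[[tn]]
    m <- mean(v); s <- sd(v)
    q <- quantile(v, c(.25, .5, .75), names = FALSE, type = 7)
    data.frame(trait = tn, count = length(v), mean = m, sd = s,
               cv_pct = if (m != 0) 100 * s / m else NA_real_,
               min = min(v), q25 = q[1], q50 = q[2], q75 = q[3], max = max(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Row-standardized k-nearest-neighbour spatial weights
#'
#' @param coords matrix of plot centroid coordinates (n x 2)
#' @param k number of neighbours
#' @param scheme "knn" (binary neighbours, then row-standardized) or
#'   "idw" (inverse distance among the k neighbours, row-standardized)
#' @return sparse `dgCMatrix` of weights with zero diagonal, rows sum to 1
#' @export
moran_weights <- function(coords, k = 8, scheme = c("knn", "idw")) {
  scheme <- match.arg(scheme)
  n <- nrow(coords)
  if (n < 4) stop("need at least 4 locations")
  k <- min(k, n - 1)
  nn <- FNN::get.knn(coords, k = k)
  i <- rep(seq_len(n), each = k)
  j <- as.vector(t(nn$nn.index))
  w <- if (scheme == "knn") rep(1, length(j)) else as.vector(t(1 / pmax(nn$nn.dist, 1e-12)))
  W <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
  rs <- Matrix::rowSums(W)
  Matrix::Diagonal(x = 1 / rs) %*% W
}

moran_i_value <- function(z, W) {
  zc <- z - mean(z)
  n <- length(z)
  s0 <- sum(W)
  as.numeric((n / s0) * (sum(zc * as.vector(W %*% zc)) / sum(zc^2)))
}

#' Global Moran's I of prediction residuals with a permutation test
#'
#' Measures spatial autocorrelation of per-plot residuals over the plot
#' centroids using row-standardized k-nearest-neighbour weights. The null
#' ("residuals are completely spatially random") expectation is
#' `-1/(n - 1)`; significance comes from a two-sided permutation test.
#'
#' @param residuals numeric vector of per-plot residuals
#' @param coords plot centroids (n x 2)
#' @param k neighbours in the weights scheme
#' @param scheme see [moran_weights()]
#' @param n_permutations random permutations (default 999; use more to
#'   resolve p-values below 0.001)
#' @param seed integer seed for the permutations
#' @param alpha significance threshold for the `significant` flag
#' @return list of class `moran_result`: `i`, `expected`, `p_value`,
#'   `significant`, `n`, `scheme`, `perm_i` (the permutation distribution)
#' @export
morans_i <- function(residuals, coords, k = 8, scheme = "knn",
                     n_permutations = 999, seed = 1, alpha = 0.001) {
  if (sd(residuals) == 0) stop("Moran's I undefined for constant residuals")
  W <- moran_weights(coords, k = k, scheme = scheme)
  n <- length(residuals)
  i_obs <- moran_i_value(residuals, W)
  set.seed(substream_seed(seed, "moran"))
  zc <- residuals - mean(residuals)
  denom <- sum(zc^2)
  s0 <- sum(W)
  Z <- vapply(seq_len(n_permutations), function(p) sample(zc), numeric(n))
  cross <- Matrix::colSums((W %*% Z) * Z)
  perm_i <- as.numeric((n / s0) * cross / denom)
  p_hi <- (1 + sum(perm_i >= i_obs)) / (n_permutations + 1)
  p_lo <- (1 + sum(perm_i <= i_obs)) / (n_permutations + 1)
  p <- min(1, 2 * min(p_hi, p_lo))
  structure(list(i = i_obs, expected = -1 / (n - 1), p_value = p,
                 significant = p < alpha, n = n,
                 scheme = sprintf("%s k=%d row-standardized", scheme, k),
                 perm_i = perm_i),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (E[I] = %.4f), p = %.4g%s [%s]\n",
              x$i, x$expected, x$p_value,
              if (x$significant) " *" else "", x$scheme))
  invisible(x)
}

#' Spatial prediction map of plot-level trait estimates
#'
#' Joins measured and predicted values (and their residual) onto the plot
#' polygons for choropleth display and GeoJSON export.
#'
#' @param predictions data.frame with `plot_id`, `measured`, `predicted`
#' @param design a `plot_design`
#' @return data.frame of class `prediction_map`: the design columns plus
#'   `measured`, `predicted`, `residual` (= measured - predicted)
#' @export
prediction_map <- function(predictions, design) {
  missing <- setdiff(design$plot_id, predictions$plot_id)
  if (length(missing))
    stop("no prediction for plot(s): ", paste(missing, collapse = ", "))
  m <- merge(as.data.frame(design), predictions, by = "plot_id", sort = FALSE)
  m$residual <- m$measured - m$predicted
  class(m) <- c("prediction_map", "data.frame")
  m
}

#' Render a prediction map as a ggplot choropleth
#' @param map a `prediction_map`
#' @param fill which attribute to colour by
#' @return a ggplot object
#' @export
plot_prediction_map <- function(map, fill = c("predicted", "measured", "residual")) {
  fill <- match.arg(fill)
  rect <- do.call(rbind, lapply(seq_len(nrow(map)), function(i) {
    p <- map[i, ]
    data.frame(x = c(p$xmin, p$xmax, p$xmax, p$xmin),
               y = c(p$ymin, p$ymin, p$ymax, p$ymax),
               id = p$plot_id, value = p[[fill]])
  }))
  ggplot2::ggplot(rect, ggplot2::aes(x = x, y = y, group = id, fill = value)) +
    ggplot2::geom_polygon() +
    ggplot2::scale_fill_viridis_c(name = fill) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)")
}

#' Write a prediction map as GeoJSON
#' @param map a `prediction_map`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_prediction_map <- function(map, path) {
  write_plots_geojson(map, path,
                      extra = map[, c("measured", "predicted", "residual")])
}

#' Bar chart of Moran's I across models, starred when significant
#' @param moran_table data.frame with columns `model`, `moran_i`,
#'   `significant` (as written by [run_pipeline()])
#' @return a ggplot object
#' @export
plot_moran_bars <- function(moran_table) {
  moran_table$label <- ifelse(moran_table$significant, "*", "")
  ggplot2::ggplot(moran_table,
                  ggplot2::aes(x = model, y = moran_i)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = label), vjust = -0.3, size = 6) +
    ggplot2::labs(x = NULL, y = "Global Moran's I") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
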