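#' Normalized difference spectral index of two band means
#'
#' `(m_i - m_j) / (m_i + m_j)`; antisymmetric under swapping the bands and
#' bounded in [-1, 1] whenever both means are non-negative. A zero
#' denominator yields `NA` (undefined-value sentinel).
#'
#' @param m_i,m_j plot-wise band means (vectorized)
#' @return NDSI values
#' @export
ndsi <- function(m_i, m_j) {
  den <- m_i + m_j
  out <- (m_i - m_j) / den
  out[den == 0] <- NA_real_
  out
}

#' Build a band stack from a plot-mean table
#'
#' @param M numeric matrix (plots x bands) of plot-wise masked means
#' @param wavelengths wavelengths (nm) of the spectral columns, in ascending
#'   order; the remaining columns are named auxiliaries
#' @param aux_labels names of the trailing auxiliary columns
#' @param scale_aux z-score the auxiliary columns before NDSI formation
#'   (height/intensity/thermal live on arbitrary scales that would otherwise
#'   break the [-1, 1] range); spectral columns are never rescaled
#' @return list of class `band_stack`
#' @export
band_stack <- function(M, wavelengths,
                       aux_labels = c("height", "intensity", "thermal"),
                       scale_aux = TRUE) {
  n_spec <- length(wavelengths)
  stopifnot(ncol(M) == n_spec + length(aux_labels))
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be strictly ascending")
  if (anyNA(M)) stop("band stack must not contain missing values")
  if (scale_aux && length(aux_labels)) {
    j <- n_spec + seq_along(aux_labels)
    for (jj in j) {
      s <- sd(M[, jj])
      M[, jj] <- if (s > 0) (M[, jj] - mean(M[, jj])) / s else 0
    }
  }
  labels <- c(sprintf("%.1fnm", wavelengths), aux_labels)
  colnames(M) <- labels
  structure(list(M = M, wavelengths = wavelengths, labels = labels,
                 n_spectral = n_spec), class = "band_stack")
}

#' Exhaustive NDSI band-pair screen against one trait
#'
#' For every unordered pair of bands (i, j) the per-plot NDSI is correlated
#' with the trait; the squared Pearson correlation (equivalently the R^2 of
#' the simple regression of the trait on the NDSI) fills a symmetric
#' heatmap. Pairs whose NDSI is undefined on any plot (zero denominator) are
#' flagged and excluded from the argmax.
#'
#' @param stack a `band_stack` (or a `plot_prep`, whose band stack is used)
#' @param trait numeric vector over plots
#' @param spectral_only restrict the screen to the spectral bands
#' @return list of class `ndsi_heatmap`: `r2` (symmetric matrix, NA
#'   diagonal), `labels`, `n_invalid` (count of invalid pairs), `best`
#'   (list `i`, `j`, `label_i`, `label_j`, `r2`)
#' @export
ndsi_heatmap <- function(stack, trait, spectral_only = FALSE) {
  if (inherits(stack, "plot_prep"))
    stack <- band_stack(stack$band_stack$M, stack$band_stack$wavelengths)
  M <- stack$M
  if (spectral_only) M <- M[, seq_len(stack$n_spectral), drop = FALSE]
  B <- ncol(M); n <- nrow(M)
  if (n < 3) stop("need at least 3 plots")
  if (sd(trait) == 0) stop("trait is constant")
  tc <- trait - mean(trait)
  sst <- sum(tc^2)
  r2 <- matrix(NA_real_, B, B, dimnames = list(colnames(M), colnames(M)))
  n_invalid <- 0L
  for (i in seq_len(B - 1)) {
    j <- (i + 1):B
    den <- M[, i] + M[, j, drop = FALSE]
    D <- (M[, i] - M[, j, drop = FALSE]) / den
    D[den == 0] <- NA
    bad <- colSums(is.na(D)) > 0
    n_invalid <- n_invalid + sum(bad)
    Dc <- sweep(D, 2, colMeans(D))
    ssd <- colSums(Dc^2)
    r <- colSums(Dc * tc)^2 / (ssd * sst)
    r[ssd == 0] <- 0        # constant NDSI carries no information
    r[bad] <- NA
    r2[i, j] <- r
    r2[j, i] <- r
  }
  best <- best_pair_matrix(r2)
  structure(list(r2 = r2, labels = colnames(M), n_invalid = n_invalid,
                 best = best), class = "ndsi_heatmap")
}

best_pair_matrix <- function(r2) {
  B <- ncol(r2)
  ut <- upper.tri(r2)
  vals <- r2[ut]
  if (all(is.na(vals))) stop("no valid band pair in heatmap")
  mx <- max(vals, na.rm = TRUE)
  idx <- which(ut & !is.na(r2) & r2 == mx, arr.ind = TRUE)
  # ties: smaller first band index (lower wavelength), then smaller second
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  i <- idx[1, 1]; j <- idx[1, 2]
  list(i = i, j = j, label_i = colnames(r2)[i], label_j = colnames(r2)[j],
       r2 = r2[i, j])
}

#' Best band pair of an NDSI heatmap
#' @param heatmap an `ndsi_heatmap`
#' @return list with `i`, `j`, `label_i`, `label_j`, `r2`
#' @export
best_pair <- function(heatmap) {
  stopifnot(inherits(heatmap, "ndsi_heatmap"))
  heatmap$best
}

#' Screen all traits of a phenotype table
#'
#' @param stack a `band_stack`
#' @param traits data.frame with one numeric column per trait
#' @param spectral_only restrict to spectral bands
#' @return data.frame with one row per trait: best band pair labels and R^2
#' @export
ndsi_screen_traits <- function(stack, traits, spectral_only = FALSE) {
  rows <- lapply(names(traits), function(tn) {
    hm <- ndsi_heatmap(stack, traits[[tn]], spectral_only = spectral_only)
    data.frame(trait = tn, band_i = hm$best$label_i, band_j = hm$best$label_j,
               r2 = hm$best$r2, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Render an NDSI heatmap as a ggplot raster
#' @param heatmap an `ndsi_heatmap`
#' @param title optional plot title (e.g. the trait name)
#' @return a ggplot object with the best pair marked
#' @export
plot_ndsi_heatmap <- function(heatmap, title = NULL) {
  r2 <- heatmap$r2
  df <- expand.grid(i = seq_len(nrow(r2)), j = seq_len(ncol(r2)))
  df$r2 <- as.vector(r2)
  best <- heatmap$best
  ggplot2::ggplot(df, ggplot2::aes(x = i, y = j, fill = r2)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = expression(R^2),
                                  na.value = "grey90") +
    ggplot2::annotate("point", x = c(best$i, best$j), y = c(best$j, best$i),
                      shape = 4, colour = "green", size = 3) +
    ggplot2::labs(x = "band index i", y = "band index j", title = title) +
    ggplot2::coord_equal()
}

#' Write an NDSI heatmap matrix as CSV
#' @param heatmap an `ndsi_heatmap`
#' @param path CSV file path
#' @return `path`, invisibly
#' @export
write_ndsi_heatmap <- function(heatmap, path) {
  utils::write.csv(heatmap$r2, path, row.names = TRUE)
  invisible(path)
}
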