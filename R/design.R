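#' Generate a randomized nitrogen-trial plot layout
#'
#' Lays out single-row plots (default 5.33 m x 0.76 m) in blocks that are
#' adjacent along the north-south axis. The nitrogen treatment alternates
#' block by block (`low_N`, `high_N`, `low_N`, ...), mimicking a split-plot
#' trial in which whole blocks either receive no supplemental nitrogen or a
#' high fertilizer rate. Plot rows run north-south: plot length is along y,
#' plot width along x; a block is a band of `plots_per_block` side-by-side
#' rows. Large trials can be folded into several block columns.
#'
#' @param n_blocks number of treatment blocks (>= 1)
#' @param plots_per_block number of single-row plots per block (>= 1)
#' @param seed integer seed (controls genotype assignment)
#' @param plot_length,plot_width plot dimensions in metres
#' @param n_block_cols number of block columns the field is folded into
#' @param alley east-west alley width between block columns, metres
#' @param n_genotypes size of the genotype pool sampled with replacement
#' @return a `data.frame` of class `plot_design` with one row per plot:
#'   `plot_id`, `block_id`, `grid_row`, `grid_col`, `treatment`,
#'   `genotype_id` and the polygon bounds `xmin`, `xmax`, `ymin`, `ymax`.
#' @export
generate_design <- function(n_blocks, plots_per_block, seed = 1,
                            plot_length = 5.33, plot_width = 0.76,
                            n_block_cols = 1, alley = 0.76,
                            n_genotypes = 66) {
  if (!is.numeric(n_blocks) || n_blocks < 1 ||
      !is.numeric(plots_per_block) || plots_per_block < 1)
    stop("n_blocks and plots_per_block must be positive counts")
  n_blocks <- as.integer(n_blocks)
  plots_per_block <- as.integer(plots_per_block)
  n_block_cols <- max(1L, as.integer(n_block_cols))

  blocks_per_col <- ceiling(n_blocks / n_block_cols)
  block <- rep(seq_len(n_blocks), each = plots_per_block)
  within <- rep(seq_len(plots_per_block), times = n_blocks)
  bcol <- (block - 1L) %/% blocks_per_col        # 0-based block column
  brow <- (block - 1L) %% blocks_per_col         # 0-based block row

  xmin <- bcol * (plots_per_block * plot_width + alley) +
    (within - 1L) * plot_width
  ymax <- -brow * plot_length                    # y decreases southward
  d <- data.frame(
    plot_id = sprintf("P%04d", seq_along(block)),
    block_id = sprintf("B%03d", block),
    grid_row = as.integer(brow + 1L),
    grid_col = as.integer(bcol * plots_per_block + within),
    treatment = factor(ifelse(block %% 2L == 1L, "low_N", "high_N"),
                       levels = c("low_N", "high_N")),
    genotype_id = NA_integer_,
    xmin = xmin, xmax = xmin + plot_width,
    ymin = ymax - plot_length, ymax = ymax,
    stringsAsFactors = FALSE
  )
  set.seed(substream_seed(seed, "design"))
  d$genotype_id <- sample.int(n_genotypes, nrow(d), replace = TRUE)
  class(d) <- c("plot_design", "data.frame")
  d
}

#' Plot centroids of a design
#' @param design a `plot_design`
#' @return matrix with columns x, y
#' @export
plot_centroids <- function(design) {
  cbind(x = (design$xmin + design$xmax) / 2,
        y = (design$ymin + design$ymax) / 2)
}

#' Write plot polygons as GeoJSON
#'
#' Each plot becomes a Polygon feature with `plot_id`, `block_id`,
#' `treatment` and `genotype_id` properties (plus any extra attribute
#' columns passed in `extra`).
#'
#' @param design a `plot_design`
#' @param path output file
#' @param extra optional data.frame of additional per-plot properties
#' @return `path`, invisibly
#' @export
write_plots_geojson <- function(design, path, extra = NULL) {
  feats <- lapply(seq_len(nrow(design)), function(i) {
    p <- design[i, ]
    ring <- list(c(p$xmin, p$ymin), c(p$xmax, p$ymin),
                 c(p$xmax, p$ymax), c(p$xmin, p$ymax), c(p$xmin, p$ymin))
    props <- list(plot_id = p$plot_id, block_id = p$block_id,
                  treatment = as.character(p$treatment),
                  genotype_id = p$genotype_id)
    if (!is.null(extra)) props <- c(props, as.list(extra[i, , drop = FALSE]))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a plot-polygon GeoJSON written by [write_plots_geojson()]
#' @param path GeoJSON file
#' @return a `plot_design` data.frame (axis-aligned bounds recovered from the
#'   polygon rings)
#' @export
read_plots_geojson <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(g$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    pr <- f$properties
    data.frame(plot_id = pr$plot_id, block_id = pr$block_id,
               grid_row = NA_integer_, grid_col = NA_integer_,
               treatment = pr$treatment, genotype_id = pr$genotype_id,
               xmin = min(ring[, 1]), xmax = max(ring[, 1]),
               ymin = min(ring[, 2]), ymax = max(ring[, 2]),
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  d$treatment <- factor(d$treatment, levels = c("low_N", "high_N"))
  class(d) <- c("plot_design", "data.frame")
  d
}
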