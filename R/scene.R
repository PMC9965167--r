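#' Default rendering specification for synthetic field scenes
#'
#' Controls the geometry, spectral templates, trait-to-signal links and noise
#' of [render_scene()]. The trait links are deliberately linear so that
#' parameter recovery by downstream models is analyzable: the vegetation NIR
#' plateau (750-1000 nm) is `nir_coef[1] + nir_coef[2] * total_plant_n`
#' (kg/ha), and canopy height is `height_coef[1] + height_coef[2] *
#' dry_stalk_biomass` (kg/ha). Soil and shadow pixels are spectrally distinct
#' (bright sloped soil line, dark flat shadow) and are placed as a border
#' ring plus random speckle inside each plot polygon.
#'
#' @param n_bands number of hyperspectral bands across 400-1000 nm (the
#'   sensor nominally has 270; one band can be dropped downstream to match a
#'   269-band working set)
#' @param gsd ground sampling distance, m/pixel
#' @param nonveg_fraction target fraction of non-vegetation pixels inside a
#'   plot polygon (border + speckle), in [0, 1]
#' @param shadow_fraction fraction of plot pixels rendered as shadow (part of
#'   `nonveg_fraction`), in [0, 1]
#' @param refl_noise_sd per-pixel multiplicative brightness noise sd
#' @param band_noise_sd additive per-pixel-per-band reflectance noise sd
#' @param height_noise_sd canopy height pixel noise sd, m
#' @param terrain_slope length-2 (dz/dx, dz/dy) of an optional terrain ramp;
#'   c(0, 0) keeps the terrain flat at z = 0
#' @param ... overrides for the remaining documented defaults
#' @return a list of rendering parameters
#' @export
default_render_spec <- function(n_bands = 270, gsd = 0.03,
                                nonveg_fraction = 0.25, shadow_fraction = 0.07,
                                refl_noise_sd = 0.04, band_noise_sd = 0.005,
                                height_noise_sd = 0.05,
                                terrain_slope = c(0, 0), ...) {
  spec <- list(
    n_bands = n_bands, wl_range = c(400, 1000), gsd = gsd,
    field_margin_m = 0.45, border_px = 1L,
    nonveg_fraction = nonveg_fraction, shadow_fraction = shadow_fraction,
    nir_coef = c(0.33, 9e-4),       # NIR plateau vs total plant N (kg/ha)
    height_coef = c(0.8, 1.74e-4),  # canopy height (m) vs stalk biomass (kg/ha)
    refl_noise_sd = refl_noise_sd, band_noise_sd = band_noise_sd,
    height_noise_sd = height_noise_sd,
    intensity = c(canopy = 120, soil = 40, shadow = 20),
    intensity_sd = c(canopy = 8, soil = 5, shadow = 3),
    thermal = c(canopy = 27, soil = 32, shadow = 29.5),
    thermal_sd = c(canopy = 0.3, soil = 0.5, shadow = 0.3),
    terrain_slope = terrain_slope,
    shadow_scale = 0.5
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(spec))
  if (length(bad)) stop("unknown render_spec fields: ", paste(bad, collapse = ", "))
  spec <- modifyList(spec, ov)
  fr <- c(spec$nonveg_fraction, spec$shadow_fraction)
  if (any(fr < 0 | fr > 1)) stop("render_spec fractions must lie in [0, 1]")
  spec
}

# fixed visible-region vegetation reflectance template (gain-independent part)
veg_vis_curve <- function(wl) {
  0.035 + 0.055 * exp(-((wl - 555) / 30)^2) +
    0.004 * exp(-((wl - 440) / 25)^2)
}

# per-band affine decomposition of the vegetation spectrum: R = a + c * gain
# where `gain` is the plot's NIR plateau level; linear ramp across 700-760 nm
veg_band_coefs <- function(wl) {
  c_part <- pmin(pmax((wl - 700) / 60, 0), 1)
  a_part <- veg_vis_curve(wl) * (1 - c_part)
  list(a = a_part, c = c_part)
}

soil_curve <- function(wl) 0.10 + (wl - 400) / 600 * 0.16

#' Render a synthetic multimodal field scene
#'
#' Builds co-registered hyperspectral, canopy-height, LiDAR-intensity and
#' thermal rasters over the plot layout, plus per-pixel ground-truth class
#' labels (vegetation / soil / shadow). Canopy pixels follow a vegetation
#' reflectance template whose NIR plateau scales linearly with the plot's
#' total plant nitrogen; canopy height scales linearly with stalk biomass;
#' thermal is near-uniform with vegetation slightly cooler than soil (water
#' is assumed non-limiting). With all noise terms at zero the plot-mean NIR
#' reflectance over the truth mask equals the planted linear function of the
#' trait exactly.
#'
#' @param design a `plot_design` from [generate_design()]
#' @param phenotypes a `phenotype_record` from [sample_trait_population()]
#' @param render_spec see [default_render_spec()]
#' @param seed integer seed
#' @return an object of class `field_scene`: hyperspectral array
#'   (rows x cols x bands) with `wavelengths`, `height`, `intensity`,
#'   `thermal` matrices on the same grid, `gsd`, `origin` (top-left corner),
#'   `class_map` (0 soil, 1 vegetation, 2 shadow), `plots`, `phenotypes`,
#'   and the render spec and seed used
#' @export
render_scene <- function(design, phenotypes, render_spec = default_render_spec(),
                         seed = 1) {
  rs <- render_spec
  stopifnot(nrow(design) == nrow(phenotypes))
  set.seed(substream_seed(seed, "render"))

  gsd <- rs$gsd
  m <- rs$field_margin_m
  x0 <- min(design$xmin) - m; x1 <- max(design$xmax) + m
  y0 <- max(design$ymax) + m; y1 <- min(design$ymin) - m
  nc <- ceiling((x1 - x0) / gsd); nr <- ceiling((y0 - y1) / gsd)
  origin <- c(x0, y0)
  grid <- surface_raster(matrix(0, nr, nc), cell_size = gsd, origin = origin)

  # ---- per-pixel class map and per-pixel plot membership -------------------
  class_map <- matrix(0L, nr, nc)            # 0 = soil everywhere outside plots
  plot_index <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(design))) {
    w <- polygon_window(grid, design[i, ], margin = 0)
    rows <- w$rows; cols <- w$cols
    plot_index[rows, cols] <- i
    class_map[rows, cols] <- 1L
    bp <- rs$border_px
    core_rows <- rows; core_cols <- cols
    if (bp > 0 && length(rows) > 2 * bp && length(cols) > 2 * bp) {
      class_map[rows[seq_len(bp)], cols] <- 0L
      class_map[rows[seq(length(rows) - bp + 1, length(rows))], cols] <- 0L
      class_map[rows, cols[seq_len(bp)]] <- 0L
      class_map[rows, cols[seq(length(cols) - bp + 1, length(cols))]] <- 0L
      core_rows <- rows[(bp + 1):(length(rows) - bp)]
      core_cols <- cols[(bp + 1):(length(cols) - bp)]
    }
    npix <- length(rows) * length(cols)
    n_border <- npix - length(core_rows) * length(core_cols)
    n_shadow <- round(rs$shadow_fraction * npix)
    n_soil_speck <- max(0, round(rs$nonveg_fraction * npix) - n_border - n_shadow)
    core <- as.matrix(expand.grid(r = core_rows, c = core_cols))
    n_speck <- min(nrow(core), n_shadow + n_soil_speck)
    if (n_speck > 0) {
      pick <- core[sample.int(nrow(core), n_speck), , drop = FALSE]
      if (n_shadow > 0) {
        sh <- pick[seq_len(min(n_shadow, nrow(pick))), , drop = FALSE]
        class_map[sh] <- 2L
      }
      if (nrow(pick) > n_shadow) {
        so <- pick[(n_shadow + 1):nrow(pick), , drop = FALSE]
        class_map[so] <- 0L
      }
    }
  }

  veg <- class_map == 1L & plot_index > 0L
  shadow <- class_map == 2L
  npx <- nr * nc

  # ---- trait-to-signal links ----------------------------------------------
  nir_gain_plot <- pmin(pmax(rs$nir_coef[1] +
                               rs$nir_coef[2] * phenotypes$total_plant_n,
                             0.05), 0.95)
  height_plot <- pmax(rs$height_coef[1] +
                        rs$height_coef[2] * phenotypes$dry_stalk_biomass, 0.1)
  gain_map <- matrix(0, nr, nc)
  gain_map[veg] <- nir_gain_plot[plot_index[veg]]
  hmap <- matrix(0, nr, nc)
  hmap[veg] <- height_plot[plot_index[veg]]

  # ---- hyperspectral cube --------------------------------------------------
  wl <- seq(rs$wl_range[1], rs$wl_range[2], length.out = rs$n_bands)
  cf <- veg_band_coefs(wl)
  soil_r <- soil_curve(wl)
  eps <- if (rs$refl_noise_sd > 0) rnorm(npx, 0, rs$refl_noise_sd) else numeric(npx)
  hyper <- array(0, dim = c(nr, nc, rs$n_bands))
  base_px <- numeric(npx)
  for (b in seq_len(rs$n_bands)) {
    base_px[] <- soil_r[b]
    base_px[shadow] <- rs$shadow_scale * soil_r[b]
    base_px[veg] <- cf$a[b] + cf$c[b] * gain_map[veg]
    v <- base_px * (1 + eps)
    if (rs$band_noise_sd > 0) v <- v + rnorm(npx, 0, rs$band_noise_sd)
    hyper[, , b] <- pmin(pmax(v, 0), 1)
  }

  # ---- auxiliary rasters ---------------------------------------------------
  draw_class <- function(means, sds) {
    v <- matrix(rnorm(npx, means["soil"], sds["soil"]), nr, nc)
    v[shadow] <- rnorm(sum(shadow), means["shadow"], sds["shadow"])
    v[veg] <- rnorm(sum(veg), means["canopy"], sds["canopy"])
    v
  }
  height <- matrix(0, nr, nc)
  if (rs$height_noise_sd > 0)
    height[veg] <- pmax(hmap[veg] + rnorm(sum(veg), 0, rs$height_noise_sd), 0)
  else height[veg] <- hmap[veg]
  intensity <- pmax(draw_class(rs$intensity, rs$intensity_sd), 0)
  thermal <- draw_class(rs$thermal, rs$thermal_sd)

  structure(list(
    hyperspectral = hyper, wavelengths = wl,
    height = height, intensity = intensity, thermal = thermal,
    gsd = gsd, origin = origin,
    class_map = class_map, plot_index = plot_index,
    plots = design, phenotypes = phenotypes,
    planted = list(nir_gain = nir_gain_plot, canopy_height = height_plot),
    render_spec = rs, seed = seed
  ), class = "field_scene")
}

#' @export
print.field_scene <- function(x, ...) {
  cat(sprintf("<field_scene> %d x %d px @ %.3g m, %d bands (%.0f-%.0f nm), %d plots\n",
              nrow(x$height), ncol(x$height), x$gsd, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths), nrow(x$plots)))
  invisible(x)
}

#' Extract one modality of a scene as a `surface_raster`
#' @param scene a `field_scene`
#' @param modality one of "height", "intensity", "thermal"
#' @return a `surface_raster`
#' @export
scene_raster <- function(scene, modality = c("height", "intensity", "thermal")) {
  modality <- match.arg(modality)
  surface_raster(scene[[modality]], cell_size = scene$gsd, origin = scene$origin)
}

#' Ground-truth vegetation mask for one plot window
#'
#' Vegetation pixels of any plot falling inside the window count as
#' vegetation (with adjacent rows, a window margin can overlap the
#' neighbouring plot's canopy).
#'
#' @param scene a `field_scene`
#' @param plot_id plot identifier
#' @param margin window margin in pixels (must match the chip extraction)
#' @return logical matrix (TRUE = vegetation) over the plot window
#' @export
truth_mask <- function(scene, plot_id, margin = 0) {
  i <- match(plot_id, scene$plots$plot_id)
  if (is.na(i)) stop("unknown plot_id: ", plot_id)
  grid <- scene_raster(scene, "height")
  w <- polygon_window(grid, scene$plots[i, ], margin = margin)
  scene$class_map[w$rows, w$cols] == 1L
}

terrain_z <- function(scene, x, y) {
  s <- scene$render_spec$terrain_slope
  s[1] * x + s[2] * y
}

#' Simulate a LiDAR point cloud over a rendered scene
#'
#' Points are placed uniformly over the field extent at the requested
#' density. Points falling on canopy pixels return from the canopy top
#' (terrain + canopy height + vertical noise) with probability
#' `canopy_return_prob`, otherwise from the ground; soil and shadow pixels
#' always return from the ground. Canopy returns carry higher intensity than
#' ground returns, mirroring vegetation reflectivity at the laser wavelength.
#'
#' @param scene a `field_scene`
#' @param density requested point density, points/m^2 (the realized density
#'   is exact up to rounding of the total count)
#' @param seed integer seed
#' @param canopy_return_prob probability a canopy-pixel point samples the
#'   canopy rather than the ground beneath it
#' @param z_sd vertical noise sd, m
#' @return data.frame with columns `x`, `y`, `z`, `intensity`,
#'   `ground` (logical)
#' @export
generate_pointcloud <- function(scene, density = 1600, seed = 1,
                                canopy_return_prob = 0.85, z_sd = 0.03) {
  if (density <= 0) stop("density must be > 0")
  set.seed(substream_seed(seed, "pointcloud"))
  nr <- nrow(scene$height); nc <- ncol(scene$height)
  wx <- nc * scene$gsd; wy <- nr * scene$gsd
  n <- round(density * wx * wy)
  x <- scene$origin[1] + runif(n, 0, wx)
  y <- scene$origin[2] - runif(n, 0, wy)
  grid <- scene_raster(scene, "height")
  rc <- xy_to_rc(grid, x, y)
  rc[, 1] <- pmin(pmax(rc[, 1], 1L), nr)
  rc[, 2] <- pmin(pmax(rc[, 2], 1L), nc)
  lin <- rc[, 1] + (rc[, 2] - 1L) * nr
  h <- scene$height[lin]
  is_veg <- scene$class_map[lin] == 1L & h > 0
  canopy <- is_veg & runif(n) < canopy_return_prob
  zt <- terrain_z(scene, x, y)
  z <- zt + ifelse(canopy, h, 0) + rnorm(n, 0, z_sd)
  ints <- scene$intensity[lin] + rnorm(n, 0, 2)
  ints[!canopy] <- pmax(rnorm(sum(!canopy),
                              scene$render_spec$intensity["soil"],
                              scene$render_spec$intensity_sd["soil"]), 0)
  data.frame(x = x, y = y, z = z, intensity = pmax(ints, 0), ground = !canopy)
}

#' Write / read a point cloud as a tab-separated table
#' @param points data.frame with x, y, z, intensity, ground
#' @param path TSV file path
#' @return `path` invisibly, or the point data.frame
#' @export
write_pointcloud_tsv <- function(points, path) {
  utils::write.table(points, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pointcloud_tsv
#' @export
read_pointcloud_tsv <- function(path) {
  p <- utils::read.table(path, sep = "\t", header = TRUE)
  p$ground <- as.logical(p$ground)
  p
}

#' Convenience constructor: design + traits + rendered scene in one call
#'
#' @param n_plots total number of plots (split into blocks of
#'   `plots_per_block`)
#' @param plots_per_block plots per treatment block
#' @param n_bands hyperspectral band count
#' @param seed master seed driving all three stages
#' @param effect_spec,render_spec stage specifications
#' @param n_block_cols block columns in the layout
#' @return a `field_scene`
#' @export
simulate_field <- function(n_plots = 60, plots_per_block = 6, n_bands = 60,
                           seed = 1, effect_spec = default_effect_spec(),
                           render_spec = default_render_spec(n_bands = n_bands),
                           n_block_cols = 1) {
  n_blocks <- ceiling(n_plots / plots_per_block)
  if (n_blocks * plots_per_block != n_plots)
    stop("n_plots must be a multiple of plots_per_block")
  d <- generate_design(n_blocks, plots_per_block, seed = seed,
                       n_block_cols = n_block_cols)
  ph <- sample_trait_population(d, effect_spec, seed = seed)
  render_scene(d, ph, render_spec, seed = seed)
}
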