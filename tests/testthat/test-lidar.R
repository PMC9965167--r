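test_that("outlier filter removes exactly a displaced point (brute-force oracle)", {
  set.seed(21)
  g <- expand.grid(x = seq(0, 1, 0.1), y = seq(0, 1, 0.1))
  pts <- data.frame(x = g$x, y = g$y, z = 0)
  pts[50, "z"] <- 10   # one point far above the sheet
  # brute-force kNN mean distances
  D <- as.matrix(dist(pts))
  md <- apply(D, 1, function(r) mean(sort(r)[2:9]))
  flagged <- unname(which(md > mean(md) + 3 * sd(md)))
  expect_identical(flagged, 50L)
  out <- remove_outliers(pts, k_neighbors = 8, sigma_mult = 3)
  expect_equal(nrow(out), nrow(pts) - 1)
  expect_false(10 %in% out$z)
})

test_that("outlier filter identity cases", {
  g <- expand.grid(x = seq(0, 1, 0.25), y = seq(0, 1, 0.25))
  pts <- data.frame(x = g$x, y = g$y, z = 0)
  expect_equal(nrow(remove_outliers(pts, 4, Inf)), nrow(pts))
  expect_equal(nrow(remove_outliers(pts, 4, 3)), nrow(pts))  # regular grid
  expect_error(remove_outliers(pts[1:3, ], 8, 3), "at least")
})

test_that("outlier removal never exceeds the cap fraction", {
  set.seed(5)
  pts <- data.frame(x = runif(200), y = runif(200), z = c(rep(0, 150),
                                                          runif(50, 5, 50)))
  out <- remove_outliers(pts, 8, 0.1, cap_fraction = 0.05)
  expect_gte(nrow(out), 190)
})

test_that("DSM takes the per-cell maximum (brute force agreement)", {
  set.seed(31)
  pts <- data.frame(x = runif(2000, 0, 3), y = runif(2000, 0, 3),
                    z = rnorm(2000), ground = FALSE)
  dsm <- rasterize_dsm(pts, cell_size = 0.5,
                       origin = c(0, 3), dims = c(6, 6))
  for (i in 1:6) for (j in 1:6) {
    sel <- pts$x >= (j - 1) * 0.5 & pts$x < j * 0.5 &
      pts$y <= 3 - (i - 1) * 0.5 & pts$y > 3 - i * 0.5
    expected <- if (any(sel)) max(pts$z[sel]) else NA_real_
    expect_equal(dsm$values[i, j], expected, info = paste(i, j))
  }
})

test_that("one point per 3 cm cell reproduces z exactly", {
  g <- expand.grid(x = seq(0.015, 0.285, 0.03), y = seq(0.015, 0.285, 0.03))
  pts <- data.frame(x = g$x, y = g$y, z = seq_len(nrow(g)), ground = FALSE)
  dsm <- rasterize_dsm(pts, cell_size = 0.03, origin = c(0, 0.3),
                       dims = c(10, 10))
  expect_false(anyNA(dsm$values))
  rc <- maizefuse:::xy_to_rc(dsm, pts$x, pts$y)
  expect_equal(dsm$values[cbind(rc[, 1], rc[, 2])], pts$z)
})

test_that("DTM recovers an inclined plane to 1e-6 via TIN interpolation", {
  set.seed(41)
  a <- 0.05; b <- -0.02; c0 <- 1.3
  # sparse ground samples snapped to cell centres (a cell's lowest return then
  # sits exactly at its centre), plus the four corner cells to span the hull
  ctr <- seq(0.25, 9.75, 0.5)
  g <- expand.grid(x = ctr, y = -ctr)
  keep <- sort(sample(nrow(g), 60))
  pts <- g[keep, ]
  pts <- rbind(pts, expand.grid(x = c(0.25, 9.75), y = c(-0.25, -9.75)))
  pts$z <- a * pts$x + b * pts$y + c0
  pts$ground <- TRUE
  dtm <- rasterize_dtm(pts, cell_size = 0.5, origin = c(0, 0), dims = c(20, 20))
  cc <- maizefuse:::cell_centers(dtm)
  inside <- cc$x >= 0.75 & cc$x <= 9.25 & cc$y <= -0.75 & cc$y >= -9.25
  err <- abs(dtm$values - (a * cc$x + b * cc$y + c0))
  expect_lt(max(err[inside]), 1e-6)
  expect_false(anyNA(dtm$values))   # outside-hull cells filled by nearest
})

test_that("flat ground gives a zero DTM and single voids interpolate to zero", {
  g <- expand.grid(x = seq(0.25, 4.75, 0.5), y = seq(-4.75, -0.25, 0.5))
  pts <- data.frame(x = g$x, y = g$y, z = 0, ground = TRUE)
  void <- !(abs(pts$x - 2.25) < 0.01 & abs(pts$y + 2.25) < 0.01)
  dtm <- rasterize_dtm(pts[void, ], cell_size = 0.5, origin = c(0, 0),
                       dims = c(10, 10))
  expect_equal(max(abs(dtm$values)), 0)
  expect_error(rasterize_dtm(pts[1:2, ], 0.5), "at least 3")
  coll <- data.frame(x = 1:5, y = 1:5, z = 0, ground = TRUE)
  expect_error(rasterize_dtm(coll, 0.5), "collinear")
})

test_that("CHM subtracts, clips negatives, propagates nodata, shift-invariant", {
  dsm <- surface_raster(matrix(c(2, NA, 0.95, 3), 2, 2), 1, c(0, 2))
  dtm <- surface_raster(matrix(c(0, 0, 1, 1), 2, 2), 1, c(0, 2))
  chm <- canopy_height(dsm, dtm)
  expect_equal(chm$values[1, 1], 2)
  expect_true(is.na(chm$values[2, 1]))
  expect_equal(chm$values[1, 2], 0)    # 0.95 - 1 clipped
  expect_equal(chm$values[2, 2], 2)
  # adding a constant to all z leaves the CHM unchanged
  dsm2 <- dsm; dsm2$values <- dsm2$values + 7.5
  dtm2 <- dtm; dtm2$values <- dtm2$values + 7.5
  expect_equal(canopy_height(dsm2, dtm2)$values, chm$values)
  bad <- surface_raster(matrix(0, 3, 3), 1, c(0, 2))
  expect_error(canopy_height(dsm, bad), "match")
})

test_that("intensity raster takes the highest point's intensity by default", {
  pts <- data.frame(x = c(0.2, 0.2, 0.7), y = c(-0.2, -0.2, -0.2),
                    z = c(1, 2, 1), intensity = c(10, 50, 7), ground = FALSE)
  r <- rasterize_intensity(pts, cell_size = 0.5, origin = c(0, 0), dims = c(1, 2))
  expect_equal(r$values[1, 1], 50)
  expect_equal(r$values[1, 2], 7)
  # alternative rule: maximum intensity in the cell
  pts2 <- rbind(pts, data.frame(x = 0.2, y = -0.2, z = 0.5, intensity = 99,
                                ground = FALSE))
  r2 <- rasterize_intensity(pts2, 0.5, c(0, 0), c(1, 2), rule = "max_intensity")
  expect_equal(r2$values[1, 1], 99)
})

test_that("end-to-end surfaces recover the planted canopy height", {
  sc <- cached("pc_scene", function()
    simulate_field(n_plots = 4, plots_per_block = 2, n_bands = 12, seed = 13))
  pts <- generate_pointcloud(sc, density = 900, seed = 13)
  s <- lidar_surfaces(pts, cell_size = 0.06)
  for (i in seq_len(4)) {
    px <- sc$plots[i, ]
    cc <- maizefuse:::cell_centers(s$chm)
    sel <- cc$x >= px$xmin & cc$x <= px$xmax & cc$y >= px$ymin & cc$y <= px$ymax
    v <- s$chm$values[sel]
    p90 <- quantile(v[!is.na(v)], 0.9)
    expect_lt(abs(p90 - sc$planted$canopy_height[i]), 0.15)
  }
  # canopy cells carry higher intensity than ground returns, as planted
  expect_gt(mean(s$intensity$values[s$chm$values > 0.5], na.rm = TRUE),
            mean(pts$intensity[pts$ground]))
})
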