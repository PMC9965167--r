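test_that("polygon windows cover the polygon plus margin and clip at edges", {
  r <- surface_raster(matrix(0, 100, 100), cell_size = 1, origin = c(0, 100))
  one <- list(xmin = 3, xmax = 4, ymin = 96, ymax = 97)
  w <- polygon_window(r, one, margin = 0)
  expect_equal(length(w$rows), 1); expect_equal(length(w$cols), 1)

  w2 <- polygon_window(r, one, margin = 3)
  expect_equal(length(w2$rows), 7); expect_equal(length(w2$cols), 7)

  edge <- list(xmin = 0, xmax = 2, ymin = 98, ymax = 100)
  w3 <- polygon_window(r, edge, margin = 5)   # clipped at the raster corner
  expect_equal(w3$rows[1], 1); expect_equal(w3$cols[1], 1)

  outside <- list(xmin = 200, xmax = 210, ymin = 0, ymax = 5)
  expect_error(polygon_window(r, outside), "overlap")
})

test_that("a 5.33 m x 0.76 m plot at 3 cm spans at least 176 x 25 pixels", {
  sc <- small_scene()
  grid <- scene_raster(sc, "height")
  w <- polygon_window(grid, sc$plots[1, ], margin = 0)
  expect_gte(length(w$rows), 176)   # plot length (north-south)
  expect_gte(length(w$cols), 25)    # plot width
})

test_that("segmentation recovers truth masks on separable chips across seeds", {
  sc <- small_scene()
  for (s in 1:10) {
    i <- (s %% nrow(sc$plots)) + 1
    cs <- chip_set(sc, sc$plots$plot_id[i], margin = 5)
    mask <- segment_vegetation(cs, seed = s)
    truth <- truth_mask(sc, sc$plots$plot_id[i], margin = 5)
    expect_gte(mean(mask == truth), 0.95)
  }
})

test_that("degenerate chips label everything vegetation with a warning", {
  chips <- list(hyper = array(0.5, c(4, 4, 6)), height = matrix(1, 4, 4),
                intensity = matrix(2, 4, 4), thermal = matrix(25, 4, 4),
                wavelengths = seq(400, 1000, length.out = 6))
  expect_warning(m <- segment_vegetation(chips, seed = 1), "degenerate")
  expect_true(all(m))
})

test_that("vegetation labelling follows NIR, not cluster index", {
  sc <- small_scene()
  cs <- chip_set(sc, sc$plots$plot_id[2], margin = 5)
  m1 <- segment_vegetation(cs, seed = 1)
  m2 <- segment_vegetation(cs, seed = 99)   # different k-means++ init order
  expect_gt(mean(m1 == m2), 0.99)
  truth <- truth_mask(sc, sc$plots$plot_id[2], margin = 5)
  expect_gt(mean(cs$hyper[, , 35][m1]), mean(cs$hyper[, , 35][!m1]))
  expect_gte(mean(m1 == truth), 0.95)
})

test_that("masked_mean obeys its contract", {
  b <- matrix(c(1, 3, 100, NA), 2, 2)
  m <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(masked_mean(b, m), 2)
  expect_equal(masked_mean(matrix(7, 3, 3), matrix(TRUE, 3, 3)), 7)
  # unmasked pixel values are irrelevant
  b2 <- b; b2[3] <- -999
  expect_equal(masked_mean(b2, m), masked_mean(b, m))
  # nodata excluded from the mean
  m3 <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  expect_equal(masked_mean(b, m3), 2)
  expect_error(masked_mean(b, matrix(FALSE, 2, 2)), "empty")
})

test_that("standardization round-trips and fits on training rows only", {
  set.seed(8)
  x <- matrix(rnorm(60, 10, 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  st <- standardize(x)
  expect_equal(unname(colMeans(st$scaled)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(st$scaled, 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_equal(invert_scaler(st$scaler, st$scaled), x, tolerance = 1e-12)

  st_tr <- standardize(x, fit_rows = 1:10)
  # leakage check: perturbing held-out rows leaves the scaler unchanged
  x2 <- x; x2[15:20, ] <- x2[15:20, ] + 100
  st_tr2 <- standardize(x2, fit_rows = 1:10)
  expect_identical(st_tr$scaler, st_tr2$scaler)

  # constant shift of a column moves only its mean parameter
  x3 <- x; x3[, 2] <- x3[, 2] + 5
  st3 <- standardize(x3)
  expect_equal(st3$scaler$sd, st$scaler$sd, tolerance = 1e-12)
  expect_equal(st3$scaler$mean[2] - st$scaler$mean[2], 5, ignore_attr = TRUE)

  xz <- cbind(x, d = 1)
  expect_error(standardize(xz), "d")
})

test_that("prep assembles a complete band-mean stack", {
  prep <- small_prep()
  M <- prep$band_stack$M
  expect_equal(dim(M), c(12, 40 + 3))
  expect_false(anyNA(M))
  expect_true(all(prep$accuracy >= 0.95))
  expect_identical(colnames(M)[41:43], c("height", "intensity", "thermal"))
  # dropping one band yields the 269-of-270 style reduced stack
  prep269 <- prep_plots(small_scene(), margin = 5, seed = 3,
                        use_truth_mask = TRUE, drop_band = 1)
  expect_equal(ncol(prep269$band_stack$M), 39 + 3)
})
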