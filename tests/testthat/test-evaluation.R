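test_that("regression metrics implement the printed formulas", {
  y <- c(1, 2, 3, 4); yh <- y
  m <- regression_metrics(y, yh)
  expect_equal(m$r2, 1); expect_equal(m$rmse, 0); expect_equal(m$mae, 0)

  m2 <- regression_metrics(y, rep(mean(y), 4))
  expect_equal(m2$r2, 0)

  # residuals {1, -1} at n = 2: MAE 1, RMSE with n-1 denominator = sqrt(2)
  m3 <- regression_metrics(c(1, 2), c(2, 1))
  expect_equal(m3$mae, 1)
  expect_equal(m3$rmse, sqrt(2))
  expect_equal(regression_metrics(c(1, 2), c(2, 1), rmse_denom = "n")$rmse, 1)
  expect_error(regression_metrics(c(1, 1), c(1, 2)), "constant")
})

test_that("printed (n-1) RMSE strictly exceeds the conventional form", {
  set.seed(16)
  for (i in 1:10) {
    y <- rnorm(sample(3:50, 1)); yh <- y + rnorm(length(y))
    expect_gt(regression_metrics(y, yh)$rmse,
              regression_metrics(y, yh, rmse_denom = "n")$rmse)
    m <- regression_metrics(y, yh)
    expect_gte(m$rmse, m$mae)   # RMSE >= MAE for the same residuals
  }
})

test_that("cv recomputation reproduces the published-style summary cells", {
  # mean/sd pairs with self-consistent printed rounding
  expect_equal(round(100 * 2153.74 / 6510.82, 1), 33.1)  # dry stalk biomass
  expect_equal(round(100 * 498.90 / 1470.71, 1), 33.9)   # cob biomass
  expect_equal(round(100 * 3300.98 / 7176.92), 46)       # dry grain yield
  expect_equal(round(100 * 0.038 / 1.27), 3)             # grain density
  d <- describe_traits(data.frame(x = c(1, 2, 3), y = c(2, 2, 2)))
  expect_equal(d$cv_pct[1], 100 * sd(c(1, 2, 3)) / 2)
  expect_equal(d$sd[2], 0); expect_equal(d$cv_pct[2], 0)
  expect_equal(d$q50[1], 2)
})

test_that("Moran weights are row-standardized kNN", {
  set.seed(17)
  xy <- cbind(runif(30), runif(30))
  W <- moran_weights(xy, k = 5)
  expect_equal(unname(Matrix::rowSums(W)), rep(1, 30), tolerance = 1e-12)
  expect_equal(unname(Matrix::diag(W)), rep(0, 30))
  expect_error(moran_weights(xy[1:3, ]), "at least 4")
})

test_that("Moran's I null behaviour: mean near -1/(n-1), scale invariance", {
  set.seed(18)
  d <- generate_design(10, 5, seed = 18)
  xy <- plot_centroids(d)
  z <- rnorm(50)
  mi <- morans_i(z, xy, n_permutations = 4999, seed = 18)
  expect_lt(abs(mean(mi$perm_i) - (-1 / 49)), 0.008)
  mi2 <- morans_i(z * 7.3, xy, n_permutations = 99, seed = 18)
  expect_equal(mi2$i, mi$i, tolerance = 1e-12)   # positive scaling invariance
  expect_error(morans_i(rep(1, 50), xy), "constant")
})

test_that("Moran's I matches the analytic statistic of an independent oracle", {
  skip_if_not_installed("ape")
  set.seed(19)
  d <- generate_design(8, 4, seed = 19)
  xy <- plot_centroids(d)
  z <- rnorm(32)
  W <- as.matrix(moran_weights(xy, k = 6))
  ours <- morans_i(z, xy, k = 6, n_permutations = 99, seed = 1)$i
  oracle <- ape::Moran.I(z, W, scaled = FALSE)$observed
  expect_equal(ours, oracle, tolerance = 1e-10)
})

test_that("block-clustered residuals are detected; permuted ones are not", {
  d <- generate_design(16, 4, seed = 20)
  xy <- plot_centroids(d)
  z <- ifelse(xy[, 2] > median(xy[, 2]), 1, -1) + rnorm(64, 0, 0.1)
  set.seed(20)
  mi <- morans_i(z, xy, n_permutations = 4999, seed = 20)
  expect_gt(mi$i, 0.5)
  expect_lt(mi$p_value, 0.001)
  expect_true(mi$significant)
  # destroying the structure removes the signal
  mi0 <- morans_i(sample(z), xy, n_permutations = 999, seed = 21)
  expect_gt(mi0$p_value, 0.01)
})

test_that("prediction maps join values, compute residuals and round-trip", {
  d <- generate_design(4, 3, seed = 22)
  ph <- sample_trait_population(d, seed = 22)
  pred <- data.frame(plot_id = d$plot_id, measured = ph$dry_grain_yield,
                     predicted = ph$dry_grain_yield * 0.9 + 100)
  mp <- prediction_map(pred, d)
  expect_equal(mp$residual, mp$measured - mp$predicted)
  hi <- mp$treatment == "high_N"
  expect_gt(mean(mp$predicted[hi]), mean(mp$predicted[!hi]))

  f <- tempfile(fileext = ".geojson")
  write_prediction_map(mp, f)
  back <- jsonlite::read_json(f, simplifyVector = FALSE)
  vals <- vapply(back$features, function(x) x$properties$predicted, numeric(1))
  expect_equal(vals, mp$predicted, tolerance = 1e-9)

  expect_error(prediction_map(pred[-1, ], d), "P0001")
  p <- plot_prediction_map(mp)
  expect_s3_class(p, "ggplot")
})
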