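flat_spectrum <- function(c0 = 0.4, n = 61) {
  list(s = rep(c0, n), wl = seq(400, 1000, length.out = n))
}

test_that("band lookup is nearest-with-lower-tie and range-checked", {
  wl <- c(669.9, 672.1, 800)
  s <- c(0.1, 0.2, 0.3)
  expect_equal(reflectance_at(s, wl, 670), 0.1)      # 670 closer to 669.9
  expect_equal(reflectance_at(s, wl, 671), 0.1)      # exact tie -> lower
  expect_equal(reflectance_at(s, wl, 800), 0.3)
  expect_error(reflectance_at(s, wl, 1100, index = "WI"), "WI")
})

test_that("NDVI and friends evaluate the tabulated formulas", {
  wl <- seq(400, 1000, length.out = 121)   # 5 nm sampling, all targets exact
  s <- rep(0.2, 121)
  s[wl == 860] <- 0.5; s[wl == 670] <- 0.1
  vi <- hyperspectral_indices(s, wl)
  expect_equal(unname(vi["NDVI"]), (0.5 - 0.1) / (0.5 + 0.1))
  f <- flat_spectrum()
  vif <- hyperspectral_indices(f$s, f$wl)
  expect_equal(unname(vif["NDVI"]), 0)
  expect_equal(unname(vif["SR"]), 1)
  expect_equal(unname(vif["FRI2"]), 1)
  expect_equal(unname(vif["RGI"]), 1)
  expect_equal(unname(vif["PRI"]), 0)
  expect_equal(unname(vif["FCI"]), 1)
  expect_equal(unname(vif["RVS1"]), 0)
  # printed three-band GNDVI variant on the flat spectrum: (c)/(c) = 1
  expect_equal(unname(vif["GNDVI"]), 1)
  expect_length(vi, 34)
})

test_that("normalized-difference indices stay within [-1, 1]", {
  set.seed(12)
  wl <- seq(400, 1000, length.out = 61)
  for (i in 1:20) {
    vi <- hyperspectral_indices(runif(61, 0.01, 0.9), wl)
    for (nm in c("NDVI", "CI", "NRI", "PRI", "NCPI", "PPR", "RNDVI", "NPQI",
                 "WSCT"))
      expect_lte(abs(vi[[nm]]), 1)
  }
})

test_that("distribution metrics match hand-derived values on {1,2,3,4,100}", {
  v <- c(1, 2, 3, 4, 100)
  m <- distribution_metrics(v, "H", n_canopy = 10, n_ground = 5)
  expect_length(m, 30)
  expect_equal(unname(m["Hmad"]), 1.4826)          # median 3, |dev| median 1
  expect_equal(unname(m["Hcrr"]), 21 / 99)         # (22 - 1)/(100 - 1)
  expect_equal(unname(m["Hmax"]), 100)
  expect_equal(unname(m["Hmean"]), 22)
  expect_equal(unname(m["Hiqr"]), unname(quantile(v, .75) - quantile(v, .25)))
  expect_equal(unname(m["Hcg"]), 2)
  expect_equal(unname(m["Haad"]), mean(abs(v - 22)))
})

test_that("percentile metrics agree with a brute-force sort oracle", {
  set.seed(13)
  for (i in 1:20) {
    v <- rnorm(sample(10:1000, 1))
    m <- distribution_metrics(v, "I", n_canopy = 1, n_ground = 1)
    sv <- sort(v)
    for (p in c(10, 20, 30, 40, 50, 60, 70, 80, 90, 95, 98, 99)) {
      # type-7 linear interpolation between order statistics
      h <- (length(sv) - 1) * p / 100
      oracle <- sv[floor(h) + 1] + (h - floor(h)) *
        (sv[min(floor(h) + 2, length(sv))] - sv[floor(h) + 1])
      expect_equal(unname(m[paste0("I", p)]), oracle, tolerance = 1e-12)
    }
    expect_equal(unname(m["Iskn"]),
                 mean((v - mean(v))^3) / mean((v - mean(v))^2)^1.5)
    expect_equal(unname(m["Ikurt"]),
                 mean((v - mean(v))^4) / mean((v - mean(v))^2)^2 - 3)
  }
})

test_that("canopy-return densities sit near their nominal levels", {
  set.seed(14)
  v <- runif(1e5)
  m <- distribution_metrics(v, "H", n_canopy = 1, n_ground = 1)
  expect_equal(unname(m["Hd50"]), 0.5, tolerance = 0.01)
  expect_equal(unname(m["Hd90"]), 0.1, tolerance = 0.01)
})

test_that("location metrics shift with a constant offset; spread does not", {
  set.seed(15)
  v <- rnorm(500, 2, 0.3)
  m0 <- distribution_metrics(v, "H", n_canopy = 1, n_ground = 1)
  m1 <- distribution_metrics(v + 5, "H", n_canopy = 1, n_ground = 1)
  for (nm in c("Hmax", "Hmin", "Hmean", "H50", "H95"))
    expect_equal(unname(m1[nm] - m0[nm]), 5, tolerance = 1e-9)
  for (nm in c("Hsd", "Hmad", "Haad", "Hiqr", "Hskn", "Hkurt"))
    expect_equal(unname(m1[nm]), unname(m0[nm]), tolerance = 1e-9)
})

test_that("constant input falls back to zero cv/relief with a warning", {
  expect_warning(m <- distribution_metrics(rep(2, 10), "H",
                                           n_canopy = 1, n_ground = 1),
                 "constant")
  expect_equal(unname(m["Hcv"]), 0)
  expect_equal(unname(m["Hcrr"]), 0)
  expect_error(distribution_metrics(1, "H"), "at least 2")
})

test_that("thermal index implements both printed and conventional forms", {
  expect_equal(thermal_index(30, 20, 40, "printed"), -1)
  expect_equal(thermal_index(30, 20, 40, "normalized"), 0.5)
  expect_equal(thermal_index(20, 20, 40, "normalized"), 0)
  expect_true(is.na(thermal_index(40, 20, 40, "printed")))
  expect_error(thermal_index(30, 40, 20), "exceed")
})

test_that("the feature table has exactly the 34/30/30/1 layout", {
  fx <- small_features()
  expect_equal(ncol(fx), 95)
  expect_false(anyDuplicated(colnames(fx)) > 0)
  reg <- feature_registry()
  expect_equal(nrow(reg), 95)
  expect_equal(as.vector(table(reg$modality)[c("hyperspectral", "height",
                                               "intensity", "thermal")]),
               c(34, 30, 30, 1))
  expect_identical(colnames(fx), reg$name)
  expect_false(anyNA(fx))
})
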