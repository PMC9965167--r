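# small chips + targets for fast network tests (window 24 x 10, 6 bands)
tiny_prep <- function() cached("tiny_prep", function() {
  d <- generate_design(4, 2, seed = 21, plot_length = 0.9, plot_width = 0.42)
  ph <- sample_trait_population(d, seed = 21)
  sc <- render_scene(d, ph, default_render_spec(n_bands = 12), seed = 21)
  prep_plots(sc, margin = 2, seed = 21, use_truth_mask = TRUE)
})
tiny_cfg <- function(...) default_train_config(window = c(24, 10), bins = 6,
                                               batch_size = 4, ...)

test_that("Huber loss branches, continuity and MSE relation", {
  expect_equal(huber_loss(0, 0.5, delta = 1), 0.125)
  expect_equal(huber_loss(0, 2, delta = 1), 1.5)
  expect_equal(huber_loss(0, 1, delta = 1), 0.5)            # both branches
  expect_equal(huber_loss(0, 1 + 1e-12, delta = 1), 0.5, tolerance = 1e-9)
  r <- seq(-0.99, 0.99, by = 0.01)
  expect_equal(huber_loss(0, r, delta = 1), r^2 / 2)        # = MSE/2 inside
  r2 <- c(-5, -2, 1.5, 3)
  expect_true(all(huber_loss(0, r2, delta = 1) < r2^2 / 2)) # strictly below
  expect_error(huber_loss(0, 1, delta = 0), "delta")
})

test_that("crop offsets are identical across modalities and deterministic", {
  dims <- list(P1 = c(30, 14), P2 = c(28, 12))
  o1 <- augment_offsets(dims, window = c(24, 10), n_crops = 20, seed = 5)
  o2 <- augment_offsets(dims, window = c(24, 10), n_crops = 20, seed = 5)
  expect_identical(o1, o2)   # the shared-seed contract: one draw, all modalities
  expect_equal(nrow(o1), 40)
  expect_true(all(o1$row_off >= 0 & o1$row_off <= 6))
  expect_true(all(o1$col_off >= 0 & o1$col_off <= 4))

  # chip exactly window-sized -> all crops at offset zero
  o3 <- augment_offsets(list(P = c(24, 10)), window = c(24, 10), n_crops = 20,
                        seed = 1)
  expect_true(all(o3$row_off == 0 & o3$col_off == 0))
  expect_error(augment_offsets(list(P = c(20, 10)), window = c(24, 10)),
               "smaller")
})

test_that("network construction follows the stream and fusion contract", {
  n3 <- build_network(c("hyperspectral", "lidar_height", "lidar_intensity",
                        "thermal"), n_tasks = 8, seed = 2)
  expect_equal(length(n3$streams), 3)          # lidar channels share a stream
  expect_equal(n3$n_fused, 192)
  expect_equal(dim(n3$head$W2), c(32, 8))
  n1 <- build_network("hyperspectral", n_tasks = 1, seed = 2)
  expect_equal(n1$n_fused, 64)
  n4 <- build_network(c("hyperspectral", "lidar_height", "lidar_intensity"),
                      n_tasks = 2, stack_lidar = FALSE, seed = 2)
  expect_equal(length(n4$streams), 3)
  expect_error(build_network(character(0), 1), "at least one")
  expect_error(build_network("hyperspectral", 0), "n_tasks")
  # filter ladder 8-16-32-64 with 3x3(x7) kernels
  dims_w <- lapply(n3$streams$hyper$layers, function(l) dim(l$w))
  expect_equal(vapply(dims_w, function(d) d[5], numeric(1)), c(8, 16, 32, 64))
  expect_equal(dims_w[[1]][1:3], c(3, 3, 7))
})

test_that("mono- and multi-task builds share stream weights at initialization", {
  m1 <- build_network(c("hyperspectral", "thermal"), n_tasks = 1, seed = 11)
  m8 <- build_network(c("hyperspectral", "thermal"), n_tasks = 8, seed = 11)
  expect_identical(m1$streams$hyper$layers, m8$streams$hyper$layers)
  expect_identical(m1$streams$thermal$layers, m8$streams$thermal$layers)
  expect_false(identical(dim(m1$head$W2), dim(m8$head$W2)))
})

test_that("zeroing one modality changes only that stream's fused block", {
  net <- build_network(c("hyperspectral", "thermal"), n_tasks = 2, bins = 6,
                       seed = 3)
  set.seed(1)
  x <- list(hyper = array(rnorm(24 * 10 * 6 * 1 * 2), c(24, 10, 6, 1, 2)),
            thermal = array(rnorm(24 * 10 * 1 * 1 * 2), c(24, 10, 1, 1, 2)))
  f1 <- maizefuse:::net_forward(net, x, train = FALSE)
  x2 <- x; x2$thermal[] <- 0
  f2 <- maizefuse:::net_forward(net, x2, train = FALSE)
  expect_identical(f1$fused[1:64, ], f2$fused[1:64, ])        # hyper block
  expect_false(identical(f1$fused[65:128, ], f2$fused[65:128, ]))
})

test_that("the network memorizes a tiny dataset (overfit sanity check)", {
  prep <- tiny_prep()
  split <- list(train = 1:8, val = 1:8, test = 1:8)
  cfg <- tiny_cfg(max_epochs = 60, n_crops = 0, dropout = 0, lr = 0.003,
                  patience = NULL, seed = 5)
  fit <- train_fusion_net(prep, tasks = c("dry_grain_yield", "total_plant_n"),
                          modalities = c("hyperspectral", "lidar_height",
                                         "lidar_intensity"),
                          config = cfg, split = split)
  expect_lt(tail(fit$history$train_loss, 1), 0.05)
  preds <- predict_fusion_net(fit, prep)
  expect_true(all(is.finite(preds)))
  expect_equal(dim(preds), c(8, 2))
})

test_that("training is deterministic per seed and aborts on bad targets", {
  prep <- tiny_prep()
  split <- list(train = 1:4, val = 5:6, test = 7:8)
  cfg <- tiny_cfg(max_epochs = 2, n_crops = 2, seed = 9)
  f1 <- train_fusion_net(prep, tasks = "dry_grain_yield",
                         modalities = "hyperspectral", config = cfg,
                         split = split)
  f2 <- train_fusion_net(prep, tasks = "dry_grain_yield",
                         modalities = "hyperspectral", config = cfg,
                         split = split)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$net$head$W2, f2$net$head$W2)
  bad <- matrix(NA_real_, 8, 1, dimnames = list(NULL, "dry_grain_yield"))
  expect_error(train_fusion_net(prep, tasks = "dry_grain_yield",
                                modalities = "hyperspectral", config = cfg,
                                split = split, targets = bad,
                                scale_targets = FALSE))
})

test_that("no plot contributes crops to more than one split", {
  prep <- tiny_prep()
  d <- prep$design
  split <- stratified_split(as.character(d$treatment),
                            fractions = c(0.5, 0.25, 0.25), seed = 4)
  expect_length(intersect(split$train, split$val), 0)
  expect_length(intersect(split$train, split$test), 0)
  expect_length(intersect(split$val, split$test), 0)
  # augmented sample list references training plots only
  cfg <- tiny_cfg(max_epochs = 1, n_crops = 3, seed = 4)
  fit <- train_fusion_net(prep, tasks = "dry_grain_yield",
                          modalities = "hyperspectral", config = cfg,
                          split = split)
  expect_setequal(fit$split$train, split$train)
})

test_that("inverse-standardization of predictions round-trips", {
  y <- matrix(rnorm(20, 100, 10), 10, 2,
              dimnames = list(NULL, c("a", "b")))
  st <- standardize(y)
  expect_equal(invert_scaler(st$scaler, st$scaled), y, tolerance = 1e-12)
})
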