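make_linear_problem <- function(n = 80, p = 6, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  list(x = x, y = as.numeric(x[, 1] * 2 - x[, 3] + 0.5))
}

small_space <- function() {
  list(svr = list(cost = c(1, 10), kernel = c("radial", "linear"),
                  gamma_mult = 1, epsilon = 0.1),
       rfr = list(num_trees = c(100), max_depth = c(0, 10), min_node = c(1, 5)),
       folds = 5)
}

test_that("SVR grid search picks the linear kernel for a noiseless linear target", {
  pr <- make_linear_problem()
  fit <- fit_with_search(pr$x[1:60, ], pr$y[1:60], "svr",
                         space = small_space(), seed = 2)
  expect_equal(fit$best$kernel, "linear")
  yh <- predict(fit, pr$x[61:80, ])
  expect_gt(regression_metrics(pr$y[61:80], yh)$r2, 0.95)
})

test_that("search is deterministic and a single-point grid is returned as-is", {
  pr <- make_linear_problem(seed = 3)
  sp <- list(svr = list(cost = 5, kernel = "radial", gamma_mult = 1,
                        epsilon = 0.1), rfr = small_space()$rfr, folds = 5)
  fit <- fit_with_search(pr$x, pr$y, "svr", space = sp, seed = 7)
  expect_equal(fit$best$cost, 5)
  expect_equal(fit$best$kernel, "radial")
  f1 <- fit_with_search(pr$x, pr$y, "rfr", space = small_space(), seed = 7)
  f2 <- fit_with_search(pr$x, pr$y, "rfr", space = small_space(), seed = 7)
  expect_identical(f1$best, f2$best)
  expect_identical(predict(f1, pr$x), predict(f2, pr$x))
  expect_error(fit_with_search(pr$x, rep(1, nrow(pr$x)), "rfr"), "degenerate")
})

test_that("MDI importance concentrates on a planted feature and sums to one", {
  set.seed(4)
  x <- matrix(rnorm(150 * 5), 150, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- x[, 4]
  fit <- fit_with_search(x, y, "rfr", space = small_space(), seed = 4)
  imp <- mdi_importance(fit, top = Inf)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_equal(imp$feature[1], "f4")
  expect_gt(imp$importance[1], 0.9)
  expect_error(mdi_importance(fit_with_search(x, y, "svr",
                                              space = small_space())),
               "random forest")
})

test_that("pure-noise features get near-uniform small importances", {
  set.seed(5)
  x <- matrix(rnorm(200 * 8), 200, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- rnorm(200)
  fit <- fit_with_search(x, y, "rfr", space = small_space(), seed = 5)
  imp <- mdi_importance(fit, top = Inf)
  expect_lt(max(imp$importance), 0.3)
  expect_gt(min(imp$importance), 0.02)
})

test_that("the canonical seven modality feature sets are well formed", {
  fx <- small_features()
  sets <- modality_feature_sets(colnames(fx))
  expect_identical(names(sets),
                   c("thermal", "inten", "dsm", "hyper", "hyper_dsm",
                     "hyper_dsm_inten", "hyper_dsm_inten_thermal"))
  expect_length(sets$thermal, 1)
  expect_length(sets$inten, 30)
  expect_length(sets$dsm, 30)
  expect_length(sets$hyper, 34)
  expect_length(sets$hyper_dsm_inten_thermal, 95)
})

test_that("bootstrap evaluation is leakage-free and structured", {
  fx <- small_features()
  prep <- small_prep()
  traits <- as.data.frame(prep$phenotypes)[, c("dry_grain_yield",
                                               "grain_density")]
  rep1 <- bootstrap_evaluate(fx, traits, prep$design$treatment,
                             feature_sets = list(hyper = modality_feature_sets(colnames(fx))$hyper),
                             regressors = "rfr", n_shuffles = 2,
                             space = small_space(), seed = 5)
  expect_setequal(unique(rep1$raw$split), c("train", "val", "test"))
  expect_equal(nrow(rep1$raw), 2 * 1 * 2 * 3)
  expect_true(all(rep1$summary$r2_sd >= 0))

  # single shuffle -> zero dispersion
  rep2 <- bootstrap_evaluate(fx, traits["dry_grain_yield"],
                             prep$design$treatment,
                             feature_sets = list(hyper = modality_feature_sets(colnames(fx))$hyper),
                             regressors = "rfr", n_shuffles = 1,
                             space = small_space(), seed = 5)
  expect_true(all(rep2$summary$r2_sd == 0 | is.na(rep2$summary$r2_sd)))

  # perturbing test rows does not change a fit trained on the same split
  sp <- stratified_split(as.character(prep$design$treatment), seed = 1005)
  keep <- apply(fx[sp$train, ], 2, sd) > 0
  sc1 <- standardize(fx[, keep], fit_rows = sp$train)
  fx2 <- fx; fx2[sp$test, ] <- fx2[sp$test, ] * 3 + 11
  sc2 <- standardize(fx2[, keep], fit_rows = sp$train)
  expect_identical(sc1$scaler, sc2$scaler)
  f1 <- fit_with_search(sc1$scaled[sp$train, ], traits$dry_grain_yield[sp$train],
                        "rfr", space = small_space(), seed = 2)
  f2 <- fit_with_search(sc2$scaled[sp$train, ], traits$dry_grain_yield[sp$train],
                        "rfr", space = small_space(), seed = 2)
  expect_identical(f1$best, f2$best)
  expect_identical(predict(f1, sc1$scaled[sp$val, ]),
                   predict(f2, sc2$scaled[sp$val, ]))
})

test_that("stratified split keeps both treatments in every part", {
  strata <- rep(c("low_N", "high_N"), each = 15)
  sp <- stratified_split(strata, seed = 3)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), 1:30)
  for (part in sp) expect_setequal(unique(strata[part]), c("low_N", "high_N"))
  expect_error(stratified_split(strata[1:4]), "fewer than 2")
})
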