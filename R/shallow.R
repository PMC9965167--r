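#' Default hyperparameter search space for the shallow baselines
#'
#' SVR: cost grid, radial/linear kernels, gamma as multiples of the scale
#' heuristic `1 / (p * mean pixel variance)`, epsilon-tube 0.1 on
#' standardized targets. RFR: tree count, maximum depth (0 = unlimited) and
#' minimum leaf size grids. Scored by 5-fold inner cross-validation.
#'
#' @param folds inner CV folds (>= 2)
#' @return list with `svr`, `rfr` grids and `folds`
#' @export
default_search_space <- function(folds = 5) {
  if (folds < 2) stop("folds must be >= 2")
  list(svr = list(cost = c(0.1, 1, 10, 100),
                  kernel = c("radial", "linear"),
                  gamma_mult = c(0.1, 1, 10),
                  epsilon = 0.1),
       rfr = list(num_trees = c(100, 300, 500),
                  max_depth = c(0, 10, 20),
                  min_node = c(1, 3, 5)),
       folds = folds)
}

svr_grid <- function(space) {
  g <- expand.grid(cost = space$svr$cost, kernel = space$svr$kernel,
                   gamma_mult = space$svr$gamma_mult, stringsAsFactors = FALSE)
  g$gamma_mult[g$kernel == "linear"] <- 1   # gamma is inert for linear kernels
  unique(g)
}

rfr_grid <- function(space) {
  expand.grid(num_trees = space$rfr$num_trees, max_depth = space$rfr$max_depth,
              min_node = space$rfr$min_node)
}

fit_one <- function(x, y, regressor, cfg, seed) {
  if (regressor == "svr") {
    gamma0 <- 1 / (ncol(x) * max(mean(apply(x, 2, var)), 1e-12))
    e1071::svm(x, y, type = "eps-regression", kernel = cfg$kernel,
               cost = cfg$cost, gamma = gamma0 * cfg$gamma_mult,
               epsilon = 0.1, scale = FALSE)
  } else {
    # all features offered at every split (the common regression-forest
    # default in scikit-learn-style pipelines)
    ranger::ranger(x = x, y = y, num.trees = cfg$num_trees,
                   mtry = ncol(x),
                   max.depth = if (cfg$max_depth == 0) NULL else cfg$max_depth,
                   min.node.size = cfg$min_node, importance = "impurity",
                   seed = seed, num.threads = 1)
  }
}

predict_one <- function(model, x) {
  if (inherits(model, "ranger")) predict(model, data = x,
                                         num.threads = 1)$predictions
  else as.numeric(predict(model, x))
}

#' Fit an SVR or RFR with exhaustive inner-CV grid search
#'
#' Every grid point is scored by k-fold cross-validated R-squared on the
#' training data; the best setting (ties to the first grid row) is refit on
#' the full training split. Fold assignment and forest growth are
#' deterministic for a fixed seed.
#'
#' @param x standardized feature matrix (training split only)
#' @param y target vector
#' @param regressor "svr" or "rfr"
#' @param space see [default_search_space()]
#' @param seed integer seed
#' @return list of class `shallow_fit`: `model`, `regressor`, `best`
#'   (chosen grid row), `cv` (grid with mean CV R^2)
#' @export
fit_with_search <- function(x, y, regressor = c("svr", "rfr"),
                            space = default_search_space(), seed = 1) {
  regressor <- match.arg(regressor)
  x <- as.matrix(x)
  if (sd(y) == 0) stop("degenerate (constant) target")
  n <- nrow(x)
  if (n < space$folds) stop("fewer samples than folds")
  grid <- if (regressor == "svr") svr_grid(space) else rfr_grid(space)
  set.seed(substream_seed(seed, "cvfolds"))
  fold <- sample(rep(seq_len(space$folds), length.out = n))
  scores <- vapply(seq_len(nrow(grid)), function(gi) {
    cfg <- grid[gi, , drop = FALSE]
    r2 <- vapply(seq_len(space$folds), function(f) {
      tr <- fold != f
      m <- fit_one(x[tr, , drop = FALSE], y[tr], regressor, cfg, seed)
      yh <- predict_one(m, x[!tr, , drop = FALSE])
      1 - sum((yh - y[!tr])^2) / sum((y[!tr] - mean(y[!tr]))^2)
    }, numeric(1))
    mean(r2)
  }, numeric(1))
  best_i <- which.max(scores)
  best <- grid[best_i, , drop = FALSE]
  model <- fit_one(x, y, regressor, best, seed)
  structure(list(model = model, regressor = regressor, best = best,
                 cv = cbind(grid, cv_r2 = scores),
                 feature_names = colnames(x)),
            class = "shallow_fit")
}

#' @export
predict.shallow_fit <- function(object, newdata, ...) {
  predict_one(object$model, as.matrix(newdata))
}

#' Mean-decrease-impurity feature importance of a fitted forest
#'
#' Impurity importances normalized to sum to one, in descending order.
#'
#' @param fit a `shallow_fit` with `regressor == "rfr"`
#' @param top return only the leading features (default 10, Inf for all)
#' @return data.frame with `feature` and `importance`
#' @export
mdi_importance <- function(fit, top = 10) {
  if (!inherits(fit, "shallow_fit") || fit$regressor != "rfr")
    stop("MDI importance requires a fitted random forest")
  imp <- ranger::importance(fit$model)
  imp <- imp / sum(imp)
  ord <- order(imp, decreasing = TRUE)
  out <- data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
                    stringsAsFactors = FALSE)
  head(out, top)
}

#' The seven modality feature sets
#'
#' @param feature_names colnames of a [plot_features()] matrix
#' @return named list of feature-name vectors: thermal, inten, dsm, hyper,
#'   hyper_dsm, hyper_dsm_inten, hyper_dsm_inten_thermal
#' @export
modality_feature_sets <- function(feature_names) {
  reg <- feature_registry()
  by_mod <- split(reg$name, reg$modality)
  pick <- function(mods) intersect(unlist(by_mod[mods]), feature_names)
  list(thermal = pick("thermal"),
       inten = pick("intensity"),
       dsm = pick("height"),
       hyper = pick("hyperspectral"),
       hyper_dsm = pick(c("hyperspectral", "height")),
       hyper_dsm_inten = pick(c("hyperspectral", "height", "intensity")),
       hyper_dsm_inten_thermal = pick(c("hyperspectral", "height",
                                        "intensity", "thermal")))
}

#' Bootstrap evaluation of the shallow baselines
#'
#' For each of `n_shuffles` reshuffled stratified 60/20/20 splits, fits the
#' scaler and the grid search on the training split only, then scores
#' R-squared, RMSE and MAE on train, validation and test. Zero-variance
#' feature columns (as judged on the training rows) are dropped before
#' scaling. Targets are standardized on the training split for the SVR (the
#' epsilon tube assumes unit scale) and predictions are mapped back before
#' scoring.
#'
#' @param features plots x features matrix ([plot_features()])
#' @param traits data.frame of target traits (one column per trait)
#' @param treatment per-plot stratification factor
#' @param feature_sets named list of feature-name subsets
#'   ([modality_feature_sets()] gives the canonical seven)
#' @param regressors subset of c("svr", "rfr")
#' @param n_shuffles reshuffled splits (default 5)
#' @param space search space
#' @param seed integer seed
#' @return list of class `bootstrap_report`: `raw` (one row per trait x
#'   feature set x regressor x split x shuffle) and `summary` (mean and sd
#'   over shuffles)
#' @export
bootstrap_evaluate <- function(features, traits, treatment,
                               feature_sets = modality_feature_sets(colnames(features)),
                               regressors = c("svr", "rfr"), n_shuffles = 5,
                               space = default_search_space(), seed = 1) {
  stopifnot(!anyNA(features[, unlist(feature_sets)]), !anyNA(traits))
  raw <- list()
  for (sh in seq_len(n_shuffles)) {
    sp <- stratified_split(as.character(treatment), seed = seed + sh * 1000L)
    for (fs in names(feature_sets)) {
      X <- features[, feature_sets[[fs]], drop = FALSE]
      keep <- apply(X[sp$train, , drop = FALSE], 2, sd) > 0
      Xk <- X[, keep, drop = FALSE]
      sc <- standardize(Xk, fit_rows = sp$train)
      for (tn in names(traits)) {
        y <- traits[[tn]]
        ysc <- standardize(matrix(y, dimnames = list(NULL, tn)),
                           fit_rows = sp$train)
        for (rg in regressors) {
          yfit <- if (rg == "svr") ysc$scaled[sp$train, 1] else y[sp$train]
          fit <- fit_with_search(sc$scaled[sp$train, , drop = FALSE], yfit,
                                 regressor = rg, space = space,
                                 seed = seed + sh)
          for (spl in c("train", "val", "test")) {
            idx <- sp[[spl]]
            yh <- predict(fit, sc$scaled[idx, , drop = FALSE])
            if (rg == "svr")
              yh <- invert_scaler(ysc$scaler,
                                  matrix(yh, dimnames = list(NULL, tn)))[, 1]
            m <- regression_metrics(y[idx], yh)
            raw[[length(raw) + 1L]] <-
              data.frame(trait = tn, feature_set = fs, regressor = rg,
                         split = spl, shuffle = sh, r2 = m$r2, rmse = m$rmse,
                         mae = m$mae, n = m$n, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  raw <- do.call(rbind, raw)
  agg <- aggregate(cbind(r2, rmse, mae) ~ trait + feature_set + regressor + split,
                   data = raw, FUN = mean)
  sds <- aggregate(cbind(r2, rmse, mae) ~ trait + feature_set + regressor + split,
                   data = raw, FUN = sd)
  names(agg)[5:7] <- c("r2_mean", "rmse_mean", "mae_mean")
  agg$r2_sd <- sds$r2; agg$rmse_sd <- sds$rmse; agg$mae_sd <- sds$mae
  structure(list(raw = raw, summary = agg), class = "bootstrap_report")
}

#' Bar chart of bootstrap R-squared by feature set (per trait)
#' @param report a `bootstrap_report`
#' @param split which split to display
#' @return a ggplot object
#' @export
plot_bootstrap_report <- function(report, split = "test") {
  s <- report$summary[report$summary$split == split, ]
  ggplot2::ggplot(s, ggplot2::aes(x = feature_set, y = r2_mean,
                                  fill = regressor)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = r2_mean - r2_sd,
                                        ymax = r2_mean + r2_sd),
                           position = "dodge") +
    ggplot2::facet_wrap(~trait) +
    ggplot2::labs(x = NULL, y = expression(R^2)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
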