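#' Default training configuration for the fusion network
#'
#' Defaults follow common practice for small-sample CNN regression: Huber
#' threshold 1 on standardized targets, Adam starting at 0.001 with an
#' exponential decay of 0.9 every 5 epochs, a 60/20/20 plot-level split,
#' dropout 0.5 after the 32-unit layer, batch size 16, early stopping on
#' validation loss, 20 aligned random crops per training plot on a 176 x 25
#' pixel window, and hyperspectral band binning to 8 spectral bins to keep
#' single-CPU training fast.
#'
#' @param ... overrides of the documented defaults
#' @return a list of training parameters
#' @export
default_train_config <- function(...) {
  cfg <- list(delta = 1, lr = 0.001, lr_decay = 0.9, decay_every = 5,
              split = c(0.6, 0.2, 0.2), batch_size = 16, max_epochs = 30,
              dropout = 0.5, patience = 15, n_crops = 20,
              window = c(176, 25), bins = 8, seed = 1,
              steps_per_epoch = NULL, verbose = FALSE)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, ov)
  if (cfg$lr <= 0 || cfg$delta <= 0) stop("lr and delta must be > 0")
  if (abs(sum(cfg$split) - 1) > 1e-8) stop("split fractions must sum to 1")
  cfg
}

# per-channel affine normalization fitted on the training plots' chips
fit_chip_norm <- function(chips, train_idx) {
  hyper <- sapply(train_idx, function(i) apply(chips[[i]]$hyper, 3, mean))
  lidar <- sapply(train_idx, function(i) apply(chips[[i]]$lidar, 3, mean))
  hyper_px <- unlist(lapply(train_idx, function(i) as.vector(chips[[i]]$hyper)))
  list(hyper = list(mean = rowMeans(hyper), sd = max(stats::sd(hyper_px), 1e-6)),
       lidar = list(mean = rowMeans(as.matrix(lidar)),
                    sd = pmax(apply(sapply(train_idx, function(i)
                      apply(chips[[i]]$lidar, 3, stats::sd)), 1, mean), 1e-6)),
       thermal = list(mean = mean(sapply(train_idx, function(i)
                        mean(chips[[i]]$thermal))),
                      sd = max(mean(sapply(train_idx, function(i)
                        stats::sd(chips[[i]]$thermal))), 1e-6)))
}

apply_chip_norm <- function(chips, norm) {
  lapply(chips, function(ch) {
    h <- ch$hyper
    for (b in seq_len(dim(h)[3])) h[, , b] <- (h[, , b] - norm$hyper$mean[b]) / norm$hyper$sd
    l <- ch$lidar
    for (b in seq_len(dim(l)[3])) l[, , b] <- (l[, , b] - norm$lidar$mean[b]) / norm$lidar$sd[b]
    list(hyper = h, lidar = l,
         thermal = array((ch$thermal - norm$thermal$mean) / norm$thermal$sd,
                         dim = dim(ch$thermal)))
  })
}

# per-plot chip arrays for the network, band-binned once
net_chips <- function(prep, bins, margin = NULL) {
  margin <- margin %||% prep$margin
  d <- prep$design
  lapply(seq_len(nrow(d)), function(i) {
    cs <- chip_set(prep$scene, d$plot_id[i], margin = margin)
    list(hyper = bin_bands(cs$hyper, bins),
         lidar = array(c(cs$height, cs$intensity),
                       dim = c(dim(cs$height), 2)),
         thermal = array(cs$thermal, dim = c(dim(cs$thermal), 1)))
  })
}

# assemble one batch of aligned crops into per-stream 5-D arrays
make_batch <- function(net, chips, plot_idx, row_off, col_off, window) {
  N <- length(plot_idx)
  wh <- window[1]; ww <- window[2]
  out <- list()
  for (s in names(net$streams)) {
    st <- net$streams[[s]]
    if (st$kind == "3d") {
      D <- dim(chips[[plot_idx[1]]]$hyper)[3]
      arr <- array(0, dim = c(wh, ww, D, 1L, N))
      for (i in seq_len(N)) {
        r <- row_off[i]; cc <- col_off[i]
        arr[, , , 1L, i] <- chips[[plot_idx[i]]]$hyper[r + seq_len(wh),
                                                       cc + seq_len(ww), ]
      }
    } else {
      src <- if (identical(s, "thermal")) "thermal" else "lidar"
      ch_sel <- if (identical(src, "lidar")) {
        match(st$sources, c("lidar_height", "lidar_intensity"))
      } else 1L
      arr <- array(0, dim = c(wh, ww, 1L, length(ch_sel), N))
      for (i in seq_len(N)) {
        r <- row_off[i]; cc <- col_off[i]
        arr[, , 1L, , i] <- chips[[plot_idx[i]]][[src]][r + seq_len(wh),
                                                        cc + seq_len(ww),
                                                        ch_sel]
      }
    }
    out[[s]] <- arr
  }
  out
}

#' Train the multimodal multi-task fusion network
#'
#' Splits plots 60/20/20 stratified by treatment, standardizes the trait
#' targets on the training plots only, augments training plots with aligned
#' random crops (validation and test always use the center crop), and
#' minimizes the unweighted mean of the per-trait Huber losses with Adam
#' under an exponentially decayed learning rate and early stopping on
#' validation loss. Crops of one plot never straddle splits because the
#' split is drawn at the plot level before augmentation.
#'
#' @param prep a `plot_prep`
#' @param tasks trait names to predict (1 = mono-task, 8 = multi-task)
#' @param modalities modality subset, see [build_network()]
#' @param config see [default_train_config()]
#' @param split optional precomputed list(train, val, test) of plot indices
#' @param targets optional plots x tasks matrix overriding the phenotype
#'   table (columns named as `tasks`)
#' @param scale_targets standardize targets on the training split (default)
#' @param chips optional precomputed [net_chips()] result (reused across
#'   training runs on the same scene)
#' @return list of class `fusion_fit`: the trained `net`, target `scaler`,
#'   `split`, per-epoch `history`, and the configuration
#' @export
train_fusion_net <- function(prep, tasks = trait_names(),
                             modalities = c("hyperspectral", "lidar_height",
                                            "lidar_intensity", "thermal"),
                             config = default_train_config(), split = NULL,
                             targets = NULL, scale_targets = TRUE,
                             chips = NULL) {
  cfg <- config
  d <- prep$design
  n <- nrow(d)
  if (is.null(targets)) {
    targets <- as.matrix(as.data.frame(prep$phenotypes)[, tasks, drop = FALSE])
    rownames(targets) <- d$plot_id
  }
  if (is.null(split))
    split <- stratified_split(as.character(d$treatment), cfg$split, cfg$seed)
  if (scale_targets) {
    st <- standardize(targets, fit_rows = split$train)
    Y <- st$scaled; scaler <- st$scaler
  } else { Y <- targets; scaler <- NULL }

  if (is.null(chips)) chips <- net_chips(prep, cfg$bins)
  norm <- fit_chip_norm(chips, split$train)
  chips <- apply_chip_norm(chips, norm)
  dims <- lapply(chips, function(ch) dim(ch$lidar)[1:2])
  names(dims) <- d$plot_id

  net <- build_network(modalities, n_tasks = length(tasks), bins = cfg$bins,
                       seed = cfg$seed)

  # training samples: (plot, offset) pairs; 0 crops means one center crop
  if (cfg$n_crops > 0) {
    off <- augment_offsets(dims[split$train], window = cfg$window,
                           n_crops = cfg$n_crops, seed = cfg$seed)
    samples <- data.frame(idx = match(off$plot, d$plot_id),
                          row_off = off$row_off, col_off = off$col_off)
  } else {
    co <- t(vapply(split$train, function(i) center_offset(dims[[i]], cfg$window),
                   numeric(2)))
    samples <- data.frame(idx = split$train, row_off = co[, 1], col_off = co[, 2])
  }
  center_batch <- function(idx) {
    co <- t(vapply(idx, function(i) center_offset(dims[[i]], cfg$window),
                   numeric(2)))
    make_batch(net, chips, idx, co[, 1], co[, 2], cfg$window)
  }
  val_in <- center_batch(split$val)
  Yval <- t(Y[split$val, , drop = FALSE])

  par <- collect_params(net)
  state <- adam_init(par)
  best <- list(par = par, val = Inf, epoch = 0L)
  hist <- data.frame()
  bad_epochs <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- cfg$lr * cfg$lr_decay^((epoch - 1) %/% cfg$decay_every)
    set.seed(substream_seed(cfg$seed, paste0("epoch", epoch)))
    ord <- sample(nrow(samples))
    nb <- ceiling(length(ord) / cfg$batch_size)
    if (!is.null(cfg$steps_per_epoch)) nb <- min(nb, cfg$steps_per_epoch)
    tl <- 0; tn <- 0
    for (b in seq_len(nb)) {
      take <- ord[((b - 1) * cfg$batch_size + 1):min(b * cfg$batch_size,
                                                     length(ord))]
      sm <- samples[take, , drop = FALSE]
      xin <- make_batch(net, chips, sm$idx, sm$row_off, sm$col_off, cfg$window)
      Yb <- t(Y[sm$idx, , drop = FALSE])
      fw <- net_forward(net, xin, train = TRUE, dropout = cfg$dropout)
      L <- mean(huber_loss(Yb, fw$out, cfg$delta))
      if (!is.finite(L))
        stop(sprintf("non-finite loss at epoch %d batch %d (lr %.2g)",
                     epoch, b, lr))
      dout <- huber_grad(Yb, fw$out, cfg$delta) / length(Yb)
      gr <- collect_grads(net, net_backward(net, fw, dout))
      up <- adam_step(par, gr, state, lr)
      par <- up$par; state <- up$state
      net <- set_params(net, par)
      tl <- tl + L * length(take); tn <- tn + length(take)
    }
    fwv <- net_forward(net, val_in, train = FALSE)
    vl <- mean(huber_loss(Yval, fwv$out, cfg$delta))
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   train_loss = tl / tn, val_loss = vl))
    if (cfg$verbose)
      message(sprintf("epoch %3d lr %.5f train %.4f val %.4f",
                      epoch, lr, tl / tn, vl))
    if (vl < best$val - 1e-6) {
      best <- list(par = par, val = vl, epoch = epoch)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (!is.null(cfg$patience) && bad_epochs >= cfg$patience) break
    }
  }
  net <- set_params(net, best$par)
  structure(list(net = net, scaler = scaler, norm = norm, tasks = tasks,
                 split = split, history = hist, config = cfg,
                 window = cfg$window, bins = cfg$bins, modalities = modalities,
                 plot_ids = d$plot_id, best_epoch = best$epoch),
            class = "fusion_fit")
}

#' Predict plot traits with a trained fusion network
#'
#' Deterministic inference on the center crop of each plot (optionally the
#' mean over a five-crop grid), inverse-standardized back to physical units.
#'
#' @param fit a `fusion_fit`
#' @param prep the `plot_prep` the chips come from
#' @param plots integer plot indices (default: all)
#' @param aggregate "center" or "five_crop"
#' @param chips optional precomputed [net_chips()]
#' @return matrix (plots x tasks) of trait predictions
#' @export
predict_fusion_net <- function(fit, prep, plots = NULL,
                               aggregate = c("center", "five_crop"),
                               chips = NULL) {
  aggregate <- match.arg(aggregate)
  if (is.null(chips)) chips <- net_chips(prep, fit$bins)
  chips <- apply_chip_norm(chips, fit$norm)
  plots <- plots %||% seq_along(chips)
  w <- fit$window
  preds <- matrix(0, length(plots), length(fit$tasks),
                  dimnames = list(prep$design$plot_id[plots], fit$tasks))
  offsets_for <- function(dimhw) {
    ctr <- center_offset(dimhw, w)
    if (aggregate == "center") list(ctr)
    else {
      mx <- c(dimhw[1] - w[1], dimhw[2] - w[2])
      unique(list(ctr, c(0, 0), c(0, mx[2]), c(mx[1], 0), mx))
    }
  }
  for (chunk in split(seq_along(plots), ceiling(seq_along(plots) / 32))) {
    idx <- plots[chunk]
    offs <- lapply(idx, function(i) offsets_for(dim(chips[[i]]$lidar)[1:2]))
    reps <- lengths(offs)
    om <- do.call(rbind, lapply(offs, function(o) do.call(rbind, o)))
    xin <- make_batch(fit$net, chips, rep(idx, reps), om[, 1], om[, 2], w)
    fw <- net_forward(fit$net, xin, train = FALSE)
    out <- t(fw$out)
    grp <- rep(seq_along(idx), reps)
    agg <- apply(out, 2, function(cl) tapply(cl, grp, mean))
    preds[chunk, ] <- as.matrix(agg)
  }
  if (!is.null(fit$scaler)) preds <- invert_scaler(fit$scaler, preds)
  preds
}

#' Test-split metrics of a trained fusion network
#' @param fit a `fusion_fit`
#' @param prep the `plot_prep`
#' @param split_name which split to score
#' @param chips optional precomputed chips
#' @return data.frame with one row per task: r2, rmse, mae, n
#' @export
evaluate_fusion_net <- function(fit, prep, split_name = c("test", "val", "train"),
                                chips = NULL) {
  split_name <- match.arg(split_name)
  idx <- fit$split[[split_name]]
  preds <- predict_fusion_net(fit, prep, plots = idx, chips = chips)
  truth <- as.data.frame(prep$phenotypes)[idx, fit$tasks, drop = FALSE]
  rows <- lapply(fit$tasks, function(tn) {
    m <- regression_metrics(truth[[tn]], preds[, tn])
    data.frame(task = tn, r2 = m$r2, rmse = m$rmse, mae = m$mae, n = m$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Augmentation-sensitivity sweep
#'
#' Retrains the network at several crop counts (0 = center crop only) and
#' reports the mean test R-squared over the named tasks, mirroring the
#' common observation that crop augmentation lifts test performance up to a
#' saturation point.
#'
#' @param prep a `plot_prep`
#' @param crop_counts vector of crop counts to sweep
#' @param tasks,modalities,config as in [train_fusion_net()]
#' @param epochs_for optional function(crops) giving max_epochs per setting
#'   (augmented datasets need fewer passes)
#' @return data.frame with columns `n_crops` and `mean_test_r2`
#' @export
augmentation_sweep <- function(prep, crop_counts = c(0, 1, 3, 5, 10, 20),
                               tasks = c("dry_grain_yield", "total_plant_n"),
                               modalities = c("hyperspectral", "lidar_height",
                                              "lidar_intensity"),
                               config = default_train_config(),
                               epochs_for = NULL) {
  chips <- net_chips(prep, config$bins)
  split <- stratified_split(as.character(prep$design$treatment),
                            config$split, config$seed)
  rows <- lapply(crop_counts, function(k) {
    cfg <- config
    cfg$n_crops <- k
    if (!is.null(epochs_for)) cfg$max_epochs <- epochs_for(k)
    fit <- train_fusion_net(prep, tasks = tasks, modalities = modalities,
                            config = cfg, split = split, chips = chips)
    ev <- evaluate_fusion_net(fit, prep, "test", chips = chips)
    data.frame(n_crops = k, mean_test_r2 = mean(ev$r2))
  })
  do.call(rbind, rows)
}
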