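#' Huber loss
#'
#' Piecewise loss: quadratic `(y - f)^2 / 2` for residuals within `delta`,
#' linear `delta * |y - f| - delta^2 / 2` beyond. Continuous and once
#' differentiable at the transition; equals half the squared error below the
#' threshold and grows linearly (like a scaled absolute error) above it,
#' which tempers the influence of extreme phenotype values.
#'
#' @param y target value(s)
#' @param f predicted value(s)
#' @param delta transition threshold (> 0)
#' @return elementwise loss, same shape as the inputs
#' @export
huber_loss <- function(y, f, delta = 1) {
  if (!is.numeric(delta) || delta <= 0) stop("delta must be > 0")
  r <- abs(y - f)
  ifelse(r <= delta, 0.5 * r^2, delta * r - 0.5 * delta^2)
}

huber_grad <- function(y, f, delta = 1) {
  r <- f - y
  ifelse(abs(r) <= delta, r, delta * sign(r))
}

glorot_uniform <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

relu <- function(x) cpp_relu(x)

#' Stratified train/validation/test split at the plot level
#'
#' Shuffles within each stratum (nitrogen treatment) and allocates the
#' requested fractions, so the bimodal treatment structure is preserved in
#' every split.
#'
#' @param strata factor/character vector (one entry per plot)
#' @param fractions length-3 fractions summing to 1 (train, validation, test)
#' @param seed integer seed
#' @return list with integer index vectors `train`, `val`, `test`
#' @export
stratified_split <- function(strata, fractions = c(0.6, 0.2, 0.2), seed = 1) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  set.seed(substream_seed(seed, "split"))
  train <- val <- test <- integer(0)
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    n <- length(idx)
    n1 <- round(fractions[1] * n); n2 <- round(fractions[2] * n)
    train <- c(train, idx[seq_len(n1)])
    val <- c(val, idx[n1 + seq_len(n2)])
    test <- c(test, idx[if (n1 + n2 < n) (n1 + n2 + 1):n else integer(0)])
  }
  out <- list(train = sort(train), val = sort(val), test = sort(test))
  if (any(vapply(out, length, integer(1)) < 2))
    stop("a split has fewer than 2 plots; use more plots or other fractions")
  out
}

#' Random aligned crop offsets for augmentation
#'
#' Draws `n_crops` random window offsets per plot. Offsets are generated
#' once per plot from a named sub-stream of the seed and then applied to
#' every modality, so the sliding window crops the same region of the
#' hyperspectral, LiDAR and thermal chips within each iteration.
#'
#' @param chip_dims named list (or single c(rows, cols)) of chip spatial
#'   sizes per plot
#' @param window c(rows, cols) crop window (default 176 x 25 pixels)
#' @param n_crops crops per plot (default 20)
#' @param seed integer seed
#' @return data.frame with `plot`, `crop`, `row_off`, `col_off` (0-based)
#' @export
augment_offsets <- function(chip_dims, window = c(176, 25), n_crops = 20,
                            seed = 1) {
  if (!is.list(chip_dims)) chip_dims <- list(plot = chip_dims)
  out <- lapply(names(chip_dims), function(p) {
    d <- chip_dims[[p]]
    if (d[1] < window[1] || d[2] < window[2])
      stop(sprintf("chip %s (%d x %d) smaller than the %d x %d crop window",
                   p, d[1], d[2], window[1], window[2]))
    set.seed(substream_seed(seed, paste0("aug_", p)))
    data.frame(plot = p, crop = seq_len(n_crops),
               row_off = sample.int(d[1] - window[1] + 1L, n_crops,
                                    replace = TRUE) - 1L,
               col_off = sample.int(d[2] - window[2] + 1L, n_crops,
                                    replace = TRUE) - 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

center_offset <- function(chip_dim, window) {
  c(floor((chip_dim[1] - window[1]) / 2), floor((chip_dim[2] - window[2]) / 2))
}

# average consecutive spectral bands into `bins` groups
bin_bands <- function(hyper, bins) {
  B <- dim(hyper)[3]
  if (is.null(bins) || bins >= B) return(hyper)
  grp <- cut(seq_len(B), bins, labels = FALSE)
  out <- array(0, dim = c(dim(hyper)[1], dim(hyper)[2], bins))
  for (g in seq_len(bins))
    out[, , g] <- apply(hyper[, , grp == g, drop = FALSE], c(1, 2), mean)
  out
}

#' Assemble the multimodal network architecture
#'
#' One convolutional stream per selected modality group: the hyperspectral
#' cube feeds a 3-D stream (kernels 3 x 3 x 7), LiDAR height and intensity
#' are stacked as two channels of a single 2-D stream (3 x 3 kernels), and
#' thermal feeds its own 2-D stream. Every stream runs four convolution
#' layers with the 8-16-32-64 filter ladder (Glorot-uniform weights, zero
#' bias, ReLU) each followed by max pooling (2 x 2 x 6 for the 3-D stream,
#' 2 x 2 for 2-D); convolutions use 'same' zero padding and pooling uses
#' ceiling mode so four layers are well defined on a 176 x 25 window. Global
#' average pooling reduces each stream to 64 values; fusion is
#' concatenation; the head is a 32-unit ReLU layer with dropout and a linear
#' output of `n_tasks` units.
#'
#' Stream weights are initialized from sub-streams named only by the
#' modality, so mono-task and multi-task builds share identical stream
#' initializations for the same seed.
#'
#' @param modalities subset of c("hyperspectral", "lidar_height",
#'   "lidar_intensity", "thermal")
#' @param n_tasks number of output traits (>= 1)
#' @param bins spectral bins the hyperspectral chip is averaged into before
#'   entering the 3-D stream (NULL = native band count)
#' @param stack_lidar stack height+intensity as channels of one 2-D stream
#'   (the default three-stream layout); FALSE gives each its own stream
#' @param filters the filter ladder
#' @param seed integer seed for weight initialization
#' @return list of class `fusion_net`
#' @export
build_network <- function(modalities, n_tasks, bins = 8, stack_lidar = TRUE,
                          filters = c(8, 16, 32, 64), seed = 1) {
  known <- c("hyperspectral", "lidar_height", "lidar_intensity", "thermal")
  if (length(modalities) == 0) stop("need at least one modality")
  if (!all(modalities %in% known))
    stop("unknown modalities: ", paste(setdiff(modalities, known), collapse = ", "))
  if (n_tasks < 1) stop("n_tasks must be >= 1")

  streams <- list()
  lidar_sel <- intersect(c("lidar_height", "lidar_intensity"), modalities)
  if ("hyperspectral" %in% modalities)
    streams$hyper <- list(kind = "3d", channels = 1L,
                          kernel = c(3L, 3L, 7L), pool = c(2L, 2L, 6L))
  if (length(lidar_sel)) {
    if (stack_lidar)
      streams$lidar <- list(kind = "2d", channels = length(lidar_sel),
                            sources = lidar_sel,
                            kernel = c(3L, 3L, 1L), pool = c(2L, 2L, 1L))
    else for (m in lidar_sel)
      streams[[m]] <- list(kind = "2d", channels = 1L, sources = m,
                           kernel = c(3L, 3L, 1L), pool = c(2L, 2L, 1L))
  }
  if ("thermal" %in% modalities)
    streams$thermal <- list(kind = "2d", channels = 1L, sources = "thermal",
                            kernel = c(3L, 3L, 1L), pool = c(2L, 2L, 1L))

  for (s in names(streams)) {
    set.seed(substream_seed(seed, paste0("stream_", s)))
    st <- streams[[s]]
    cin <- st$channels
    layers <- list()
    for (l in seq_along(filters)) {
      k <- st$kernel
      fan_in <- prod(k) * cin; fan_out <- prod(k) * filters[l]
      layers[[l]] <- list(
        w = glorot_uniform(c(k, cin, filters[l]), fan_in, fan_out),
        b = numeric(filters[l]))
      cin <- filters[l]
    }
    streams[[s]]$layers <- layers
  }
  n_fused <- 64L * length(streams)
  set.seed(substream_seed(seed, "head"))
  head <- list(
    W1 = glorot_uniform(c(n_fused, 32), n_fused, 32),
    b1 = numeric(32),
    W2 = glorot_uniform(c(32, n_tasks), 32, n_tasks),
    b2 = numeric(n_tasks))
  structure(list(streams = streams, head = head, n_tasks = as.integer(n_tasks),
                 bins = bins, filters = filters, modalities = modalities,
                 n_fused = n_fused, seed = seed),
            class = "fusion_net")
}

#' @export
print.fusion_net <- function(x, ...) {
  cat(sprintf("<fusion_net> streams: %s | fusion width %d | %d task(s)\n",
              paste(names(x$streams), collapse = ", "), x$n_fused, x$n_tasks))
  invisible(x)
}

# forward pass for a named list of stream input arrays (H,W,D,C,N)
net_forward <- function(net, inputs, train = FALSE, dropout = 0.5) {
  caches <- list()
  gaps <- list()
  N <- dim(inputs[[1]])[5]
  for (s in names(net$streams)) {
    st <- net$streams[[s]]
    x <- inputs[[s]]
    lc <- list()
    for (l in seq_along(st$layers)) {
      ly <- st$layers[[l]]
      y <- cpp_relu(cpp_conv3d_fwd(x, dim(x), ly$w, dim(ly$w), ly$b))
      pl <- cpp_maxpool3d_fwd(y, dim(y), st$pool[1], st$pool[2], st$pool[3])
      lc[[l]] <- list(x = x, relu = y, idx = pl$idx, ydim = dim(y))
      x <- pl$y
    }
    dmx <- dim(x)
    Pn <- prod(dmx[1:3])
    xm <- matrix(x, Pn, dmx[4] * N)
    g <- matrix(colMeans(xm), dmx[4], N)
    caches[[s]] <- list(layers = lc, pooled_dim = dmx, P = Pn)
    gaps[[s]] <- g
  }
  fused <- do.call(rbind, gaps)                       # n_fused x N
  z1 <- crossprod(net$head$W1, fused) + net$head$b1   # 32 x N
  a1 <- relu(z1)
  if (train && dropout > 0) {
    mask <- matrix(runif(length(a1)) >= dropout, nrow(a1), ncol(a1))
    a1d <- a1 * mask / (1 - dropout)
  } else { mask <- NULL; a1d <- a1 }
  out <- crossprod(net$head$W2, a1d) + net$head$b2    # n_tasks x N
  list(out = out, fused = fused, a1 = a1, a1d = a1d, mask = mask,
       dropout = dropout, caches = caches, N = N)
}

# backward pass; returns gradients in the same structure as the parameters
net_backward <- function(net, fw, dout) {
  N <- fw$N
  gW2 <- fw$a1d %*% t(dout)
  gb2 <- rowSums(dout)
  da1d <- net$head$W2 %*% dout
  da1 <- if (!is.null(fw$mask)) da1d * fw$mask / (1 - fw$dropout) else da1d
  dz1 <- da1 * (fw$a1 > 0)
  gW1 <- fw$fused %*% t(dz1)
  gb1 <- rowSums(dz1)
  dfused <- net$head$W1 %*% dz1                       # n_fused x N
  gstreams <- list()
  offset <- 0L
  for (s in names(net$streams)) {
    st <- net$streams[[s]]
    cache <- fw$caches[[s]]
    dg <- dfused[offset + seq_len(64L), , drop = FALSE]  # 64 x N
    offset <- offset + 64L
    dmx <- cache$pooled_dim; Pn <- cache$P
    dx <- array(rep(as.vector(dg), each = Pn) / Pn, dim = dmx)
    glayers <- vector("list", length(st$layers))
    for (l in rev(seq_along(st$layers))) {
      lc <- cache$layers[[l]]
      drelu <- cpp_relu_bwd(cpp_maxpool3d_bwd(lc$idx, dx, lc$ydim), lc$relu)
      bw <- cpp_conv3d_bwd(lc$x, dim(lc$x), st$layers[[l]]$w,
                           dim(st$layers[[l]]$w), drelu)
      glayers[[l]] <- list(w = bw$gw, b = bw$gb)
      dx <- bw$gx
    }
    gstreams[[s]] <- glayers
  }
  list(streams = gstreams, head = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

# flatten parameters / gradients to a named list of arrays
collect_params <- function(net) {
  out <- list()
  for (s in names(net$streams))
    for (l in seq_along(net$streams[[s]]$layers)) {
      out[[paste0(s, "_w", l)]] <- net$streams[[s]]$layers[[l]]$w
      out[[paste0(s, "_b", l)]] <- net$streams[[s]]$layers[[l]]$b
    }
  out$head_W1 <- net$head$W1; out$head_b1 <- net$head$b1
  out$head_W2 <- net$head$W2; out$head_b2 <- net$head$b2
  out
}

collect_grads <- function(net, gr) {
  out <- list()
  for (s in names(net$streams))
    for (l in seq_along(gr$streams[[s]])) {
      out[[paste0(s, "_w", l)]] <- gr$streams[[s]][[l]]$w
      out[[paste0(s, "_b", l)]] <- gr$streams[[s]][[l]]$b
    }
  out$head_W1 <- gr$head$W1; out$head_b1 <- gr$head$b1
  out$head_W2 <- gr$head$W2; out$head_b2 <- gr$head$b2
  out
}

set_params <- function(net, par) {
  for (s in names(net$streams))
    for (l in seq_along(net$streams[[s]]$layers)) {
      net$streams[[s]]$layers[[l]]$w <- par[[paste0(s, "_w", l)]]
      net$streams[[s]]$layers[[l]]$b <- par[[paste0(s, "_b", l)]]
    }
  net$head$W1 <- par$head_W1; net$head$b1 <- par$head_b1
  net$head$W2 <- par$head_W2; net$head$b2 <- par$head_b2
  net
}

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (k in names(par)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grad[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grad[[k]]^2
    par[[k]] <- par[[k]] - lr * (state$m[[k]] / bc1) /
      (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(par = par, state = state)
}
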