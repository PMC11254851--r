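## Layer-graph construction for the two architectures.
##
## A model is an ordered list of layer descriptors from which the forward
## pass, the parameter count and the mult-add count all derive. Temporal
## convolutions in the eight-block network share weights across the twelve
## leads (leads ride along the batch axis); the residual network takes the
## twelve leads as input channels, as in its original description.

#' Configuration of the eight-block temporal/spatial network
#'
#' Eight temporal convolutional blocks (convolution, batch normalization,
#' ReLU, max-pool) with kernel size 7 in the initial block, 5 in
#' intermediate blocks and 3 in deeper blocks, followed by one spatial
#' block fusing the 12-lead axis, then a two-layer regression head ending
#' in a single scalar (predicted age in years).
#'
#' The canonical filter counts, spatial width and head widths are
#' calibrated so that the analytic parameter count is 593,505 at a
#' 1,024-sample input and 599,649 at 5,120 samples, with forward mult-adds
#' of 1.57 G at 5,120 samples.
#'
#' @param filters per-block temporal filter counts.
#' @param kernels per-block kernel sizes (odd).
#' @param pools per-block max-pool windows.
#' @param spatial_filters filter count of the lead-fusing spatial block.
#' @param head widths of the two fully connected layers before the scalar
#'   output.
#' @param n_leads number of leads (12).
#' @return An object of class \code{attianet_config}.
#' @export
attianet_config <- function(filters = c(32, 32, 120, 120, 144, 144, 280, 280),
                            kernels = c(7, 5, 5, 5, 3, 3, 3, 3),
                            pools = rep(2L, length(filters)),
                            spatial_filters = 6L,
                            head = c(64L, 23L),
                            n_leads = 12L) {
  if (length(kernels) != length(filters) || length(pools) != length(filters))
    stop_ecg("filters, kernels and pools must have equal length")
  if (any(kernels %% 2 == 0)) stop_ecg("kernels must be odd")
  if (length(head) != 2L) stop_ecg("head must give two widths")
  structure(list(arch = "attianet", filters = filters, kernels = kernels,
                 pools = as.integer(pools),
                 spatial_filters = as.integer(spatial_filters),
                 head = as.integer(head), n_leads = as.integer(n_leads)),
            class = "attianet_config")
}

#' Configuration of the four-block 1D residual network
#'
#' A convolutional stem followed by four residual blocks, each implementing
#' the canonical structure: a skip path (max-pool then 1x1 convolution) and
#' a main path of two kernel-17 convolutions, each followed by dropout,
#' with the merge taken before the final batch normalization, ReLU and
#' dropout. Each block reduces the temporal dimension by a factor of 4
#' while increasing the channel dimension by 64 (64 -> 128 -> 192 -> 256 ->
#' 320); the flattened final feature map connects to the scalar output
#' through a narrow calibrated head.
#'
#' Convolutions carry no biases (every convolution is followed by batch
#' normalization). The stem widths/kernels and the head width are
#' calibrated so the analytic parameter count reproduces 6,940,065 at a
#' 1,024-sample input and 7,021,985 at 5,120 samples.
#'
#' @param stem_filters,stem_kernels widths and kernel sizes of the two stem
#'   convolutions; the second width must equal \code{channels[1]}.
#' @param channels channel schedule: stem output then the four block widths.
#' @param kernel main-path kernel size (17).
#' @param reduction per-block temporal reduction factor (4).
#' @param dropout dropout rate inside the residual blocks.
#' @param head_width width of the single hidden layer of the head.
#' @param n_leads number of leads (= input channels, 12).
#' @return An object of class \code{resnet1d_config}.
#' @export
resnet1d_config <- function(stem_filters = c(128L, 64L),
                            stem_kernels = c(33L, 19L),
                            channels = c(64L, 128L, 192L, 256L, 320L),
                            kernel = 17L, reduction = 4L, dropout = 0.5,
                            head_width = 16L, n_leads = 12L) {
  if (length(channels) < 2L) stop_ecg("channels must list stem + block widths")
  if (stem_filters[length(stem_filters)] != channels[1])
    stop_ecg("last stem width must equal channels[1]")
  structure(list(arch = "resnet1d", stem_filters = as.integer(stem_filters),
                 stem_kernels = as.integer(stem_kernels),
                 channels = as.integer(channels), kernel = as.integer(kernel),
                 reduction = as.integer(reduction), dropout = dropout,
                 head_width = as.integer(head_width),
                 n_leads = as.integer(n_leads)),
            class = "resnet1d_config")
}

init_mat <- function(nr, nc, fan_in, init) {
  if (!init) return(matrix(0, nr, nc))
  matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

layer_conv <- function(name, in_ch, out_ch, k, stride = 1L, bias = TRUE,
                       per_lead = FALSE, block = "", path = "main",
                       init = TRUE) {
  list(name = name, kind = "conv1d", in_ch = in_ch, out_ch = out_ch, k = k,
       stride = as.integer(stride), bias = bias, per_lead = per_lead,
       block = block, path = path, frozen = FALSE,
       W = init_mat(out_ch, in_ch * k, in_ch * k, init),
       b = if (bias) numeric(out_ch) else NULL)
}

layer_bn <- function(name, ch, block = "", path = "main") {
  list(name = name, kind = "batchnorm", ch = ch, block = block, path = path,
       frozen = FALSE, gamma = rep(1, ch), beta = numeric(ch),
       rmean = numeric(ch), rvar = rep(1, ch))
}

layer_linear <- function(name, n_in, n_out, block = "head", init = TRUE) {
  list(name = name, kind = "linear", n_in = n_in, n_out = n_out,
       block = block, path = "main", frozen = FALSE,
       W = init_mat(n_out, n_in, n_in, init), b = numeric(n_out))
}

layer_simple <- function(name, kind, block = "", path = "main", ...) {
  c(list(name = name, kind = kind, block = block, path = path), list(...))
}

#' Build the eight-block temporal/spatial network
#'
#' @param config an \code{\link{attianet_config}}.
#' @param input_len input length in samples; must be a multiple of 1,024
#'   (the pad-to-grid unit).
#' @param init draw initial weights (He normal, from the session RNG)?
#'   \code{FALSE} allocates a weightless graph for complexity accounting.
#' @return An object of class \code{ecg_model}.
#' @export
build_attianet <- function(config = attianet_config(), input_len,
                           init = TRUE) {
  if (input_len %% 1024L != 0L)
    stop_ecg("input_len (%d) must lie on the 1,024-sample grid", input_len)
  red <- prod(config$pools)
  if (input_len %% red != 0L || input_len / red < 1L)
    stop_ecg("input_len %d is shorter than the receptive field of the %d stacked pools (reduction %d)",
             input_len, length(config$pools), red)
  layers <- list()
  in_ch <- 1L
  for (i in seq_along(config$filters)) {
    f <- config$filters[i]
    blk <- sprintf("t%d", i)
    layers <- c(layers, list(
      layer_conv(paste0(blk, "_conv"), in_ch, f, config$kernels[i],
                 per_lead = TRUE, block = blk, init = init),
      layer_bn(paste0(blk, "_bn"), f, block = blk),
      layer_simple(paste0(blk, "_relu"), "relu", block = blk),
      layer_simple(paste0(blk, "_pool"), "maxpool", block = blk,
                   pool = config$pools[i])))
    in_ch <- f
  }
  csp <- config$spatial_filters
  sp <- list(name = "spatial_conv", kind = "spatial_conv", in_ch = in_ch,
             leads = config$n_leads, out_ch = csp, block = "spatial",
             path = "main", frozen = FALSE,
             W = init_mat(csp, in_ch * config$n_leads,
                          in_ch * config$n_leads, init),
             b = numeric(csp))
  flat <- as.integer(input_len / red) * csp
  layers <- c(layers, list(
    sp,
    layer_bn("sp_bn", csp, block = "spatial"),
    layer_simple("sp_relu", "relu", block = "spatial"),
    layer_simple("flatten", "flatten", block = "head"),
    layer_linear("fc1", flat, config$head[1], init = init),
    layer_simple("fc1_relu", "relu", block = "head"),
    layer_linear("fc2", config$head[1], config$head[2], init = init),
    layer_simple("fc2_relu", "relu", block = "head"),
    layer_linear("out", config$head[2], 1L, init = init)))
  new_ecg_model("attianet", config, input_len, layers)
}

#' Build the four-block 1D residual network
#'
#' @param config a \code{\link{resnet1d_config}}.
#' @inheritParams build_attianet
#' @return An object of class \code{ecg_model}.
#' @export
build_resnet1d <- function(config = resnet1d_config(), input_len,
                           init = TRUE) {
  if (input_len %% 1024L != 0L)
    stop_ecg("input_len (%d) must lie on the 1,024-sample grid", input_len)
  n_blocks <- length(config$channels) - 1L
  red <- config$reduction^n_blocks
  if (input_len %% red != 0L || input_len / red < 1L)
    stop_ecg("input_len %d is shorter than the receptive field of %d residual blocks (reduction %d)",
             input_len, n_blocks, red)
  sf <- config$stem_filters; sk <- config$stem_kernels
  layers <- list()
  in_ch <- config$n_leads
  for (i in seq_along(sf)) {
    layers <- c(layers, list(
      layer_conv(sprintf("stem_conv%d", i), in_ch, sf[i], sk[i],
                 bias = FALSE, block = "stem", init = init),
      layer_bn(sprintf("stem_bn%d", i), sf[i], block = "stem"),
      layer_simple(sprintf("stem_relu%d", i), "relu", block = "stem")))
    in_ch <- sf[i]
  }
  for (i in seq_len(n_blocks)) {
    cin <- config$channels[i]; cout <- config$channels[i + 1L]
    blk <- sprintf("res%d", i)
    layers <- c(layers, list(
      layer_conv(paste0(blk, "_conv1"), cin, cout, config$kernel,
                 bias = FALSE, block = blk, init = init),
      layer_bn(paste0(blk, "_bn1"), cout, block = blk),
      layer_simple(paste0(blk, "_relu1"), "relu", block = blk),
      layer_simple(paste0(blk, "_drop1"), "dropout", block = blk,
                   rate = config$dropout),
      layer_conv(paste0(blk, "_conv2"), cout, cout, config$kernel,
                 stride = config$reduction, bias = FALSE, block = blk,
                 init = init),
      layer_simple(paste0(blk, "_pool_skip"), "maxpool", block = blk,
                   path = "skip", pool = config$reduction),
      layer_conv(paste0(blk, "_conv_skip"), cin, cout, 1L, bias = FALSE,
                 block = blk, path = "skip", init = init),
      layer_simple(paste0(blk, "_add"), "add", block = blk, path = "merge"),
      layer_bn(paste0(blk, "_bn2"), cout, block = blk, path = "merge"),
      layer_simple(paste0(blk, "_relu2"), "relu", block = blk,
                   path = "merge"),
      layer_simple(paste0(blk, "_drop2"), "dropout", block = blk,
                   path = "merge", rate = config$dropout)))
  }
  flat <- as.integer(input_len / red) * config$channels[length(config$channels)]
  layers <- c(layers, list(
    layer_simple("flatten", "flatten", block = "head"),
    layer_linear("fc1", flat, config$head_width, init = init),
    layer_simple("fc1_relu", "relu", block = "head"),
    layer_linear("out", config$head_width, 1L, init = init)))
  new_ecg_model("resnet1d", config, input_len, layers)
}

new_ecg_model <- function(arch, config, input_len, layers) {
  names(layers) <- vapply(layers, `[[`, character(1), "name")
  structure(list(arch = arch, config = config,
                 input_len = as.integer(input_len), layers = layers,
                 n_leads = config$n_leads),
            class = "ecg_model")
}

#' @export
print.ecg_model <- function(x, ...) {
  cr <- count_params(x)
  cat(sprintf("<ecg_model %s> input %d samples, %d layers, %s parameters (%s trainable)\n",
              x$arch, x$input_len, length(x$layers),
              format(cr$total, big.mark = ","),
              format(cr$trainable, big.mark = ",")))
  invisible(x)
}

#' @export
summary.ecg_model <- function(object, ...) {
  rep <- complexity_report(object)
  print(object)
  print(rep)
  invisible(rep)
}

## ---- forward / backward execution -------------------------------------

# (records, 12, L) -> cube (1, L, 12 * records), lead fastest within record
batch_to_perlead <- function(x) {
  d <- dim(x)
  array(aperm(x, c(3, 2, 1)), dim = c(1L, d[3], d[2] * d[1]))
}

# (records, 12, L) -> cube (12, L, records)
batch_to_channels <- function(x) aperm(x, c(2, 3, 1))

run_layer_fwd <- function(layer, x, training, state) {
  kind <- layer$kind
  if (kind == "conv1d") {
    y <- cpp_conv1d_fwd(x, layer$W,
                        if (is.null(layer$b)) numeric(layer$out_ch) else layer$b,
                        layer$k, layer$stride, !is.null(layer$b))
    return(list(y = y, cache = if (training) x))
  }
  if (kind == "batchnorm") {
    train_bn <- training && !layer$frozen
    r <- cpp_bn_fwd(x, dim(x), layer$gamma, layer$beta, layer$rmean,
                    layer$rvar, state$bn_momentum, 1e-5, train_bn)
    cache <- if (training) list(x = x, mean = r$mean, var = r$var)
    return(list(y = r$y, cache = cache,
                stats = if (train_bn) list(rmean = r$rmean, rvar = r$rvar)))
  }
  if (kind == "relu") {
    y <- cpp_relu_fwd(x)
    return(list(y = y, cache = if (training) y))
  }
  if (kind == "maxpool") {
    r <- cpp_maxpool_fwd(x, dim(x), layer$pool)
    return(list(y = r$y,
                cache = if (training) list(idx = r$idx, dims = dim(x))))
  }
  if (kind == "dropout") {
    if (!training || isTRUE(layer$frozen) || layer$rate <= 0)
      return(list(y = x, cache = NULL))
    r <- cpp_dropout_fwd(x, layer$rate)
    return(list(y = r$y, cache = r$mask))
  }
  stop_ecg("no forward rule for layer kind `%s`", kind)
}

run_layer_bwd <- function(layer, dy, cache) {
  kind <- layer$kind
  if (kind == "conv1d") {
    r <- cpp_conv1d_bwd(cache, layer$W, dy, layer$k, layer$stride,
                        !is.null(layer$b))
    g <- list(W = r$dW)
    if (!is.null(layer$b)) g$b <- as.numeric(r$db)
    return(list(dx = r$dx, grads = g))
  }
  if (kind == "batchnorm") {
    if (layer$frozen) {
      # inference-mode statistics: gradient is a per-channel rescaling
      scale <- layer$gamma / sqrt(layer$rvar + 1e-5)
      dx <- dy
      for (n in seq_len(dim(dy)[3])) dx[, , n] <- dy[, , n] * scale
      return(list(dx = dx, grads = NULL))
    }
    r <- cpp_bn_bwd(cache$x, dy, dim(cache$x), layer$gamma, cache$mean,
                    cache$var, 1e-5)
    return(list(dx = r$dx,
                grads = list(gamma = as.numeric(r$dgamma),
                             beta = as.numeric(r$dbeta))))
  }
  if (kind == "relu") return(list(dx = cpp_relu_bwd(cache, dy), grads = NULL))
  if (kind == "maxpool")
    return(list(dx = cpp_maxpool_bwd(cache$idx, dy, cache$dims[1],
                                     cache$dims[2], cache$dims[3]),
                grads = NULL))
  if (kind == "dropout") {
    if (is.null(cache)) return(list(dx = dy, grads = NULL))
    return(list(dx = dy * cache, grads = NULL))
  }
  stop_ecg("no backward rule for layer kind `%s`", kind)
}

# Full forward pass. Returns predictions and, when `training`, the caches
# needed for backpropagation plus updated batch-norm running statistics.
model_forward <- function(graph, x, training = FALSE,
                          bn_momentum = 0.1) {
  d <- dim(x)
  if (length(d) != 3L || d[2] != graph$n_leads)
    stop_ecg("batch must have dim (records, %d, samples)", graph$n_leads)
  if (d[3] != graph$input_len)
    stop_ecg("batch length %d does not match graph input length %d",
             d[3], graph$input_len)
  state <- list(bn_momentum = bn_momentum)
  caches <- list()
  stats <- list()
  n <- d[1]
  if (graph$arch == "attianet") {
    h <- batch_to_perlead(x)
    for (ly in graph$layers) {
      if (ly$block == "spatial" || ly$block == "head") break
      r <- run_layer_fwd(ly, h, training, state)
      h <- r$y
      if (training) caches[[ly$name]] <- r$cache
      if (!is.null(r$stats)) stats[[ly$name]] <- r$stats
    }
    # fuse leads: cube (C, L', 12n) -> matrix (C*12, L'*n)
    dC <- dim(h)
    Lp <- dC[2]
    h4 <- array(h, dim = c(dC[1], Lp, graph$n_leads, n))
    X <- matrix(aperm(h4, c(1, 3, 2, 4)), nrow = dC[1] * graph$n_leads)
    sp <- graph$layers$spatial_conv
    Z <- sp$W %*% X + sp$b
    if (training) caches$spatial_conv <- X
    h <- array(Z, dim = c(sp$out_ch, Lp, n))
    for (nm in c("sp_bn", "sp_relu")) {
      r <- run_layer_fwd(graph$layers[[nm]], h, training, state)
      h <- r$y
      if (training) caches[[nm]] <- r$cache
      if (!is.null(r$stats)) stats[[nm]] <- r$stats
    }
    M <- matrix(h, nrow = dim(h)[1] * dim(h)[2])   # flatten: (C*L') x n
    if (training) caches$flatten <- dim(h)
    for (nm in c("fc1", "fc1_relu", "fc2", "fc2_relu", "out")) {
      ly <- graph$layers[[nm]]
      if (ly$kind == "linear") {
        if (training) caches[[nm]] <- M
        M <- ly$W %*% M + ly$b
      } else {
        M2 <- pmax(M, 0)
        if (training) caches[[nm]] <- M2
        M <- M2
      }
    }
    pred <- as.numeric(M)
  } else if (graph$arch == "resnet1d") {
    h <- batch_to_channels(x)
    lys <- graph$layers
    for (ly in lys) {
      if (ly$block == "stem") {
        r <- run_layer_fwd(ly, h, training, state)
        h <- r$y
        if (training) caches[[ly$name]] <- r$cache
        if (!is.null(r$stats)) stats[[ly$name]] <- r$stats
      }
    }
    n_blocks <- length(graph$config$channels) - 1L
    for (i in seq_len(n_blocks)) {
      blk <- sprintf("res%d", i)
      inp <- h
      m <- inp
      for (suf in c("_conv1", "_bn1", "_relu1", "_drop1", "_conv2")) {
        ly <- lys[[paste0(blk, suf)]]
        r <- run_layer_fwd(ly, m, training, state)
        m <- r$y
        if (training) caches[[ly$name]] <- r$cache
        if (!is.null(r$stats)) stats[[ly$name]] <- r$stats
      }
      rs <- run_layer_fwd(lys[[paste0(blk, "_pool_skip")]], inp, training,
                          state)
      if (training) caches[[paste0(blk, "_pool_skip")]] <- rs$cache
      rk <- run_layer_fwd(lys[[paste0(blk, "_conv_skip")]], rs$y, training,
                          state)
      if (training) caches[[paste0(blk, "_conv_skip")]] <- rk$cache
      h <- m + rk$y
      for (suf in c("_bn2", "_relu2", "_drop2")) {
        ly <- lys[[paste0(blk, suf)]]
        r <- run_layer_fwd(ly, h, training, state)
        h <- r$y
        if (training) caches[[ly$name]] <- r$cache
        if (!is.null(r$stats)) stats[[ly$name]] <- r$stats
      }
    }
    M <- matrix(h, nrow = dim(h)[1] * dim(h)[2])
    if (training) caches$flatten <- dim(h)
    for (nm in c("fc1", "fc1_relu", "out")) {
      ly <- lys[[nm]]
      if (ly$kind == "linear") {
        if (training) caches[[nm]] <- M
        M <- ly$W %*% M + ly$b
      } else {
        M2 <- pmax(M, 0)
        if (training) caches[[nm]] <- M2
        M <- M2
      }
    }
    pred <- as.numeric(M)
  } else stop_ecg("unknown architecture `%s`", graph$arch)
  if (any(!is.finite(pred)))
    warning("non-finite predictions in forward pass", call. = FALSE)
  list(pred = pred, caches = if (training) caches, bn_stats = stats)
}

# Backpropagation of d(loss)/d(pred). Returns per-layer gradient lists.
model_backward <- function(graph, dpred, caches) {
  grads <- list()
  lys <- graph$layers
  n <- length(dpred)
  dM <- matrix(dpred, nrow = 1L)
  if (graph$arch == "attianet") {
    for (nm in c("out", "fc2_relu", "fc2", "fc1_relu", "fc1")) {
      ly <- lys[[nm]]
      if (ly$kind == "linear") {
        X <- caches[[nm]]
        grads[[nm]] <- list(W = dM %*% t(X), b = rowSums(dM))
        dM <- t(ly$W) %*% dM
      } else {
        dM <- dM * (caches[[nm]] > 0)
      }
    }
    dh <- array(dM, dim = caches$flatten)
    for (nm in c("sp_relu", "sp_bn")) {
      r <- run_layer_bwd(lys[[nm]], dh, caches[[nm]])
      dh <- r$dx
      if (!is.null(r$grads)) grads[[nm]] <- r$grads
    }
    sp <- lys$spatial_conv
    dZ <- matrix(dh, nrow = dim(dh)[1])
    X <- caches$spatial_conv
    grads$spatial_conv <- list(W = dZ %*% t(X), b = rowSums(dZ))
    dX <- t(sp$W) %*% dZ                       # (C*12) x (L'*n)
    Lp <- dim(dh)[2]
    d4 <- array(dX, dim = c(sp$in_ch, graph$n_leads, Lp, n))
    dh <- array(aperm(d4, c(1, 3, 2, 4)),
                dim = c(sp$in_ch, Lp, graph$n_leads * n))
    temporal <- rev(Filter(function(l) startsWith(l$block, "t"), lys))
    for (ly in temporal) {
      r <- run_layer_bwd(ly, dh, caches[[ly$name]])
      dh <- r$dx
      if (!is.null(r$grads)) grads[[ly$name]] <- r$grads
    }
  } else {
    for (nm in c("out", "fc1_relu", "fc1")) {
      ly <- lys[[nm]]
      if (ly$kind == "linear") {
        X <- caches[[nm]]
        grads[[nm]] <- list(W = dM %*% t(X), b = rowSums(dM))
        dM <- t(ly$W) %*% dM
      } else dM <- dM * (caches[[nm]] > 0)
    }
    dh <- array(dM, dim = caches$flatten)
    n_blocks <- length(graph$config$channels) - 1L
    for (i in rev(seq_len(n_blocks))) {
      blk <- sprintf("res%d", i)
      for (suf in c("_drop2", "_relu2", "_bn2")) {
        ly <- lys[[paste0(blk, suf)]]
        r <- run_layer_bwd(ly, dh, caches[[ly$name]])
        dh <- r$dx
        if (!is.null(r$grads)) grads[[ly$name]] <- r$grads
      }
      dmain <- dh; dskip <- dh
      rk <- run_layer_bwd(lys[[paste0(blk, "_conv_skip")]], dskip,
                          caches[[paste0(blk, "_conv_skip")]])
      if (!is.null(rk$grads)) grads[[paste0(blk, "_conv_skip")]] <- rk$grads
      rs <- run_layer_bwd(lys[[paste0(blk, "_pool_skip")]], rk$dx,
                          caches[[paste0(blk, "_pool_skip")]])
      dinp_skip <- rs$dx
      for (suf in c("_conv2", "_drop1", "_relu1", "_bn1", "_conv1")) {
        ly <- lys[[paste0(blk, suf)]]
        r <- run_layer_bwd(ly, dmain, caches[[ly$name]])
        dmain <- r$dx
        if (!is.null(r$grads)) grads[[ly$name]] <- r$grads
      }
      dh <- dmain + dinp_skip
    }
    for (ly in rev(Filter(function(l) l$block == "stem", lys))) {
      r <- run_layer_bwd(ly, dh, caches[[ly$name]])
      dh <- r$dx
      if (!is.null(r$grads)) grads[[ly$name]] <- r$grads
    }
  }
  grads
}

#' Predict ages for a batch of records
#'
#' @param object an \code{ecg_model}.
#' @param newdata array of dim (records, 12, samples) with samples equal to
#'   the graph input length (zero-pad with \code{\link{pad_to_grid}} first),
#'   or a single \code{ecg_record}.
#' @param ... unused.
#' @return Numeric vector of predicted ages (years), one per record.
#' @export
predict.ecg_model <- function(object, newdata, ...) {
  if (inherits(newdata, "ecg_record")) {
    sig <- pad_to_grid(newdata$signal)
    newdata <- array(0, dim = c(1L, 12L, object$input_len))
    newdata[1, , seq_len(min(ncol(sig), object$input_len))] <-
      sig[, seq_len(min(ncol(sig), object$input_len))]
  }
  model_forward(object, newdata, training = FALSE)$pred
}

## ---- freezing and serialization ---------------------------------------

param_names <- function(layer) {
  switch(layer$kind,
         conv1d = if (is.null(layer$b)) "W" else c("W", "b"),
         spatial_conv = c("W", "b"),
         linear = c("W", "b"),
         batchnorm = c("gamma", "beta"),
         character(0))
}

#' Freeze the early layers of a residual network for fine-tuning
#'
#' With \code{boundary = "through_resblock3"}, all parameters up to and
#' including the third residual block are frozen (their batch-normalization
#' statistics are held in inference mode); the fourth block and the head
#' remain trainable. \code{"none"} marks everything trainable.
#'
#' @param graph an \code{ecg_model} built by \code{\link{build_resnet1d}}.
#' @param boundary \code{"through_resblock3"} or \code{"none"}.
#' @return The graph with updated \code{frozen} flags.
#' @export
freeze_scope <- function(graph, boundary = c("through_resblock3", "none")) {
  boundary <- match.arg(boundary)
  if (boundary == "none") {
    for (nm in names(graph$layers)) graph$layers[[nm]]$frozen <- FALSE
    return(graph)
  }
  if (graph$arch != "resnet1d" ||
      !any(startsWith(names(graph$layers), "res3_")))
    stop_ecg("freeze boundary `%s` requires a resnet1d graph with a third residual block",
             boundary)
  frozen_blocks <- c("stem", "res1", "res2", "res3")
  for (nm in names(graph$layers))
    graph$layers[[nm]]$frozen <- graph$layers[[nm]]$block %in% frozen_blocks
  graph
}

#' Count trainable parameters of a graph
#'
#' @param graph an \code{ecg_model}.
#' @return Number of scalar parameters in unfrozen layers.
#' @export
trainable_params <- function(graph) {
  sum(vapply(graph$layers, function(ly) {
    if (isTRUE(ly$frozen)) return(0)
    sum(vapply(param_names(ly), function(p) length(ly[[p]]), numeric(1)))
  }, numeric(1)))
}

#' Serialize model weights as raw 32-bit floats plus a JSON manifest
#'
#' The weight file holds exactly 4 bytes per parameter, so the file size in
#' decimal MB matches \code{\link{disk_mb}}.
#'
#' @param graph an \code{ecg_model}.
#' @param prefix output path prefix; writes \code{<prefix>.bin} and
#'   \code{<prefix>.json}.
#' @return Invisibly, the manifest path.
#' @export
save_weights <- function(graph, prefix) {
  man <- list()
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con), add = TRUE)
  for (ly in graph$layers) {
    for (p in param_names(ly)) {
      v <- ly[[p]]
      man[[paste(ly$name, p, sep = ".")]] <-
        if (is.matrix(v)) dim(v) else length(v)
      writeBin(as.numeric(v), con, size = 4L, endian = "little")
    }
  }
  jsonlite::write_json(man, paste0(prefix, ".json"), auto_unbox = FALSE)
  invisible(paste0(prefix, ".json"))
}

#' Load serialized weights into a compatible graph
#'
#' @param graph an \code{ecg_model} whose layer shapes must match the
#'   manifest; mismatches raise an error listing the offending layers.
#' @param prefix path prefix used in \code{\link{save_weights}}.
#' @return The graph with weights replaced.
#' @export
load_weights <- function(graph, prefix) {
  man <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  bad <- character(0)
  for (ly in graph$layers) for (p in param_names(ly)) {
    key <- paste(ly$name, p, sep = ".")
    v <- ly[[p]]
    want <- if (is.matrix(v)) dim(v) else length(v)
    if (is.null(man[[key]]) || !identical(as.integer(man[[key]]),
                                          as.integer(want)))
      bad <- c(bad, key)
  }
  if (length(bad))
    stop_ecg("weight manifest mismatch for: %s", paste(bad, collapse = ", "))
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con), add = TRUE)
  for (nm in names(graph$layers)) {
    ly <- graph$layers[[nm]]
    for (p in param_names(ly)) {
      v <- ly[[p]]
      vals <- readBin(con, "numeric", n = length(v), size = 4L,
                      endian = "little")
      if (is.matrix(v)) graph$layers[[nm]][[p]] <- matrix(vals, nrow(v))
      else graph$layers[[nm]][[p]] <- vals
    }
  }
  graph
}
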