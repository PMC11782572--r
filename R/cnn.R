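# Minimal convolutional network engine -------------------------------------
#
# Realizes an architecture_plan layer-for-layer on 16x16x1 inputs.
# Activations travel as arrays (channels, height, width, batch) until the
# first fully connected layer, then as (features, batch) matrices.
# Convolutions use "same" zero padding and stride 1 (only pooling changes
# the spatial size, matching the codec's dimension simulation); they are
# evaluated as im2col gathers followed by one BLAS matrix product, which is
# what keeps desk-scale training fast in plain R. Hidden fully connected
# layers apply ReLU; the output layer is softmax with cross-entropy loss.

.im2col_cache <- new.env(parent = emptyenv())

# Precompute gather indices mapping a padded (C, H+2p, W+2p) sample to the
# (Fs^2*C) x (H*W) im2col matrix; kernel dim runs channel-fastest, output
# pixels run row-fastest (column-major over (row, col)).
.im2col_index <- function(C, H, W, Fs) {
  key <- paste(C, H, W, Fs, sep = "x")
  if (!is.null(.im2col_cache[[key]])) return(.im2col_cache[[key]])
  p <- (Fs - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  kk <- expand.grid(c = seq_len(C), di = 0:(Fs - 1L), dj = 0:(Fs - 1L))
  px <- expand.grid(i = seq_len(H), j = seq_len(W))
  # linear index into (C, Hp, Wp) for kernel element k at output pixel x
  idx <- outer(seq_len(nrow(kk)), seq_len(nrow(px)), function(a, b) {
    kk$c[a] + (px$i[b] + kk$di[a] - 1L) * C +
      (px$j[b] + kk$dj[a] - 1L) * C * Hp
  })
  out <- list(idx = as.integer(idx), p = p, Hp = Hp, Wp = Wp,
              kdim = nrow(kk), npix = nrow(px),
              groups = sort(unique(as.integer(idx))))
  .im2col_cache[[key]] <- out
  out
}

.pad_input <- function(x, p) {
  d <- dim(x)                     # (C, H, W, B)
  if (p == 0L) return(x)
  out <- array(0, c(d[1], d[2] + 2L * p, d[3] + 2L * p, d[4]))
  out[, p + seq_len(d[2]), p + seq_len(d[3]), ] <- x
  out
}

# Convolution forward: x (C,H,W,B) -> (filters,H,W,B)
.conv_forward <- function(layer, x) {
  d <- dim(x)
  ii <- .im2col_index(d[1], d[2], d[3], layer$params$filter_size)
  xp <- .pad_input(x, ii$p)
  dim(xp) <- c(length(xp) / d[4], d[4])
  cols <- xp[ii$idx, , drop = FALSE]
  dim(cols) <- c(ii$kdim, ii$npix * d[4])
  y <- layer$W %*% cols + layer$b
  dim(y) <- c(nrow(layer$W), d[2], d[3], d[4])
  layer$cache <- list(cols = cols, in_dim = d, ii = ii)
  list(layer = layer, out = y)
}

.conv_backward <- function(layer, dy) {
  cc <- layer$cache
  d <- cc$in_dim
  dim(dy) <- c(nrow(layer$W), cc$ii$npix * d[4])
  layer$grads <- list(W = tcrossprod(dy, cc$cols), b = rowSums(dy))
  dcols <- crossprod(layer$W, dy)            # (kdim, npix*B)
  dim(dcols) <- c(cc$ii$kdim * cc$ii$npix, d[4])
  agg <- rowsum(dcols, cc$ii$idx)            # groups sorted ascending
  dxp <- matrix(0, d[1] * cc$ii$Hp * cc$ii$Wp, d[4])
  dxp[cc$ii$groups, ] <- agg
  dim(dxp) <- c(d[1], cc$ii$Hp, cc$ii$Wp, d[4])
  p <- cc$ii$p
  dx <- dxp[, p + seq_len(d[2]), p + seq_len(d[3]), , drop = FALSE]
  layer$cache <- NULL
  list(layer = layer, dx = dx)
}

# Batch normalization over (H, W, B) per channel.
.bn_forward <- function(layer, x, training) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1], prod(d[-1]))
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm^2) - mu^2
    layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
    layer$run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  invstd <- 1 / sqrt(v + layer$eps)
  xhat <- (xm - mu) * invstd
  y <- layer$gamma * xhat + layer$beta
  dim(y) <- d
  if (training) layer$cache <- list(xhat = xhat, invstd = invstd, d = d)
  list(layer = layer, out = y)
}

.bn_backward <- function(layer, dy) {
  cc <- layer$cache
  d <- cc$d
  n <- prod(d[-1])
  dim(dy) <- c(d[1], n)
  layer$grads <- list(gamma = rowSums(dy * cc$xhat), beta = rowSums(dy))
  dxhat <- dy * layer$gamma
  dx <- cc$invstd / n *
    (n * dxhat - rowSums(dxhat) - cc$xhat * rowSums(dxhat * cc$xhat))
  dim(dx) <- d
  layer$cache <- NULL
  list(layer = layer, dx = dx)
}

.relu_forward <- function(layer, x) {
  mask <- x > 0
  layer$cache <- mask
  x[!mask] <- 0
  list(layer = layer, out = x)
}

.relu_backward <- function(layer, dy) {
  dy[!layer$cache] <- 0
  layer$cache <- NULL
  list(layer = layer, dx = dy)
}

# Max pooling, kernel = stride = P, floor semantics (trailing rows/cols
# beyond Ho*P are dropped; their gradient is zero).
.pool_forward <- function(layer, x) {
  P <- layer$params$pool_size
  d <- dim(x)
  Ho <- d[2] %/% P; Wo <- d[3] %/% P
  out <- array(-Inf, c(d[1], Ho, Wo, d[4]))
  for (pi in seq_len(P)) {
    for (pj in seq_len(P)) {
      sub <- x[, seq.int(pi, Ho * P, by = P), seq.int(pj, Wo * P, by = P), ,
               drop = FALSE]
      out <- pmax(out, sub)
    }
  }
  layer$cache <- list(x = x, out = out, d = d, Ho = Ho, Wo = Wo)
  list(layer = layer, out = out)
}

.pool_backward <- function(layer, dy) {
  cc <- layer$cache
  P <- layer$params$pool_size
  dx <- array(0, cc$d)
  assigned <- array(FALSE, dim(cc$out))
  for (pi in seq_len(P)) {
    for (pj in seq_len(P)) {
      ri <- seq.int(pi, cc$Ho * P, by = P)
      rj <- seq.int(pj, cc$Wo * P, by = P)
      sub <- cc$x[, ri, rj, , drop = FALSE]
      m <- (sub == cc$out) & !assigned      # ties routed to first position
      assigned <- assigned | m
      g <- array(0, dim(m))
      g[m] <- dy[m]
      dx[, ri, rj, ] <- g
    }
  }
  layer$cache <- NULL
  list(layer = layer, dx = dx)
}

# Fully connected; hidden layers (not the output) apply ReLU.
.fc_forward <- function(layer, x) {
  if (length(dim(x)) == 4L) {
    in_dim <- dim(x)
    dim(x) <- c(prod(in_dim[1:3]), in_dim[4])
  } else in_dim <- NULL
  z <- layer$W %*% x + layer$b
  a <- if (layer$hidden) pmax(z, 0) else z
  layer$cache <- list(x = x, z = z, in_dim = in_dim)
  list(layer = layer, out = a)
}

.fc_backward <- function(layer, dy) {
  cc <- layer$cache
  if (layer$hidden) dy[cc$z <= 0] <- 0
  layer$grads <- list(W = tcrossprod(dy, cc$x), b = rowSums(dy))
  dx <- crossprod(layer$W, dy)
  if (!is.null(cc$in_dim)) dim(dx) <- cc$in_dim
  layer$cache <- NULL
  list(layer = layer, dx = dx)
}

.softmax <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

#' Build a trainable classifier from an architecture plan
#'
#' Layer-for-layer realization on 16x16x1 input with a two-way softmax
#' output. He-normal weight initialization, deterministic per seed.
#'
#' @param plan a validated/repaired `architecture_plan`.
#' @param seed integer seed for weight initialization.
#' @return an object of class `cnn_model`.
#' @export
build_model <- function(plan, seed = 1L) {
  stopifnot(inherits(plan, "architecture_plan"))
  with_seed(seed, {
    C <- plan$input_shape[3]; H <- plan$input_shape[1]; W <- plan$input_shape[2]
    layers <- list()
    flat <- NULL
    specs <- plan$layers
    n_fc_total <- sum(vapply(specs, `[[`, character(1), "kind") ==
                        "fully_connected")
    fc_seen <- 0L
    for (ls in specs) {
      layer <- ls
      if (ls$kind == "convolution") {
        fan_in <- ls$params$filter_size^2 * C
        layer$W <- matrix(stats::rnorm(ls$params$filters * fan_in,
                                       sd = sqrt(2 / fan_in)),
                          nrow = ls$params$filters)
        layer$b <- rep(0, ls$params$filters)
        C <- ls$params$filters
      } else if (ls$kind == "batch_normalization") {
        layer$gamma <- rep(1, C); layer$beta <- rep(0, C)
        layer$run_mean <- rep(0, C); layer$run_var <- rep(1, C)
        layer$momentum <- 0.9; layer$eps <- 1e-5
      } else if (ls$kind == "max_pooling") {
        P <- ls$params$pool_size
        H <- H %/% P; W <- W %/% P
        if (H < 1 || W < 1) stop("pooling reduces dimension below 1",
                                 call. = FALSE)
      } else if (ls$kind == "fully_connected") {
        fc_seen <- fc_seen + 1L
        in_dim <- if (is.null(flat)) C * H * W else flat
        units <- ls$params$units
        layer$W <- matrix(stats::rnorm(units * in_dim, sd = sqrt(2 / in_dim)),
                          nrow = units)
        layer$b <- rep(0, units)
        layer$hidden <- fc_seen < n_fc_total
        flat <- units
      }
      layers <- c(layers, list(layer))
    }
    structure(list(layers = layers, plan = plan, seed = seed, t_step = 0L,
                   trained_epochs = 0L, loss_trace = numeric(0)),
              class = "cnn_model")
  })
}

# frames matrix (B x 256, row-major 16x16) -> input array (1, 16, 16, B)
.frames_to_input <- function(x) {
  side <- as.integer(sqrt(ncol(x)))
  a <- array(t(x), c(side, side, nrow(x)))   # [col, row, b]
  a <- aperm(a, c(2, 1, 3))                  # [row, col, b]
  dim(a) <- c(1L, side, side, nrow(x))
  a
}

.model_forward <- function(model, x, training = FALSE) {
  out <- x
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    r <- switch(l$kind,
      convolution = .conv_forward(l, out),
      batch_normalization = .bn_forward(l, out, training),
      activation = .relu_forward(l, out),
      max_pooling = .pool_forward(l, out),
      fully_connected = .fc_forward(l, out))
    model$layers[[i]] <- r$layer
    out <- r$out
  }
  list(model = model, scores = out)
}

.model_backward <- function(model, dy) {
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    r <- switch(l$kind,
      convolution = .conv_backward(l, dy),
      batch_normalization = .bn_backward(l, dy),
      activation = .relu_backward(l, dy),
      max_pooling = .pool_backward(l, dy),
      fully_connected = .fc_backward(l, dy))
    model$layers[[i]] <- r$layer
    dy <- r$dx
  }
  model
}

.layer_params <- function(kind) {
  switch(kind,
         convolution = c("W", "b"),
         fully_connected = c("W", "b"),
         batch_normalization = c("gamma", "beta"),
         character(0))
}

.apply_updates <- function(model, options) {
  lr <- options$learning_rate
  t <- model$t_step
  # fold the adam bias corrections into two scalars so the per-parameter
  # arithmetic stays at a handful of vectorized passes
  if (options$optimizer == "adam") {
    a <- lr * sqrt(1 - 0.999^t) / (1 - 0.9^t)
    epsb <- 1e-8 * sqrt(1 - 0.999^t)
  }
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    for (pn in .layer_params(l$kind)) {
      g <- l$grads[[pn]]
      if (is.null(g)) next
      st <- l$opt_state[[pn]]
      if (is.null(st)) st <- list(m = g * 0, v = g * 0)
      dims <- dim(l[[pn]])
      if (options$optimizer == "adam") {
        r <- .fused_adam(l[[pn]], st$m, st$v, g, a, epsb)
        l[[pn]] <- r$w; st$m <- r$m; st$v <- r$v
      } else if (options$optimizer == "sgdm") {
        r <- .fused_sgdm(l[[pn]], st$m, g, lr)
        l[[pn]] <- r$w; st$m <- r$m
      } else {                                   # rmsprop
        r <- .fused_rmsprop(l[[pn]], st$v, g, lr)
        l[[pn]] <- r$w; st$v <- r$v
      }
      if (!is.null(dims)) dim(l[[pn]]) <- dims
      l$opt_state[[pn]] <- st
      l$grads[[pn]] <- NULL
    }
    model$layers[[i]] <- l
  }
  model
}

#' Training options
#'
#' Reference settings: 10 epochs per stage at learning rate 0.001.
#'
#' @param optimizer `"adam"`, `"sgdm"` (SGD with momentum 0.9) or
#'   `"rmsprop"`.
#' @param batch_size one of 8, 16, 32, 64, 128.
#' @param epochs full passes over the training split (>= 0).
#' @param learning_rate fixed learning rate.
#' @param seed integer seed for shuffling.
#' @return an object of class `training_options`.
#' @export
training_options <- function(optimizer = "adam", batch_size = 32L,
                             epochs = 10L, learning_rate = 0.001,
                             seed = 1L) {
  if (!optimizer %in% OPTIMIZER_CHOICES) {
    stop_field("optimizer", paste("must be one of",
                                  paste(OPTIMIZER_CHOICES, collapse = ", ")))
  }
  if (!batch_size %in% BATCH_CHOICES) {
    stop_field("batch_size", paste("must be one of",
                                   paste(BATCH_CHOICES, collapse = ", ")))
  }
  structure(list(optimizer = optimizer, batch_size = as.integer(batch_size),
                 epochs = check_count(epochs, "epochs", min = 0L),
                 learning_rate = learning_rate,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "training_options")
}

#' Train a model on labeled frames
#'
#' Runs exactly `options$epochs` shuffled passes with the chosen optimizer
#' at a fixed learning rate, minimizing softmax cross-entropy. A non-finite
#' loss aborts with an error (treated as an objective failure by the
#' search).
#'
#' @param model a `cnn_model`.
#' @param x numeric matrix, frames in rows (256 columns, row-major 16x16).
#' @param y integer class labels in \{1, 2\}.
#' @param options a [training_options()].
#' @return the fitted model; `model$loss_trace` has one mean-loss entry per
#'   epoch.
#' @export
train_model <- function(model, x, y, options = training_options()) {
  stopifnot(inherits(model, "cnn_model"), nrow(x) == length(y))
  if (options$epochs == 0L) return(model)
  if (length(unique(y)) < 2L) stop("training split must contain both classes",
                                   call. = FALSE)
  n <- nrow(x)
  xa <- .frames_to_input(x)              # one layout pass for all epochs
  with_seed(derive_seed(options$seed, 101L), {
    for (ep in seq_len(options$epochs)) {
      ord <- sample(n)
      starts <- seq.int(1L, n, by = options$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[seq.int(s, min(s + options$batch_size - 1L, n))]
        xb <- xa[, , , idx, drop = FALSE]
        yb <- y[idx]
        fw <- .model_forward(model, xb, training = TRUE)
        model <- fw$model
        probs <- .softmax(fw$scores)
        eps <- 1e-12
        ll <- -mean(log(probs[cbind(yb, seq_along(yb))] + eps))
        if (!is.finite(ll)) stop("training diverged: non-finite loss",
                                 call. = FALSE)
        ep_loss <- ep_loss + ll * length(idx)
        dy <- probs
        dy[cbind(yb, seq_along(yb))] <- dy[cbind(yb, seq_along(yb))] - 1
        dy <- dy / length(idx)
        model$t_step <- model$t_step + 1L
        model <- .model_backward(model, dy)
        model <- .apply_updates(model, options)
      }
      model$loss_trace <- c(model$loss_trace, ep_loss / n)
      model$trained_epochs <- model$trained_epochs + 1L
    }
  })
  model
}

#' Class scores for frames
#'
#' @param model a fitted `cnn_model`.
#' @param x frames matrix (rows of 256).
#' @param chunk evaluation batch size.
#' @return matrix n x 2 of class probabilities (columns: class 1, class 2);
#'   rows sum to 1.
#' @export
predict_scores <- function(model, x, chunk = 256L) {
  out <- matrix(0, nrow(x), model$plan$n_classes)
  starts <- seq.int(1L, nrow(x), by = chunk)
  for (s in starts) {
    idx <- seq.int(s, min(s + chunk - 1L, nrow(x)))
    fw <- .model_forward(model, .frames_to_input(x[idx, , drop = FALSE]),
                         training = FALSE)
    out[idx, ] <- t(.softmax(fw$scores))
  }
  colnames(out) <- paste0("class", seq_len(ncol(out)))
  out
}

#' Count of trainable parameters
#' @param model a `cnn_model`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(l) {
    sum(vapply(.layer_params(l$kind), function(pn) length(l[[pn]]),
               numeric(1)))
  }, numeric(1)))
}
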