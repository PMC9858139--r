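# Internal mini-batch training engine for the lightweight CNN.
#
# Activations are (H*W*C) x batch matrices, pixel-major with channel
# last (index i + H*j + H*W*c), matching the C++ convolution kernels.
# The engine implements exactly the layer kinds the architecture emits:
# conv, batchnorm, softplus, avgpool, add, gap, dense, softmax (the
# softmax is fused with the cross-entropy loss; forward returns logits).

init_cnn_weights <- function(arch, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- shape_trace(arch)
  params <- vector("list", length(arch$layers))
  c_in <- arch$input_shape[3]
  for (i in seq_along(arch$layers)) {
    ls <- arch$layers[[i]]
    shp <- unlist(tr[tr$layer == i, c("H", "W", "C")], use.names = FALSE)
    if (ls$kind == "conv") {
      fan_in <- ls$kernel^2 * c_in
      params[[i]] <- list(
        W = matrix(rnorm(ls$filters * fan_in, sd = sqrt(2 / fan_in)),
                   ls$filters, fan_in),
        b = numeric(ls$filters))
    } else if (ls$kind == "batchnorm") {
      C <- shp[3]
      params[[i]] <- list(gamma = rep(1, C), xi = numeric(C),
                          run_mean = numeric(C), run_var = rep(1, C),
                          warm = FALSE)
    } else if (ls$kind == "dense") {
      params[[i]] <- list(
        W = matrix(rnorm(ls$units * c_in, sd = sqrt(2 / c_in)),
                   ls$units, c_in),
        b = numeric(ls$units))
    }
    c_in <- shp[3]
  }
  list(arch = arch, params = params, shapes = tr)
}

layer_in_shape <- function(net, i) {
  tr <- net$shapes
  unlist(tr[tr$layer == i - 1L, c("H", "W", "C")], use.names = FALSE)
}


# 2x2 stride-2 average-pooling gather indices (list of k*k index vectors).
avgpool_indices <- function(H, W, C, k, stride) {
  Ho <- (H - k) %/% stride + 1L
  Wo <- (W - k) %/% stride + 1L
  g <- expand.grid(io = 0:(Ho - 1L), jo = 0:(Wo - 1L), c = 0:(C - 1L))
  idx <- vector("list", k * k)
  m <- 0L
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    m <- m + 1L
    idx[[m]] <- (g$io * stride + di) + H * (g$jo * stride + dj) +
      H * W * g$c + 1L
  }
  idx
}

# Forward pass; returns list(logits, caches, net). `net` is returned
# because training mode updates batch-norm running statistics.
cnn_forward <- function(net, X, train = FALSE, keep_cache = train,
                        bn_momentum = 0.99) {
  layers <- net$arch$layers
  caches <- vector("list", length(layers))
  outputs <- vector("list", length(layers))
  need_out <- rep(FALSE, length(layers))
  for (l in layers) if (!is.na(l$from)) need_out[l$from] <- TRUE
  A <- X
  for (i in seq_along(layers)) {
    ls <- layers[[i]]
    shp <- layer_in_shape(net, i)
    HW <- shp[1] * shp[2]; C <- shp[3]; B <- ncol(A)
    if (ls$kind == "conv") {
      p <- net$params[[i]]
      if (keep_cache) caches[[i]] <- A
      A <- conv2d_forward_cpp(A, shp[1], shp[2], shp[3], p$W, p$b,
                              ls$kernel, ls$stride)
    } else if (ls$kind == "batchnorm") {
      p <- net$params[[i]]
      if (train) {
        st <- bn_stats_cpp(A, HW, C)
        mu <- st$mu; v <- st$var
        if (!p$warm) {  # warm-start running statistics from first batch
          net$params[[i]]$run_mean <- mu
          net$params[[i]]$run_var <- v
          net$params[[i]]$warm <- TRUE
        } else {
          net$params[[i]]$run_mean <- bn_momentum * p$run_mean +
            (1 - bn_momentum) * mu
          net$params[[i]]$run_var <- bn_momentum * p$run_var +
            (1 - bn_momentum) * v
        }
      } else {
        mu <- p$run_mean; v <- p$run_var
      }
      sdv <- sqrt(v + 1e-5)
      if (keep_cache) caches[[i]] <- list(x = A, mu = mu, sd = sdv)
      A <- bn_affine_cpp(A, p$gamma / sdv, p$xi - mu * p$gamma / sdv, HW)
    } else if (ls$kind == "softplus") {
      if (keep_cache) caches[[i]] <- A
      A <- softplus_cpp(A)
    } else if (ls$kind == "avgpool") {
      idx <- avgpool_indices(shp[1], shp[2], C, ls$kernel, ls$stride)
      S <- A[idx[[1]], , drop = FALSE]
      for (m in 2:length(idx)) S <- S + A[idx[[m]], , drop = FALSE]
      A <- S / length(idx)
    } else if (ls$kind == "add") {
      A <- A + outputs[[ls$from]]
    } else if (ls$kind == "gap") {
      dim(A) <- c(HW, C * B)
      A <- matrix(.colMeans(A, HW, C * B), C, B)
    } else if (ls$kind == "dense") {
      p <- net$params[[i]]
      if (keep_cache) caches[[i]] <- A
      A <- p$W %*% A + p$b
    } else if (ls$kind == "softmax") {
      # fused with the loss; logits pass through
    }
    if (need_out[i]) outputs[[i]] <- A
  }
  list(logits = A, caches = caches, net = net)
}

# Backward pass from dlogits; returns gradients mirroring net$params.
cnn_backward <- function(net, X, fw, dlogits) {
  layers <- net$arch$layers
  caches <- fw$caches
  grads <- vector("list", length(layers))
  dskip <- vector("list", length(layers))
  dA <- dlogits
  for (i in rev(seq_along(layers))) {
    ls <- layers[[i]]
    if (!is.null(dskip[[i]])) dA <- dA + dskip[[i]]
    shp <- layer_in_shape(net, i)
    HW <- shp[1] * shp[2]; C <- shp[3]
    if (ls$kind == "conv") {
      p <- net$params[[i]]
      bk <- conv2d_backward_cpp(caches[[i]], dA, shp[1], shp[2], shp[3],
                                p$W, ls$kernel, ls$stride)
      grads[[i]] <- list(W = bk$dW, b = as.numeric(bk$db))
      dA <- bk$dA
    } else if (ls$kind == "batchnorm") {
      p <- net$params[[i]]
      cc <- caches[[i]]
      bk <- bn_backward_cpp(cc$x, dA, cc$mu, cc$sd, p$gamma, HW)
      grads[[i]] <- list(gamma = bk$dgamma, xi = bk$dxi)
      dA <- bk$dx
    } else if (ls$kind == "softplus") {
      dA <- softplus_grad_cpp(caches[[i]], dA)
    } else if (ls$kind == "avgpool") {
      idx <- avgpool_indices(shp[1], shp[2], C, ls$kernel, ls$stride)
      dX <- matrix(0, HW * C, ncol(dA))
      g <- dA / length(idx)
      for (m in seq_along(idx)) dX[idx[[m]], ] <- dX[idx[[m]], ] + g
      dA <- dX
    } else if (ls$kind == "add") {
      dskip[[ls$from]] <- if (is.null(dskip[[ls$from]])) dA else
        dskip[[ls$from]] + dA
    } else if (ls$kind == "gap") {
      B <- ncol(dA)
      dA <- matrix(rep(as.vector(dA), each = HW) / HW, HW * C, B)
    } else if (ls$kind == "dense") {
      p <- net$params[[i]]
      grads[[i]] <- list(W = dA %*% t(caches[[i]]),
                         b = rowSums(dA))
      dA <- t(p$W) %*% dA
    }
    # softmax: identity
  }
  grads
}

# Recompute batch-norm running statistics with the final weights by a
# forward sweep over the training inputs (precise-BN calibration):
# aggregate mean = mean of batch means, aggregate variance =
# mean(var_b + mu_b^2) - mean(mu_b)^2. This makes inference-mode
# normalization consistent with the trained network even after short
# training runs, where momentum-tracked statistics lag the weights.
bn_calibrate <- function(net, X, batch_size = 32L) {
  bn_idx <- which(vapply(net$arch$layers, function(l)
    l$kind == "batchnorm", TRUE))
  acc <- lapply(bn_idx, function(i) list(mu = 0, m2 = 0))
  names(acc) <- as.character(bn_idx)
  nb <- 0L
  for (bi in split(seq_len(ncol(X)), ceiling(seq_len(ncol(X)) / batch_size))) {
    fw <- cnn_forward(net, X[, bi, drop = FALSE], train = TRUE,
                      keep_cache = TRUE)
    nb <- nb + 1L
    for (i in bn_idx) {
      cc <- fw$caches[[i]]
      v <- cc$sd^2 - 1e-5
      key <- as.character(i)
      acc[[key]]$mu <- acc[[key]]$mu + cc$mu
      acc[[key]]$m2 <- acc[[key]]$m2 + v + cc$mu^2
    }
  }
  for (i in bn_idx) {
    key <- as.character(i)
    mu <- acc[[key]]$mu / nb
    net$params[[i]]$run_mean <- mu
    net$params[[i]]$run_var <- pmax(acc[[key]]$m2 / nb - mu^2, 0)
    net$params[[i]]$warm <- TRUE
  }
  net
}

# Cross-entropy loss and logit gradient for labels y (1-based classes).
softmax_xent <- function(logits, y) {
  P <- softmax_prob(logits)
  B <- ncol(logits)
  picked <- P[cbind(y, seq_len(B))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dl <- P
  dl[cbind(y, seq_len(B))] <- dl[cbind(y, seq_len(B))] - 1
  list(loss = loss, dlogits = dl / B)
}

# ---- optimizers (update rules per the study's settings) ----------------

optimizer_defaults <- function(name) {
  base <- list(lr = 0.001, eps = 1e-6)
  extra <- switch(name,
    sgdm = list(momentum = 0.9),
    adam = , adamax = , nadam = list(beta1 = 0.9, beta2 = 0.999),
    adagrad = list(),
    adadelta = list(rho = 0.95),
    rmsprop = list(rho = 0.9),
    stop("unknown optimizer '", name, "'"))
  c(base, extra)
}

make_optimizer <- function(name = "adam", settings = list()) {
  name <- tolower(name)
  cfg <- utils::modifyList(optimizer_defaults(name), settings)
  state <- new.env(parent = emptyenv())
  state$t <- 0L
  state$slots <- list()
  step <- function(params, grads) {
    state$t <- state$t + 1L
    t <- state$t
    for (i in seq_along(grads)) {
      if (is.null(grads[[i]])) next
      for (nm in names(grads[[i]])) {
        key <- paste0(i, ".", nm)
        g <- grads[[i]][[nm]]
        w <- params[[i]][[nm]]
        sl <- state$slots[[key]]
        if (is.null(sl)) sl <- list(m = 0 * g, v = 0 * g)
        if (name == "sgdm") {
          sl$m <- cfg$momentum * sl$m + g
          w <- w - cfg$lr * sl$m
        } else if (name == "adam") {
          sl$m <- cfg$beta1 * sl$m + (1 - cfg$beta1) * g
          sl$v <- cfg$beta2 * sl$v + (1 - cfg$beta2) * g^2
          mhat <- sl$m / (1 - cfg$beta1^t)
          vhat <- sl$v / (1 - cfg$beta2^t)
          w <- w - cfg$lr * mhat / (sqrt(vhat) + cfg$eps)
        } else if (name == "adamax") {
          sl$m <- cfg$beta1 * sl$m + (1 - cfg$beta1) * g
          sl$v <- pmax(cfg$beta2 * sl$v, abs(g))
          w <- w - cfg$lr / (1 - cfg$beta1^t) * sl$m / (sl$v + cfg$eps)
        } else if (name == "nadam") {
          sl$m <- cfg$beta1 * sl$m + (1 - cfg$beta1) * g
          sl$v <- cfg$beta2 * sl$v + (1 - cfg$beta2) * g^2
          mhat <- cfg$beta1 * sl$m / (1 - cfg$beta1^(t + 1)) +
            (1 - cfg$beta1) * g / (1 - cfg$beta1^t)
          vhat <- sl$v / (1 - cfg$beta2^t)
          w <- w - cfg$lr * mhat / (sqrt(vhat) + cfg$eps)
        } else if (name == "adagrad") {
          sl$v <- sl$v + g^2
          w <- w - cfg$lr * g / (sqrt(sl$v) + cfg$eps)
        } else if (name == "adadelta") {
          sl$v <- cfg$rho * sl$v + (1 - cfg$rho) * g^2
          dx <- -sqrt(sl$m + cfg$eps) / sqrt(sl$v + cfg$eps) * g
          sl$m <- cfg$rho * sl$m + (1 - cfg$rho) * dx^2
          w <- w + cfg$lr * dx
        } else if (name == "rmsprop") {
          sl$v <- cfg$rho * sl$v + (1 - cfg$rho) * g^2
          w <- w - cfg$lr * g / (sqrt(sl$v) + cfg$eps)
        }
        state$slots[[key]] <- sl
        params[[i]][[nm]] <- w
      }
    }
    params
  }
  list(name = name, settings = cfg, step = step)
}

# ---- input preparation -------------------------------------------------

# Resize, min-max normalize to [0, 1], replicate to `channels`, and
# stack as the (H*W*C) x n input matrix.
prep_cnn_input <- function(images, input_size, channels = 3L) {
  n <- length(images)
  HW <- prod(input_size)
  X <- matrix(0, HW * channels, n)
  for (i in seq_len(n)) {
    img <- resize_image(as_image2d(images[[i]], range = range(images[[i]])),
                        input_size[1], input_size[2])
    v <- as.vector(normalize_image(img, c(0, 1))$pixels)
    X[, i] <- rep(v, channels)
  }
  X
}
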