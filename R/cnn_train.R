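#' Training configuration for the lightweight CNN
#'
#' Defaults follow the study protocol: batch size 64, 30 epochs, 5-fold
#' cross-validation, cross-entropy loss, and the published optimizer
#' hyperparameters (learning rate 0.001; SGDM momentum 0.9; Adam-family
#' beta1 = 0.9, beta2 = 0.999; epsilon 1e-6; Adadelta rho 0.95;
#' RMSProp rho 0.9).
#'
#' @param optimizer One of `"sgdm"`, `"adam"`, `"adamax"`, `"nadam"`,
#'   `"adagrad"`, `"adadelta"`, `"rmsprop"`.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param folds Cross-validation folds (>= 2).
#' @param seed Integer seed controlling weight init, shuffling, folds.
#' @param input_size Spatial size images are resized to at the CNN
#'   boundary.
#' @param augment Optional [augment_config()] applied to the training
#'   split of each fold only (never to test folds).
#' @param bn_momentum Running-statistics momentum for batch norm.
#' @param settings Named list of optimizer hyperparameter overrides.
#' @return An object of class `cnn_train_config`.
#' @export
cnn_train_config <- function(optimizer = "adam", batch_size = 64L,
                             epochs = 30L, folds = 5L, seed = 1L,
                             input_size = 224L, augment = NULL,
                             bn_momentum = 0.99, settings = list()) {
  if (folds < 2L) stop("cnn_train_config: folds must be >= 2")
  optimizer <- tolower(optimizer)
  optimizer_defaults(optimizer)  # validates the name
  if (length(input_size) == 1L) input_size <- rep(input_size, 2L)
  structure(list(optimizer = optimizer, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), folds = as.integer(folds),
                 seed = as.integer(seed), input_size = as.integer(input_size),
                 augment = augment, bn_momentum = bn_momentum,
                 settings = settings),
            class = "cnn_train_config")
}

#' Stratified k-fold split
#'
#' Partitions indices into `k` disjoint test folds covering every index
#' exactly once, stratified so each fold's class ratio is within one
#' sample of the global ratio.
#'
#' @param labels Class labels (factor or character), one per sample.
#' @param k Number of folds.
#' @param seed Integer seed; the same seed yields the same folds.
#' @return List of `k` elements, each `list(train = ..., test = ...)`.
#' @export
#' @examples
#' folds <- kfold_split(rep(c("a", "b"), c(4, 6)), k = 5, seed = 1)
#' sort(unlist(lapply(folds, `[[`, "test")))
kfold_split <- function(labels, k, seed = 1L) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (k < 2L || k > n) stop("kfold_split: need 2 <= k <= n")
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fold <- integer(n)
  loads <- integer(k)
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    nc <- length(idx)
    base <- nc %/% k
    extra <- nc %% k
    # distribute this class's surplus to the currently lightest folds so
    # overall fold sizes stay within one sample of each other
    quota <- rep(base, k)
    if (extra > 0) quota[order(loads, sample(k))[seq_len(extra)]] <- base + 1
    fold[idx] <- rep(seq_len(k), quota)
    loads <- loads + quota
  }
  lapply(seq_len(k), function(f)
    list(train = which(fold != f), test = which(fold == f)))
}

#' Fit the lightweight CNN on labeled images
#'
#' Mini-batch training with softmax cross-entropy. Images are resized to
#' `config$input_size`, min-max normalized, and replicated to the
#' architecture's channel count at the CNN boundary.
#'
#' @param images List of [image2d()] objects.
#' @param labels Labels over `{"normal","abnormal"}` (both classes must
#'   be present).
#' @param arch Architecture from [build_lightweight_cnn()]; defaults to
#'   the standard build at `config$input_size`.
#' @param config A [cnn_train_config()].
#' @param verbose Print per-epoch loss?
#' @return An object of class `cnn_fit` with elements `net`, `classes`,
#'   `config`, `loss` (per-epoch mean loss).
#' @export
fit_cnn <- function(images, labels, arch = NULL,
                    config = cnn_train_config(), verbose = FALSE) {
  labels <- factor(as.character(labels), levels = c("normal", "abnormal"))
  if (nlevels(droplevels(labels)) < 2L)
    stop("fit_cnn: training data must contain both classes")
  if (is.null(arch))
    arch <- build_lightweight_cnn(input_size = config$input_size)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  X <- prep_cnn_input(images, config$input_size, arch$input_shape[3])
  y <- as.integer(labels)
  net <- init_cnn_weights(arch)
  opt <- make_optimizer(config$optimizer, config$settings)
  n <- ncol(X)
  losses <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(n)
    bl <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    eploss <- 0
    for (bi in bl) {
      Xb <- X[, bi, drop = FALSE]
      fw <- cnn_forward(net, Xb, train = TRUE,
                        bn_momentum = config$bn_momentum)
      net <- fw$net
      lo <- softmax_xent(fw$logits, y[bi])
      if (!is.finite(lo$loss))
        stop("fit_cnn: loss diverged (NaN) under optimizer '",
             config$optimizer, "'")
      grads <- cnn_backward(net, Xb, fw, lo$dlogits)
      net$params <- opt$step(net$params, grads)
      eploss <- eploss + lo$loss * length(bi)
    }
    losses[ep] <- eploss / n
    if (verbose)
      message(sprintf("epoch %d/%d loss=%.4f", ep, config$epochs, losses[ep]))
  }
  net <- bn_calibrate(net, X, batch_size = min(32L, n))
  structure(list(net = net, classes = levels(labels), config = config,
                 loss = losses),
            class = "cnn_fit")
}

#' @export
print.cnn_fit <- function(x, ...) {
  cat(sprintf("cnn_fit: %s optimizer, %d epochs, final loss %.4f\n",
              x$config$optimizer, x$config$epochs, tail(x$loss, 1)))
  invisible(x)
}

#' Predict classes or probabilities from a fitted CNN
#'
#' @param object A [fit_cnn()] result.
#' @param images List of [image2d()] objects.
#' @param type `"class"` (factor) or `"prob"` (matrix, one row per
#'   image, columns `normal`/`abnormal`).
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return Factor of predicted labels, or a probability matrix.
#' @export
predict.cnn_fit <- function(object, images, type = c("class", "prob"),
                            batch_size = 32L, ...) {
  type <- match.arg(type)
  X <- prep_cnn_input(images, object$config$input_size,
                      object$net$arch$input_shape[3])
  n <- ncol(X)
  probs <- matrix(NA_real_, n, length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (bi in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    fw <- cnn_forward(object$net, X[, bi, drop = FALSE], train = FALSE,
                      keep_cache = FALSE)
    probs[bi, ] <- t(softmax_prob(fw$logits))
  }
  if (type == "prob") return(probs)
  factor(object$classes[max.col(probs)], levels = object$classes)
}

#' Cross-validated training and evaluation
#'
#' Stratified k-fold protocol over the original images: the training
#' split of each fold is (optionally) augmented, the model is fitted,
#' and the held-out fold is scored with [classification_metrics()].
#' Augmented variants never straddle folds because augmentation happens
#' after the split.
#'
#' @param ds A [labeled_dataset()] containing both classes.
#' @param arch Architecture; default standard build at
#'   `config$input_size`.
#' @param config A [cnn_train_config()].
#' @param verbose Print fold progress?
#' @return An object of class `cnn_cv`: `fold_metrics` (one row per
#'   fold, percent scale), `summary` (mean and SD per metric), `folds`.
#' @export
train_and_evaluate <- function(ds, arch = NULL, config = cnn_train_config(),
                               verbose = FALSE) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (nlevels(droplevels(ds$labels)) < 2L)
    stop("train_and_evaluate: dataset must contain both classes")
  folds <- kfold_split(ds$labels, config$folds, config$seed)
  reports <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    tr_idx <- folds[[f]]$train
    te_idx <- folds[[f]]$test
    tr_imgs <- ds$images[tr_idx]
    tr_labs <- ds$labels[tr_idx]
    if (!is.null(config$augment)) {
      aug <- augment_dataset(labeled_dataset(tr_imgs, tr_labs),
                             config$augment)
      tr_imgs <- aug$images
      tr_labs <- aug$labels
    }
    fit <- fit_cnn(tr_imgs, tr_labs, arch = arch, config = config)
    pred <- predict(fit, ds$images[te_idx])
    cc <- confusion_counts(pred, ds$labels[te_idx], positive = "abnormal")
    reports[[f]] <- classification_metrics(cc)
    if (verbose)
      message(sprintf("fold %d/%d accuracy=%.2f%%", f, length(folds),
                      reports[[f]]$accuracy))
  }
  fold_metrics <- do.call(rbind, lapply(seq_along(reports), function(f)
    cbind(fold = f, as.data.frame(unclass(reports[[f]])))))
  structure(list(fold_metrics = fold_metrics,
                 summary = summarize_folds(reports),
                 folds = folds, config = config),
            class = "cnn_cv")
}

#' @export
print.cnn_cv <- function(x, ...) {
  cat(sprintf("cnn_cv: %d folds, optimizer %s\n",
              nrow(x$fold_metrics), x$config$optimizer))
  print(round(x$fold_metrics, 2), row.names = FALSE)
  cat("summary (mean +/- sd):\n")
  print(round(x$summary, 2))
  invisible(x)
}

#' @export
summary.cnn_cv <- function(object, ...) object$summary
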