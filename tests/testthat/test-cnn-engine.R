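bl <- asNamespace("brainlite")

test_that("analytic gradients match finite differences on a mini network", {
  arch <- mini_arch()
  net <- bl$init_cnn_weights(arch, seed = 42)
  set.seed(1)
  B <- 3
  X <- matrix(runif(prod(arch$input_shape) * B), prod(arch$input_shape), B)
  y <- c(1L, 2L, 1L)
  lossfn <- function(net)
    bl$softmax_xent(bl$cnn_forward(net, X, train = TRUE)$logits, y)$loss
  net <- bl$cnn_forward(net, X, train = TRUE)$net  # warm BN statistics
  fw <- bl$cnn_forward(net, X, train = TRUE)
  lo <- bl$softmax_xent(fw$logits, y)
  gr <- bl$cnn_backward(net, X, fw, lo$dlogits)
  eps <- 1e-6
  for (i in seq_along(gr)) {
    if (is.null(gr[[i]])) next
    for (nm in names(gr[[i]])) {
      w <- net$params[[i]][[nm]]
      for (j in sample(length(w), min(4, length(w)))) {
        n2 <- net
        n2$params[[i]][[nm]][j] <- w[j] + eps
        lp <- lossfn(n2)
        n2$params[[i]][[nm]][j] <- w[j] - eps
        lm <- lossfn(n2)
        num <- (lp - lm) / (2 * eps)
        ana <- gr[[i]][[nm]][j]
        # conv biases feeding batch norm have an exactly-zero gradient;
        # compare only where the gradient is informative
        if (abs(num) + abs(ana) > 1e-6)
          expect_lt(abs(num - ana) / (abs(num) + abs(ana)), 1e-4)
      }
    }
  }
})

test_that("forward logits have the declared shape and are finite", {
  arch <- mini_arch()
  net <- bl$init_cnn_weights(arch, seed = 3)
  X <- matrix(runif(144 * 5), 144, 5)
  fw <- bl$cnn_forward(net, X, train = FALSE, keep_cache = FALSE)
  expect_equal(dim(fw$logits), c(2L, 5L))
  expect_true(all(is.finite(fw$logits)))
})

test_that("every configured optimizer reduces the training loss", {
  arch <- mini_arch()
  set.seed(10)
  B <- 16
  X <- matrix(runif(144 * B), 144, B)
  # make the task learnable: class depends on mean intensity
  y <- ifelse(colMeans(X) > median(colMeans(X)), 2L, 1L)
  for (optname in c("sgdm", "adam", "adamax", "nadam", "adagrad",
                    "adadelta", "rmsprop")) {
    net <- bl$init_cnn_weights(arch, seed = 5)
    opt <- bl$make_optimizer(optname, list(lr = 0.01))
    losses <- numeric(25)
    for (it in 1:25) {
      fw <- bl$cnn_forward(net, X, train = TRUE)
      net <- fw$net
      lo <- bl$softmax_xent(fw$logits, y)
      losses[it] <- lo$loss
      gr <- bl$cnn_backward(net, X, fw, lo$dlogits)
      net$params <- opt$step(net$params, gr)
    }
    expect_lt(losses[25], losses[1])
  }
})

test_that("single-class training data is rejected and divergence is named", {
  imgs <- replicate(4, image2d(matrix(runif(64, 0, 255), 8, 8)),
                    simplify = FALSE)
  expect_error(fit_cnn(imgs, rep("normal", 4)), "both classes")
})

test_that("BN calibration makes inference match training-mode statistics", {
  arch <- mini_arch()
  net <- bl$init_cnn_weights(arch, seed = 8)
  set.seed(2)
  X <- matrix(runif(144 * 24), 144, 24)
  net <- bl$bn_calibrate(net, X, batch_size = 24L)
  fw_tr <- bl$cnn_forward(net, X, train = TRUE)
  fw_ev <- bl$cnn_forward(net, X, train = FALSE, keep_cache = FALSE)
  # calibrated over the same single batch, the running statistics equal
  # the batch statistics, so inference reproduces training-mode logits
  expect_equal(fw_ev$logits, fw_tr$logits, tolerance = 1e-6)
})
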