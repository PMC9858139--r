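test_that("valid-padding shape rule and its error path", {
  expect_equal(conv_out_shape(c(224, 224, 3), 5, 2, 32), c(110, 110, 32))
  expect_equal(conv_out_shape(c(110, 110, 32), 3, 2, 48), c(54, 54, 48))
  expect_equal(conv_out_shape(c(7, 7, 128), 1, 1, 128), c(7, 7, 128))
  expect_error(conv_out_shape(c(3, 3, 8), 5, 1, 8), "kernel")
})

test_that("convolution and batch-norm parameter formulas", {
  expect_equal(conv_param_count(5, 3, 32), 2432L)
  expect_equal(conv_param_count(3, 32, 48), 13872L)
  expect_equal(conv_param_count(1, 64, 64), 4160L)
  expect_equal(sum(bn_param_count(32)), 128L)
  expect_equal(sum(bn_param_count(48)), 192L)
  expect_equal(bn_param_count(64), c(trainable = 128L, nontrainable = 128L))
})

test_that("the default build reproduces the published activation table", {
  tr <- shape_trace(build_lightweight_cnn())
  hw <- function(i) unlist(tr[tr$layer == i, c("H", "W", "C")],
                           use.names = FALSE)
  expect_equal(hw(0), c(224, 224, 3))
  conv_rows <- tr[tr$kind == "conv", ]
  expect_equal(conv_rows$H, c(110, 54, 52, 52, 24, 22, 22, 9, 7, 7))
  expect_equal(conv_rows$C, c(32, 48, 48, 48, 64, 64, 64, 128, 128, 128))
  pool_rows <- tr[tr$kind == "avgpool", ]
  expect_equal(pool_rows$H, c(26, 11, 3))
  # batch norm and softplus preserve shape everywhere
  for (i in which(tr$kind %in% c("batchnorm", "softplus", "add")))
    expect_equal(unlist(tr[i, c("H", "W", "C")]),
                 unlist(tr[i - 1, c("H", "W", "C")]), ignore_attr = TRUE)
  expect_equal(hw(nrow(tr) - 1L), c(1, 1, 2))  # dense output
})

test_that("parameter accounting matches the published totals exactly", {
  pb <- count_params(build_lightweight_cnn())
  expect_equal(pb$trainable_total, 347954L)
  expect_equal(pb$nontrainable_total, 1504L)
  expect_equal(pb$total, 349458L)
  conv_p <- pb$layers$trainable[pb$layers$kind == "conv"]
  expect_equal(conv_p, c(2432, 13872, 20784, 2352, 27712, 36928, 4160,
                         73856, 147584, 16512))
  expect_equal(pb$layers$trainable[pb$layers$kind == "dense"], 258)
})

test_that("accounting agrees with an independent walk of the layer list", {
  # independent oracle: accumulate counts directly from kernel sizes and
  # a running channel counter, bypassing shape_trace/count_params
  arch <- build_lightweight_cnn()
  cin <- arch$input_shape[3]
  tr_tot <- 0; nt_tot <- 0
  for (ls in arch$layers) {
    if (ls$kind == "conv") {
      tr_tot <- tr_tot + ls$kernel^2 * cin * ls$filters + ls$filters
      cin <- ls$filters
    } else if (ls$kind == "batchnorm") {
      tr_tot <- tr_tot + 2 * cin
      nt_tot <- nt_tot + 2 * cin
    } else if (ls$kind == "dense") {
      tr_tot <- tr_tot + cin * ls$units + ls$units
      cin <- ls$units
    }
  }
  pb <- count_params(arch)
  expect_equal(tr_tot, pb$trainable_total)
  expect_equal(nt_tot, pb$nontrainable_total)
})

test_that("a dense head alone counts 258 parameters on 128 features", {
  bl <- asNamespace("brainlite")
  arch <- structure(list(input_shape = c(1L, 1L, 128L),
                         layers = list(bl$layer_spec("dense", units = 2L),
                                       bl$layer_spec("softmax")),
                         num_classes = 2L),
                    class = "cnn_arch")
  expect_equal(count_params(arch)$total, 258L)
})

test_that("add junction rejects shape-incompatible operands", {
  bl <- asNamespace("brainlite")
  layers <- c(bl$convnet_cell(3L, 4L, 1L), bl$convnet_cell(3L, 8L, 1L),
              list(bl$layer_spec("add", from = 3L)))
  arch <- structure(list(input_shape = c(12L, 12L, 1L), layers = layers,
                         num_classes = 2L), class = "cnn_arch")
  expect_error(shape_trace(arch), "add operands differ")
})
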