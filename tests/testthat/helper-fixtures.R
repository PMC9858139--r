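# Shared fixtures: desk-scale phantom configuration and a miniature
# architecture that exercises every layer kind cheaply.

small_phantom_config <- function(...) {
  phantom_config(size = c(64, 64), brain_radius = c(22, 19),
                 skull_thickness = 2, tumor_radius = c(4, 7), ...)
}

mini_arch <- function(input = 12L, channels = 1L) {
  bl <- asNamespace("brainlite")
  layers <- c(bl$convnet_cell(3L, 4L, 1L), bl$convnet_cell(3L, 4L, 1L))
  skip <- length(layers)
  layers <- c(layers, bl$convnet_cell(1L, 4L, 1L),
              list(bl$layer_spec("add", from = skip)),
              list(bl$layer_spec("avgpool", kernel = 2L, stride = 2L),
                   bl$layer_spec("gap"),
                   bl$layer_spec("dense", units = 2L),
                   bl$layer_spec("softmax")))
  structure(list(input_shape = c(input, input, channels), layers = layers,
                 num_classes = 2L),
            class = "cnn_arch")
}
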