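#' Convolution output shape under valid padding
#'
#' `H' = floor((H - kernel)/stride) + 1` per spatial axis (no padding),
#' `C' = filters`.
#'
#' @param input Length-3 integer `(H, W, C)`.
#' @param kernel,stride Kernel size and stride.
#' @param filters Number of output channels.
#' @return Length-3 integer `(H', W', C')`.
#' @export
#' @examples
#' conv_out_shape(c(224, 224, 3), 5, 2, 32) # 110 110 32
conv_out_shape <- function(input, kernel, stride, filters) {
  if (kernel > min(input[1:2]))
    stop("conv_out_shape: kernel larger than spatial input ",
         paste(input[1:2], collapse = "x"))
  c((input[1] - kernel) %/% stride + 1L,
    (input[2] - kernel) %/% stride + 1L, as.integer(filters))
}

#' Parameter count of a convolution layer
#'
#' `kernel^2 * c_in * c_out + c_out` (one bias per filter).
#'
#' @param kernel Kernel size.
#' @param c_in,c_out Input and output channel counts.
#' @return Integer parameter count.
#' @export
#' @examples
#' conv_param_count(5, 3, 32) # 2432
conv_param_count <- function(kernel, c_in, c_out) {
  as.integer(kernel^2 * c_in * c_out + c_out)
}

#' Parameter count of a batch-normalization layer
#'
#' Two trainable vectors (scale, shift) and two non-trainable running
#' statistics (mean, variance), each of length `channels`.
#'
#' @param channels Channel count.
#' @return Named integer vector `c(trainable, nontrainable)`.
#' @export
#' @examples
#' sum(bn_param_count(32)) # 128
bn_param_count <- function(channels) {
  c(trainable = 2L * as.integer(channels),
    nontrainable = 2L * as.integer(channels))
}

layer_spec <- function(kind, kernel = NA_integer_, stride = NA_integer_,
                       filters = NA_integer_, units = NA_integer_,
                       from = NA_integer_) {
  list(kind = kind, kernel = kernel, stride = stride, filters = filters,
       units = units, from = from)
}

# One ConvNet cell: convolution -> batch norm -> softplus.
convnet_cell <- function(kernel, filters, stride) {
  list(layer_spec("conv", kernel = kernel, stride = stride, filters = filters),
       layer_spec("batchnorm"),
       layer_spec("softplus"))
}

#' Build the lightweight four-block CNN architecture
#'
#' The declarative layer list of the lightweight model: one 5x5/32
#' stride-2 ConvNet (convolution + batch norm + softplus), then three
#' blocks of three ConvNets (3x3, 3x3, 1x1 with 48, 64, 128 filters; the
#' first 3x3 of the 48-filter block has stride 2, all others stride 1),
#' each block closing with a point-to-point add of its last two ConvNet
#' outputs (the only shape-compatible pair) and a 2x2 stride-2 average
#' pooling, followed by global average pooling, a dense layer, and
#' softmax. All convolutions use valid padding.
#'
#' @param input_size Spatial input size (scalar or length-2); the
#'   default 224 reproduces the published shape table.
#' @param in_channels Input channels (grayscale slices are replicated to
#'   3 at the CNN boundary).
#' @param num_classes Output classes (default 2: normal/abnormal).
#' @param use_add Include the add junctions (default `TRUE`).
#' @return An object of class `cnn_arch`.
#' @export
#' @examples
#' arch <- build_lightweight_cnn()
#' count_params(arch)
build_lightweight_cnn <- function(input_size = 224L, in_channels = 3L,
                                  num_classes = 2L, use_add = TRUE) {
  if (length(input_size) == 1L) input_size <- rep(input_size, 2L)
  layers <- convnet_cell(5L, 32L, 2L)
  for (blk in list(list(f = 48L, s1 = 2L), list(f = 64L, s1 = 1L),
                   list(f = 128L, s1 = 1L))) {
    layers <- c(layers, convnet_cell(3L, blk$f, blk$s1))
    layers <- c(layers, convnet_cell(3L, blk$f, 1L))
    skip_idx <- length(layers)       # softplus after the 2nd ConvNet
    layers <- c(layers, convnet_cell(1L, blk$f, 1L))
    if (use_add)
      layers <- c(layers, list(layer_spec("add", from = skip_idx)))
    layers <- c(layers, list(layer_spec("avgpool", kernel = 2L, stride = 2L)))
  }
  layers <- c(layers, list(layer_spec("gap"),
                           layer_spec("dense", units = as.integer(num_classes)),
                           layer_spec("softmax")))
  structure(list(input_shape = c(as.integer(input_size),
                                 as.integer(in_channels)),
                 layers = layers, num_classes = as.integer(num_classes)),
            class = "cnn_arch")
}

#' Per-layer activation shapes of an architecture
#'
#' Walks the layer list and applies the valid-padding floor rule at
#' every convolution and pooling layer; add junctions check operand
#' shape equality.
#'
#' @param arch A [build_lightweight_cnn()] architecture.
#' @return A data frame with columns `layer`, `kind`, `H`, `W`, `C`
#'   (the input row included as layer 0).
#' @export
shape_trace <- function(arch) {
  shp <- arch$input_shape
  out <- list(data.frame(layer = 0L, kind = "input",
                         H = shp[1], W = shp[2], C = shp[3]))
  shapes <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    ls <- arch$layers[[i]]
    shp <- switch(ls$kind,
      conv = conv_out_shape(shp, ls$kernel, ls$stride, ls$filters),
      avgpool = c(conv_out_shape(shp, ls$kernel, ls$stride, 1L)[1:2], shp[3]),
      add = {
        ref <- shapes[[ls$from]]
        if (!identical(ref, shp))
          stop("shape_trace: add operands differ: ",
               paste(ref, collapse = "x"), " vs ", paste(shp, collapse = "x"))
        shp
      },
      gap = c(1L, 1L, shp[3]),
      dense = c(1L, 1L, ls$units),
      shp)  # batchnorm, softplus, softmax keep the shape
    shapes[[i]] <- shp
    out[[i + 1L]] <- data.frame(layer = i, kind = ls$kind,
                                H = shp[1], W = shp[2], C = shp[3])
  }
  do.call(rbind, out)
}

#' Exact parameter accounting of an architecture
#'
#' Sums convolution, batch-normalization, and dense parameters from the
#' shape trace; pooling, activation, add, and softmax layers contribute
#' none. Batch-norm running statistics are the non-trainable part.
#'
#' @param arch A [build_lightweight_cnn()] architecture.
#' @return An object of class `param_breakdown`: data frame `layers`
#'   plus `trainable_total`, `nontrainable_total`, `total`.
#' @export
#' @examples
#' count_params(build_lightweight_cnn())$total # 349458
count_params <- function(arch) {
  tr <- shape_trace(arch)
  rows <- list()
  c_in <- arch$input_shape[3]
  trainable <- 0L; nontrainable <- 0L
  for (i in seq_along(arch$layers)) {
    ls <- arch$layers[[i]]
    shp <- unlist(tr[tr$layer == i, c("H", "W", "C")], use.names = FALSE)
    p_tr <- 0L; p_nt <- 0L
    if (ls$kind == "conv") {
      p_tr <- conv_param_count(ls$kernel, c_in, ls$filters)
    } else if (ls$kind == "batchnorm") {
      bn <- bn_param_count(shp[3])
      p_tr <- bn[["trainable"]]; p_nt <- bn[["nontrainable"]]
    } else if (ls$kind == "dense") {
      p_tr <- as.integer(c_in * ls$units + ls$units)
    }
    trainable <- trainable + p_tr
    nontrainable <- nontrainable + p_nt
    rows[[i]] <- data.frame(layer = i, kind = ls$kind,
                            trainable = p_tr, nontrainable = p_nt)
    c_in <- shp[3]
  }
  structure(list(layers = do.call(rbind, rows),
                 trainable_total = trainable,
                 nontrainable_total = nontrainable,
                 total = trainable + nontrainable),
            class = "param_breakdown")
}

#' @export
print.param_breakdown <- function(x, ...) {
  nz <- x$layers[x$layers$trainable + x$layers$nontrainable > 0, ]
  print(nz, row.names = FALSE)
  cat(sprintf("Trainable: %d   Non-trainable: %d   Total: %d\n",
              x$trainable_total, x$nontrainable_total, x$total))
  invisible(x)
}

#' @export
print.cnn_arch <- function(x, ...) {
  tr <- shape_trace(x)
  cat(sprintf("cnn_arch: input %s, %d layers, %d classes\n",
              paste(x$input_shape, collapse = "x"), length(x$layers),
              x$num_classes))
  print(tr, row.names = FALSE)
  invisible(x)
}
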