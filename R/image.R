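#' 2-D grayscale image with a declared intensity range
#'
#' The universal pixel carrier of the package: a numeric matrix of finite
#' intensities together with the interval they are declared to live on
#' (typically `[0, 255]` for 8-bit input or `[0, 1]` after
#' [normalize_image()]). Row `i`, column `j` addresses pixel `(i, j)`
#' throughout the package.
#'
#' @param pixels Numeric matrix (height x width) of finite values.
#' @param range Length-2 numeric, the declared intensity interval; every
#'   pixel must lie inside it.
#' @param name Optional provenance string (e.g. the source file).
#' @return An object of class `image2d` with fields `pixels`, `range`,
#'   `name`.
#' @seealso [binary_mask()], [load_image()], [normalize_image()]
#' @export
#' @examples
#' img <- image2d(matrix(0:3, 2, 2), range = c(0, 255))
#' dim(img)
image2d <- function(pixels, range = c(0, 255), name = "") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image2d: empty image")
  if (!all(is.finite(pixels)))
    stop("image2d: non-finite pixel values")
  range <- as.numeric(range)
  if (length(range) != 2L || range[1] >= range[2])
    stop("image2d: 'range' must be an increasing length-2 interval")
  if (min(pixels) < range[1] - 1e-9 || max(pixels) > range[2] + 1e-9)
    stop("image2d: pixel values outside the declared range")
  structure(list(pixels = pixels, range = range, name = as.character(name)[1]),
            class = "image2d")
}

#' @export
dim.image2d <- function(x) dim(x$pixels)

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("image2d %dx%d, range [%g, %g]%s\n",
              nrow(x$pixels), ncol(x$pixels), x$range[1], x$range[2],
              if (nzchar(x$name)) paste0(", '", x$name, "'") else ""))
  invisible(x)
}

#' @export
as.matrix.image2d <- function(x, ...) x$pixels

as_image2d <- function(x, range = c(0, 255), name = "") {
  if (inherits(x, "image2d")) x else image2d(x, range = range, name = name)
}

#' Binary mask over a pixel lattice
#'
#' A height x width matrix whose entries are exactly 0 or 1; used for
#' skull/brain/tumor regions, firing maps, and ground truth.
#'
#' @param pixels Numeric or logical matrix; logicals are converted.
#' @param name Optional provenance string.
#' @return An object of class `binary_mask` with fields `pixels`, `name`.
#' @export
#' @examples
#' m <- binary_mask(matrix(c(0, 1, 1, 0), 2, 2))
#' sum(m$pixels)
binary_mask <- function(pixels, name = "") {
  pixels <- as.matrix(pixels)
  if (is.logical(pixels)) pixels <- pixels + 0
  storage.mode(pixels) <- "double"
  if (!all(pixels %in% c(0, 1)))
    stop("binary_mask: values must be exactly 0 or 1")
  structure(list(pixels = pixels, name = as.character(name)[1]),
            class = "binary_mask")
}

#' @export
dim.binary_mask <- function(x) dim(x$pixels)

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask %dx%d, %d foreground px%s\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              if (nzchar(x$name)) paste0(", '", x$name, "'") else ""))
  invisible(x)
}

#' @export
as.matrix.binary_mask <- function(x, ...) x$pixels

as_binary_mask <- function(x, name = "") {
  if (inherits(x, "binary_mask")) x else binary_mask(x, name = name)
}

#' Labeled image collection
#'
#' Parallel collections of images, two-class labels (`normal` /
#' `abnormal`), and optional ground-truth masks.
#'
#' @param images List of [image2d()] objects.
#' @param labels Character or factor vector over `{"normal","abnormal"}`,
#'   one per image.
#' @param masks Optional list of [binary_mask()] ground-truth masks (or
#'   `NULL` entries), parallel to `images`.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(images, labels, masks = NULL) {
  stopifnot(is.list(images), length(images) >= 1L)
  images <- lapply(images, as_image2d)
  labels <- factor(as.character(labels), levels = c("normal", "abnormal"))
  if (anyNA(labels))
    stop("labeled_dataset: labels must be 'normal' or 'abnormal'")
  if (length(labels) != length(images))
    stop("labeled_dataset: images and labels differ in length")
  if (!is.null(masks) && length(masks) != length(images))
    stop("labeled_dataset: images and masks differ in length")
  structure(list(images = images, labels = labels, masks = masks),
            class = "labeled_dataset")
}

#' @export
length.labeled_dataset <- function(x) length(x$images)

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d images (%d normal, %d abnormal)%s\n",
              length(x$images), sum(x$labels == "normal"),
              sum(x$labels == "abnormal"),
              if (!is.null(x$masks)) ", with masks" else ""))
  invisible(x)
}

#' Load a grayscale image from disk
#'
#' Reads PNG, JPEG, TIFF, or single-slice NIfTI. Multi-channel input is
#' reduced to grayscale by the unweighted channel mean. PNG/JPEG are
#' declared on `[0, 255]`; TIFF keeps its stored integer values with the
#' range declared from the bit depth; NIfTI keeps raw values.
#'
#' @param path Path to the image file.
#' @return An [image2d()].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("load_image: cannot read '", path, "'")
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (grepl("\\.nii(\\.gz)?$", tolower(path))) {
    vol <- RNifti::readNifti(path)
    d <- dim(vol)
    if (length(d) > 2 && any(d[-(1:2)] > 1))
      stop("load_image: volumetric NIfTI with >1 slice is unsupported: '",
           path, "'")
    px <- matrix(as.numeric(vol), d[1], d[2])
    hi <- max(255, ceiling(max(px)))
    return(image2d(px, range = c(min(0, floor(min(px))), hi), name = path))
  }
  px <- switch(ext,
    png = png::readPNG(path) * 255,
    jpg = ,
    jpeg = jpeg::readJPEG(path) * 255,
    tif = ,
    tiff = {
      info <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
      bits <- attr(info, "bits.per.sample")
      if (is.null(bits)) bits <- 8L
      attr(info, "range") <- c(0, 2^bits - 1)
      info
    },
    stop("load_image: unsupported format '", ext, "' for '", path, "'"))
  rng <- attr(px, "range")
  if (is.null(rng)) rng <- c(0, 255)
  px <- unclass(px)
  if (length(dim(px)) == 3L) px <- apply(px, c(1, 2), mean)
  image2d(as.matrix(px), range = rng, name = path)
}

#' Save an image or mask as PNG
#'
#' `save_image()` writes an 8-bit grayscale PNG (values scaled by the
#' declared range); `save_mask()` writes a binary mask with the
#' `{0,1} <-> {0,255}` convention; `load_mask()` reads it back.
#' Round-trips are lossless for 8-bit images and for masks.
#'
#' @param img An [image2d()].
#' @param mask A [binary_mask()].
#' @param path Output path (`.png`).
#' @return Invisibly, the path.
#' @export
save_image <- function(img, path) {
  img <- as_image2d(img)
  v <- (img$pixels - img$range[1]) / diff(img$range)
  ok <- tryCatch({png::writePNG(v, target = path); TRUE},
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path))
    stop("save_image: cannot write '", path, "'")
  invisible(path)
}

#' @rdname save_image
#' @export
save_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  ok <- tryCatch({png::writePNG(mask$pixels, target = path); TRUE},
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path))
    stop("save_mask: cannot write '", path, "'")
  invisible(path)
}

#' @rdname save_image
#' @export
load_mask <- function(path) {
  img <- load_image(path)
  binary_mask((img$pixels / diff(img$range)) > 0.5, name = path)
}

#' Rescale intensities onto a target interval
#'
#' Affine map of the observed `[min, max]` onto `target`; a constant
#' image maps to the target lower bound. Idempotent on already-normalized
#' input.
#'
#' @param img An [image2d()] (or plain matrix).
#' @param target Length-2 target interval, default `c(0, 1)`.
#' @return An [image2d()] with `range = target`.
#' @export
normalize_image <- function(img, target = c(0, 1)) {
  img <- as_image2d(img, range = range(img))
  px <- img$pixels
  lo <- min(px); hi <- max(px)
  out <- if (hi > lo) {
    target[1] + (px - lo) / (hi - lo) * (target[2] - target[1])
  } else {
    matrix(target[1], nrow(px), ncol(px))
  }
  # guard rounding at the endpoints
  out <- pmin(pmax(out, target[1]), target[2])
  image2d(out, range = target, name = img$name)
}

# Center-aligned bilinear sampling at fractional (row, col) positions.
# Coordinates are 1-based; `fill` is returned outside the frame, or set
# fill = NA to clamp to the border instead (used by resize).
bilinear_sample <- function(px, ri, ci, fill = 0) {
  H <- nrow(px); W <- ncol(px)
  clamp <- is.na(fill)
  if (clamp) {
    ri <- pmin(pmax(ri, 1), H)
    ci <- pmin(pmax(ci, 1), W)
  }
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  r0 <- pmin(pmax(r0, 1), H); c0 <- pmin(pmax(c0, 1), W)
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  v <- px[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    px[cbind(r1, c0)] * fr * (1 - fc) +
    px[cbind(r0, c1)] * (1 - fr) * fc +
    px[cbind(r1, c1)] * fr * fc
  if (!clamp) {
    outside <- ri < 0.5 | ri > H + 0.5 | ci < 0.5 | ci > W + 0.5
    v[outside] <- fill
  }
  v
}

#' Bilinear resize
#'
#' Resamples to `h x w` with center-aligned (half-pixel) bilinear
#' interpolation; the declared range is preserved and resizing to the
#' input shape is the identity.
#'
#' @param img An [image2d()].
#' @param h,w Target height and width (positive integers).
#' @return An [image2d()] of size `h x w`.
#' @export
resize_image <- function(img, h, w) {
  img <- as_image2d(img, range = range(img))
  if (h < 1 || w < 1) stop("resize_image: target size must be positive")
  px <- img$pixels
  H <- nrow(px); W <- ncol(px)
  if (h == H && w == W) return(img)
  # center alignment: source row of output row i is (i - 0.5) * H/h + 0.5
  ri <- (seq_len(h) - 0.5) * (H / h) + 0.5
  ci <- (seq_len(w) - 0.5) * (W / w) + 0.5
  grid <- expand.grid(r = ri, c = ci)
  out <- matrix(bilinear_sample(px, grid$r, grid$c, fill = NA), h, w)
  out <- pmin(pmax(out, img$range[1]), img$range[2])
  image2d(out, range = img$range, name = img$name)
}
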