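#' Configuration for seeded geometric augmentation
#'
#' Intervals follow the study defaults: rotation uniformly in
#' `[-30, 30]` degrees, translation in `[-10, 10]` px per axis,
#' reflection along each axis with probability 0.5, uniform scaling in
#' `[0.5, 4]`, shearing in `[0, 30]` degrees per axis, and 9 outputs per
#' original (counting the original), which expands 60/125 originals to
#' 540/1125.
#'
#' @param rotation Rotation interval in degrees.
#' @param translate Translation interval in pixels (per axis).
#' @param reflect_prob Per-axis reflection probability.
#' @param scale Uniform scale interval.
#' @param shear Shear interval in degrees (per axis).
#' @param per_image Outputs per original image, including the original.
#' @param single_op Draw exactly one operator per output instead of a
#'   jointly drawn composition.
#' @param seed Integer seed for reproducibility (`NULL` = current RNG).
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(rotation = c(-30, 30), translate = c(-10, 10),
                           reflect_prob = 0.5, scale = c(0.5, 4),
                           shear = c(0, 30), per_image = 9L,
                           single_op = FALSE, seed = NULL) {
  if (per_image < 1) stop("augment_config: per_image must be >= 1")
  structure(list(rotation = rotation, translate = translate,
                 reflect_prob = reflect_prob, scale = scale, shear = shear,
                 per_image = as.integer(per_image), single_op = single_op,
                 seed = seed),
            class = "augment_config")
}

#' Draw a random affine transform
#'
#' Parameters are drawn uniformly from the configured intervals and
#' composed in the fixed order reflect -> rotate -> shear -> scale ->
#' translate, all about the image center. Consumes the current RNG
#' stream, so a fixed seed gives identical transforms.
#'
#' @param cfg An [augment_config()].
#' @return An object of class `affine2d`: a 2 x 2 linear part `M`
#'   (row/column coordinates), translation `t` (rows, cols), and the
#'   drawn parameters.
#' @export
random_affine <- function(cfg = augment_config()) {
  draw <- function(iv) runif(1, iv[1], iv[2])
  pars <- list(
    reflect_r = runif(1) < cfg$reflect_prob,  # flip vertically (rows)
    reflect_c = runif(1) < cfg$reflect_prob,  # flip horizontally (cols)
    rotation = draw(cfg$rotation),
    shear_x = draw(cfg$shear), shear_y = draw(cfg$shear),
    scale = draw(cfg$scale),
    translate = c(draw(cfg$translate), draw(cfg$translate)))
  if (cfg$single_op) {
    keep <- sample(c("reflect", "rotation", "shear", "scale", "translate"), 1)
    if (keep != "reflect") pars$reflect_r <- pars$reflect_c <- FALSE
    if (keep != "rotation") pars$rotation <- 0
    if (keep != "shear") pars$shear_x <- pars$shear_y <- 0
    if (keep != "scale") pars$scale <- 1
    if (keep != "translate") pars$translate <- c(0, 0)
  }
  affine2d(pars)
}

# Build the affine2d object from a parameter list. Coordinates are
# (row, col); the linear part acts about the image center.
affine2d <- function(pars) {
  refl <- diag(c(if (pars$reflect_r) -1 else 1,
                 if (pars$reflect_c) -1 else 1))
  th <- pars$rotation * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shx <- tan(pars$shear_x * pi / 180)  # shear columns along rows
  shy <- tan(pars$shear_y * pi / 180)
  shear <- matrix(c(1, shy, shx, 1), 2, 2)
  M <- (pars$scale * diag(2)) %*% shear %*% rot %*% refl
  structure(list(M = M, t = pars$translate, pars = pars), class = "affine2d")
}

identity_affine <- function() {
  affine2d(list(reflect_r = FALSE, reflect_c = FALSE, rotation = 0,
                shear_x = 0, shear_y = 0, scale = 1, translate = c(0, 0)))
}

#' @export
print.affine2d <- function(x, ...) {
  p <- x$pars
  cat(sprintf(paste0("affine2d: rot=%.1f deg, shear=(%.1f, %.1f) deg, ",
                     "scale=%.2f, translate=(%.1f, %.1f), reflect=(%s, %s)\n"),
              p$rotation, p$shear_x, p$shear_y, p$scale,
              p$translate[1], p$translate[2], p$reflect_r, p$reflect_c))
  invisible(x)
}

#' Apply an affine transform to an image
#'
#' Bilinear warp about the image center with inverse mapping; the output
#' has the input shape and out-of-frame samples are filled with 0
#' (background).
#'
#' @param img An [image2d()].
#' @param tf An `affine2d` from [random_affine()].
#' @return An [image2d()] of the same shape and range.
#' @export
apply_affine <- function(img, tf) {
  img <- as_image2d(img, range = range(img))
  px <- img$pixels
  H <- nrow(px); W <- ncol(px)
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  Minv <- solve(tf$M)
  grid <- expand.grid(r = seq_len(H), c = seq_len(W))
  q <- cbind(grid$r - ctr[1] - tf$t[1], grid$c - ctr[2] - tf$t[2])
  src <- q %*% t(Minv)
  ri <- src[, 1] + ctr[1]
  ci <- src[, 2] + ctr[2]
  out <- matrix(bilinear_sample(px, ri, ci, fill = 0), H, W)
  out <- pmin(pmax(out, img$range[1]), img$range[2])
  image2d(out, range = img$range, name = img$name)
}

#' Expand a dataset by seeded geometric augmentation
#'
#' Each image contributes `per_image` outputs: the original plus
#' `per_image - 1` random transforms. Labels are copied; ground-truth
#' masks are not propagated to transformed copies (augmented images are
#' intended for the classification stage).
#'
#' @param ds A [labeled_dataset()].
#' @param cfg An [augment_config()].
#' @return A [labeled_dataset()] of size `per_image * length(ds)`.
#' @export
#' @examples
#' ds <- make_phantom_dataset(2, 3, phantom_config(size = c(64, 64), seed = 1))
#' length(augment_dataset(ds, augment_config(per_image = 9, seed = 1)))
augment_dataset <- function(ds, cfg = augment_config()) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (!is.null(cfg$seed)) {
    old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(cfg$seed)
  }
  images <- vector("list", length(ds) * cfg$per_image)
  labels <- character(length(images))
  k <- 0L
  for (i in seq_along(ds$images)) {
    for (j in seq_len(cfg$per_image)) {
      k <- k + 1L
      images[[k]] <- if (j == 1L) ds$images[[i]] else
        apply_affine(ds$images[[i]], random_affine(cfg))
      labels[k] <- as.character(ds$labels[i])
    }
  }
  labeled_dataset(images, labels)
}
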