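#' Separability threshold for skull-stripping
#'
#' Splits the intensity histogram at the Otsu point `t` into regions
#' `R1 = {x < t}` and `R2 = {x >= t}` and derives the optimal binarization
#' threshold from the region statistics:
#' \deqn{H = (m_1 - m_2)^2 / (s_1^2 + s_2^2),\quad
#'       T = (H + \min(I)) / 2,\quad
#'       T_{opt} = T / 255}
#' with population variances and a small variance guard `eps` in the
#' denominator. `Topt` is clamped to `[0, 1]`.
#'
#' @param img An [image2d()] on the `[0, 255]` scale with at least two
#'   distinct intensities.
#' @param eps Variance guard added to `s1^2 + s2^2` (default `1e-6`).
#' @return An object of class `threshold_report`: `t_split`, `m1`, `m2`,
#'   `s1sq`, `s2sq`, `H`, `T`, `Topt`.
#' @export
#' @examples
#' img <- image2d(matrix(c(10, 20, 200, 220), 2, 2))
#' separability_threshold(img)
separability_threshold <- function(img, eps = 1e-6) {
  img <- as_image2d(img)
  px <- img$pixels
  if (max(px) == min(px))
    stop("separability_threshold: constant image, no split exists")
  t_split <- otsu_threshold(px, levels = 256L, range = c(0, 255))
  r1 <- px[px < t_split]
  r2 <- px[px >= t_split]
  if (length(r1) == 0L || length(r2) == 0L)
    stop("separability_threshold: degenerate split")
  popvar <- function(x) mean((x - mean(x))^2)
  m1 <- mean(r1); m2 <- mean(r2)
  s1sq <- popvar(r1); s2sq <- popvar(r2)
  H <- (m1 - m2)^2 / (s1sq + s2sq + eps)
  Tval <- (H + min(px)) / 2
  structure(list(t_split = t_split, m1 = m1, m2 = m2,
                 s1sq = s1sq, s2sq = s2sq, H = H, T = Tval,
                 Topt = min(max(Tval / 255, 0), 1)),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf(paste0("separability threshold: t_split=%.4g m1=%.4g m2=%.4g ",
                     "s1sq=%.4g s2sq=%.4g H=%.4g T=%.4g Topt=%.4g\n"),
              x$t_split, x$m1, x$m2, x$s1sq, x$s2sq, x$H, x$T, x$Topt))
  invisible(x)
}

#' Binarize an image at a normalized threshold
#'
#' Mask is 1 where `pixel / 255 > topt`.
#'
#' @param img An [image2d()] on the `[0, 255]` scale.
#' @param topt Normalized threshold in `[0, 1]`.
#' @return A [binary_mask()].
#' @export
binarize_image <- function(img, topt) {
  img <- as_image2d(img)
  if (topt < 0 || topt > 1) stop("binarize_image: topt must lie in [0, 1]")
  binary_mask((img$pixels / 255) > topt, name = img$name)
}

#' Morphological refinement of a head mask
#'
#' Applies, in order: area opening (8-connectivity components smaller
#' than `min_area` are removed), hole filling, erosion by a disk of
#' radius `se_radius`, and retention of the largest remaining component.
#' The result is always a subset of the hole-filled input.
#'
#' @param mask A [binary_mask()].
#' @param se_radius Disk structuring-element radius in pixels.
#' @param min_area Minimum connected-component area kept by the opening.
#' @return A [binary_mask()].
#' @export
refine_brain_mask <- function(mask, se_radius = 5, min_area = 300) {
  mask <- as_binary_mask(mask)
  if (se_radius < 1) stop("refine_brain_mask: se_radius must be >= 1")
  m <- mask$pixels
  # area opening
  lab <- cc_label8(matrix(as.integer(m), nrow(m)))
  if (max(lab) > 0L) {
    sizes <- tabulate(lab)
    keep <- which(sizes >= min_area)
    m <- matrix(as.numeric(lab %in% keep & lab > 0L), nrow(m))
  }
  # hole filling
  m <- as.numeric(EBImage::fillHull(EBImage::Image(m)))
  dim(m) <- dim(mask$pixels)
  # erosion by a disk
  brush <- EBImage::makeBrush(2L * as.integer(se_radius) + 1L, shape = "disc")
  m <- as.numeric(EBImage::erode(EBImage::Image(m), brush))
  dim(m) <- dim(mask$pixels)
  # keep the largest component
  lab <- cc_label8(matrix(as.integer(m), nrow(m)))
  if (max(lab) == 0L)
    stop("refine_brain_mask: refinement emptied the mask (failed stripping)")
  sizes <- tabulate(lab)
  m <- matrix(as.numeric(lab == which.max(sizes)), nrow(m))
  binary_mask(m, name = mask$name)
}

#' Skull-strip a brain MR slice
#'
#' Removes non-brain matter by thresholding at the separability
#' threshold ([separability_threshold()]), binarizing, refining the mask
#' morphologically ([refine_brain_mask()]), and zeroing the image outside
#' the brain mask.
#'
#' `se_radius` and `min_area` default to 5 px and 300 px for 256 x 256
#' input and are scaled with image area when left `NULL`.
#'
#' @param img An [image2d()] on the `[0, 255]` scale.
#' @param se_radius Disk radius for the erosion step (`NULL` = auto).
#' @param min_area Area-opening threshold in pixels (`NULL` = auto).
#' @param eps Variance guard, see [separability_threshold()].
#' @return An object of class `skull_strip`: `stripped` ([image2d()]),
#'   `brain_mask` ([binary_mask()]), `report` (`threshold_report`).
#' @export
#' @examples
#' ph <- make_phantom(phantom_config(noise_sigma = 0, seed = 1))
#' ss <- skull_strip(ph$image)
#' ss
skull_strip <- function(img, se_radius = NULL, min_area = NULL, eps = 1e-6) {
  img <- as_image2d(img)
  scale <- prod(dim(img$pixels)) / (256 * 256)
  if (is.null(se_radius)) se_radius <- max(1L, round(5 * sqrt(scale)))
  if (is.null(min_area)) min_area <- max(0L, round(300 * scale))
  report <- separability_threshold(img, eps = eps)
  raw <- binarize_image(img, report$Topt)
  brain <- refine_brain_mask(raw, se_radius = se_radius, min_area = min_area)
  stripped <- image2d(img$pixels * brain$pixels, range = img$range,
                      name = img$name)
  structure(list(stripped = stripped, brain_mask = brain, report = report,
                 se_radius = se_radius, min_area = min_area),
            class = "skull_strip")
}

#' @export
print.skull_strip <- function(x, ...) {
  cat(sprintf("skull_strip: %dx%d image, brain mask %d px (%.1f%%), Topt=%.4g\n",
              nrow(x$stripped$pixels), ncol(x$stripped$pixels),
              sum(x$brain_mask$pixels),
              100 * mean(x$brain_mask$pixels), x$report$Topt))
  invisible(x)
}

#' @export
plot.skull_strip <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  show_gray(x$stripped$pixels / max(1, max(x$stripped$pixels)), "stripped")
  show_gray(x$brain_mask$pixels, "brain mask")
  invisible(x)
}

show_gray <- function(m, main = "") {
  image(t(m[nrow(m):1, , drop = FALSE]), col = gray(seq(0, 1, length.out = 256)),
        axes = FALSE, asp = nrow(m) / ncol(m))
  title(main)
}
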