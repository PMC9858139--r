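#' Configuration for the synthetic T2-like brain phantom
#'
#' The phantom emulates an axial T2-weighted head slice at desk scale:
#' dark background, an elliptical brain disc of mid intensity, a thin
#' bright skull/scalp ring around it, and (for abnormal samples) a
#' hyperintense elliptical tumor strictly interior to the brain —
#' tumors are bright on T2. Ground-truth skull/brain/tumor masks are
#' exact by construction; additive Gaussian noise (clipped to range) is
#' applied after painting.
#'
#' @param size Image size `(H, W)`, default 256 x 256.
#' @param background_intensity,brain_intensity,tumor_intensity,skull_intensity
#'   Intensities on the `[0, 255]` scale (defaults 0, 110, 200, 230; the
#'   tumor must be brighter than brain tissue).
#' @param brain_radius Semi-axes of the brain ellipse in pixels.
#' @param skull_thickness Ring thickness in pixels.
#' @param tumor_radius Interval the tumor semi-axes are drawn from.
#' @param tumor_present Paint a tumor (abnormal) or not (normal)?
#' @param noise_sigma Gaussian noise SD on the `[0, 255]` scale
#'   (default 3).
#' @param jitter Relative geometry jitter (default 0.1: radii vary
#'   uniformly by +/-10%).
#' @param seed Integer seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(size = c(256L, 256L), background_intensity = 0,
                           brain_intensity = 110, tumor_intensity = 200,
                           skull_intensity = 230, brain_radius = c(90, 78),
                           skull_thickness = 4, tumor_radius = c(12, 26),
                           tumor_present = TRUE, noise_sigma = 3,
                           jitter = 0.1, seed = NULL) {
  if (length(size) == 1L) size <- rep(size, 2L)
  if (tumor_intensity <= brain_intensity)
    stop("phantom_config: tumor must be hyperintense relative to brain")
  if (max(brain_radius) + skull_thickness >= min(size) / 2)
    stop("phantom_config: head does not fit in the frame")
  structure(list(size = as.integer(size),
                 background_intensity = background_intensity,
                 brain_intensity = brain_intensity,
                 tumor_intensity = tumor_intensity,
                 skull_intensity = skull_intensity,
                 brain_radius = brain_radius,
                 skull_thickness = skull_thickness,
                 tumor_radius = tumor_radius,
                 tumor_present = tumor_present,
                 noise_sigma = noise_sigma, jitter = jitter, seed = seed),
            class = "phantom_config")
}

ellipse_mask <- function(H, W, center, radii) {
  r <- matrix(seq_len(H), H, W)
  c <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((r - center[1]) / radii[1])^2 + ((c - center[2]) / radii[2])^2 <= 1
}

#' Generate one synthetic brain phantom
#'
#' Paints background, brain disc, skull ring, and (optionally) a tumor
#' blob with jittered geometry, then adds clipped Gaussian noise. The
#' returned masks are the exact painted regions (pre-noise); the tumor
#' mask is empty iff the label is `normal`, and the brain mask contains
#' the tumor.
#'
#' @param cfg A [phantom_config()].
#' @return An object of class `phantom_sample`: `image` ([image2d()]),
#'   `skull_mask`, `brain_mask`, `tumor_mask` ([binary_mask()]), and
#'   `label` (`"normal"` or `"abnormal"`).
#' @export
#' @examples
#' ph <- make_phantom(phantom_config(noise_sigma = 0, seed = 7))
#' ph
make_phantom <- function(cfg = phantom_config()) {
  if (!is.null(cfg$seed)) {
    old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(cfg$seed)
  }
  H <- cfg$size[1]; W <- cfg$size[2]
  jit <- function(x) x * runif(length(x), 1 - cfg$jitter, 1 + cfg$jitter)
  br <- jit(cfg$brain_radius)
  center <- c((H + 1) / 2, (W + 1) / 2)
  brain <- ellipse_mask(H, W, center, br)
  head <- ellipse_mask(H, W, center, br + cfg$skull_thickness)
  skull <- head & !brain
  tumor <- matrix(FALSE, H, W)
  if (cfg$tumor_present) {
    # draw until the tumor ellipse sits strictly inside the brain disc
    for (try in 1:100) {
      tr <- sort(runif(2, cfg$tumor_radius[1], cfg$tumor_radius[2]),
                 decreasing = TRUE)
      # admissible center: tumor bounding box within shrunken brain disc
      off <- c(runif(1, -1, 1) * (br[1] - tr[1] - 2),
               runif(1, -1, 1) * (br[2] - tr[1] - 2))
      tc <- center + off * 0.7
      cand <- ellipse_mask(H, W, tc, tr)
      inside <- ellipse_mask(H, W, center, br - 2)
      if (all(inside[cand])) { tumor <- cand; break }
    }
    if (!any(tumor))
      stop("make_phantom: could not place a tumor inside the brain")
  }
  px <- matrix(cfg$background_intensity, H, W)
  px[brain] <- cfg$brain_intensity
  px[tumor] <- cfg$tumor_intensity
  px[skull] <- cfg$skull_intensity
  if (cfg$noise_sigma > 0) {
    px <- px + matrix(rnorm(H * W, sd = cfg$noise_sigma), H, W)
    px <- pmin(pmax(px, 0), 255)
  }
  structure(list(image = image2d(px, range = c(0, 255), name = "phantom"),
                 skull_mask = binary_mask(skull, name = "skull"),
                 brain_mask = binary_mask(brain, name = "brain"),
                 tumor_mask = binary_mask(tumor, name = "tumor"),
                 label = if (cfg$tumor_present) "abnormal" else "normal",
                 config = cfg),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("phantom_sample: %dx%d, label %s, tumor %d px\n",
              nrow(x$image$pixels), ncol(x$image$pixels), x$label,
              sum(x$tumor_mask$pixels)))
  invisible(x)
}

#' @export
plot.phantom_sample <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  show_gray(x$image$pixels / 255, paste("phantom:", x$label))
  show_gray(x$tumor_mask$pixels, "tumor ground truth")
  invisible(x)
}

#' Generate a labeled phantom dataset
#'
#' `n_normal + n_abnormal` phantoms with per-sample jittered geometry
#' and derived seeds, mirroring the 60-normal / 125-abnormal class
#' structure of the emulated collection. Ground-truth tumor masks are
#' attached for every sample (empty for normals).
#'
#' @param n_normal,n_abnormal Number of samples per class.
#' @param cfg A [phantom_config()] serving as the template; its `seed`
#'   is the master seed.
#' @return A [labeled_dataset()] with `masks`.
#' @export
#' @examples
#' ds <- make_phantom_dataset(3, 5, phantom_config(size = c(64, 64),
#'                            brain_radius = c(22, 19), tumor_radius = c(4, 7),
#'                            seed = 1))
#' ds
make_phantom_dataset <- function(n_normal, n_abnormal,
                                 cfg = phantom_config()) {
  n <- n_normal + n_abnormal
  if (n < 1L) stop("make_phantom_dataset: empty dataset requested")
  base_seed <- if (is.null(cfg$seed)) sample.int(1e6, 1) else cfg$seed
  images <- vector("list", n)
  masks <- vector("list", n)
  labels <- rep(c("normal", "abnormal"), c(n_normal, n_abnormal))
  for (i in seq_len(n)) {
    ci <- cfg
    ci$tumor_present <- labels[i] == "abnormal"
    ci$seed <- base_seed + i
    ph <- make_phantom(ci)
    images[[i]] <- ph$image
    masks[[i]] <- ph$tumor_mask
  }
  labeled_dataset(images, labels, masks)
}
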