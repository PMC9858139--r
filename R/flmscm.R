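#' Otsu threshold over a fixed-bin histogram
#'
#' Standard between-class-variance-maximizing threshold computed over
#' `levels` equal-width histogram bins spanning `range`; ties are broken
#' toward the lower threshold. The returned value is the lower edge of
#' the first bin assigned to the upper class, so `x < t` / `x >= t`
#' reproduces the class split (exact for integer data on `[0, 255]` with
#' 256 levels).
#'
#' @param x Numeric matrix or vector of intensities.
#' @param levels Number of histogram bins (default 256).
#' @param range Length-2 interval the histogram spans; defaults to the
#'   data range.
#' @return The threshold value on the scale of `x`.
#' @export
#' @examples
#' otsu_threshold(c(rep(0.2, 50), rep(0.8, 50)), range = c(0, 1))
otsu_threshold <- function(x, levels = 256L, range = NULL) {
  x <- as.numeric(if (inherits(x, "image2d")) x$pixels else x)
  if (max(x) == min(x))
    stop("otsu_threshold: constant input, threshold undefined")
  if (is.null(range)) range <- c(min(x), max(x))
  w <- diff(range) / levels
  bin <- pmin(pmax(floor((x - range[1]) / w), 0), levels - 1)
  counts <- tabulate(bin + 1L, nbins = levels)
  p <- counts / sum(counts)
  omega <- cumsum(p)                      # P(class 1) for split after bin k
  mu <- cumsum(p * (seq_len(levels) - 1)) # unnormalized class-1 mean
  mu_t <- mu[levels]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)                 # ties -> lowest index
  range[1] + k * w                        # lower edge of bin k+1
}

#' Gaussian linking-weight kernel
#'
#' The position-invariant linking weights of the spiking cortical model:
#' a sampled 2-D Gaussian (default 7 x 7, sd 1), normalized to sum 1,
#' with the central self-term retained.
#'
#' @param size Odd kernel size (default 7).
#' @param sigma Gaussian standard deviation in pixels (default 1).
#' @return A `size x size` matrix summing to 1.
#' @export
gaussian_linking_weights <- function(size = 7L, sigma = 1) {
  if (size %% 2L == 0L) stop("gaussian_linking_weights: size must be odd")
  r <- (size - 1L) / 2L
  d <- seq(-r, r)
  g <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  g / sum(g)
}

#' Linking strength from the local gradient
#'
#' Per-pixel coupling coefficient `beta = 1 / (1 + exp(-G))` where `G`
#' is the central-difference gradient magnitude of the (normalized)
#' input, with replicated edges. Constant regions get `beta = 0.5`;
#' edges approach 1.
#'
#' @param S An [image2d()] or matrix on the `[0, 1]` scale.
#' @return Matrix of linking strengths in `(0, 1)`.
#' @export
linking_strength <- function(S) {
  S <- if (inherits(S, "image2d")) S$pixels else as.matrix(S)
  H <- nrow(S); W <- ncol(S)
  up <- S[c(1, seq_len(H - 1)), , drop = FALSE]
  dn <- S[c(seq_len(H - 1) + 1, H), , drop = FALSE]
  lf <- S[, c(1, seq_len(W - 1)), drop = FALSE]
  rt <- S[, c(seq_len(W - 1) + 1, W), drop = FALSE]
  gx <- (rt - lf) / 2
  gy <- (dn - up) / 2
  G <- sqrt(gx^2 + gy^2)
  1 / (1 + exp(-G))
}

#' Threshold magnitude ensuring single firing
#'
#' Per-pixel threshold boost applied when a neuron fires:
#' \deqn{h = \frac{\max(S) - \min(S)}{1 - f} + \max(S)\,(1 + \beta \sum W)}
#' so that a fired neuron's threshold exceeds any attainable internal
#' activity and no neuron fires twice within the run.
#'
#' @param S Input image (matrix or [image2d()]) on `[0, 1]`.
#' @param beta Per-pixel linking strengths (see [linking_strength()]).
#' @param W Linking kernel (sums to 1 after normalization).
#' @param f Feeding decay constant (default 0.2).
#' @param beta_reduce How `beta` enters: per-pixel matrix (`"perpixel"`,
#'   default), or its scalar `"mean"` / `"max"`.
#' @return Matrix (or scalar, under a scalar reduction) of threshold
#'   magnitudes.
#' @export
threshold_magnitude <- function(S, beta, W = gaussian_linking_weights(),
                                f = 0.2,
                                beta_reduce = c("perpixel", "mean", "max")) {
  S <- if (inherits(S, "image2d")) S$pixels else as.matrix(S)
  beta_reduce <- match.arg(beta_reduce)
  b <- switch(beta_reduce, perpixel = beta, mean = mean(beta), max = max(beta))
  (max(S) - min(S)) / (1 - f) + max(S) * (1 + b * sum(W))
}

#' Automatic iteration count from the Otsu level
#'
#' The outer-loop budget: `TS = TG / (1 - f)` with `TG` the Otsu level
#' of `S`, and `N = ceil((max(S) - TS) / delta + 1)`; if `TS >= max(S)`
#' a single iteration is used.
#'
#' @param S Input image on `[0, 1]`.
#' @param f Feeding decay constant.
#' @param delta Linear threshold decay per iteration.
#' @return Integer iteration count `N >= 1`.
#' @export
mscm_iterations <- function(S, f = 0.2, delta = 0.02) {
  S <- if (inherits(S, "image2d")) S$pixels else as.matrix(S)
  TG <- otsu_threshold(S, levels = 256L, range = c(0, 1))
  TS <- TG / (1 - f)
  if (TS >= max(S)) return(1L)
  as.integer(ceiling((max(S) - TS) / delta + 1))
}

#' Parameter bundle for the modified spiking cortical model
#'
#' Collects the MSCM constants; the data-dependent fields (`beta`, `h`,
#' `N`) are filled automatically from the input image by [fl_mscm()]
#' when left `NULL`.
#'
#' @param f Feeding decay constant in `(0, 1)` (default 0.2).
#' @param mL Linking magnitude (default 1).
#' @param delta Linear threshold decay per outer iteration (default 0.02).
#' @param E0 Initial threshold (default 1).
#' @param W Linking kernel (default [gaussian_linking_weights()]).
#' @param beta Optional per-pixel linking strengths.
#' @param h Optional per-pixel threshold magnitudes.
#' @param N Optional outer iteration budget.
#' @param inner_cap Safety cap on fast-linking inner passes (default 64).
#' @param beta_reduce Reduction used when deriving `h`, see
#'   [threshold_magnitude()].
#' @return An object of class `mscm_params`.
#' @export
mscm_params <- function(f = 0.2, mL = 1, delta = 0.02, E0 = 1,
                        W = gaussian_linking_weights(), beta = NULL,
                        h = NULL, N = NULL, inner_cap = 64L,
                        beta_reduce = "perpixel") {
  stopifnot(f > 0, f < 1, delta > 0, all(W >= 0), inner_cap >= 1)
  structure(list(f = f, mL = mL, delta = delta, E0 = E0, W = W,
                 beta = beta, h = h, N = N, inner_cap = as.integer(inner_cap),
                 beta_reduce = beta_reduce),
            class = "mscm_params")
}

# Fresh lattice state for an H x W image.
mscm_init_state <- function(H, W, E0 = 1) {
  z <- matrix(0, H, W)
  list(L = z, U = z, E = matrix(E0, H, W), Y = z,
       first_fire = matrix(0L, H, W), n = 0L)
}

#' One threshold step of the modified spiking cortical model
#'
#' Applies the linear threshold decay (`E <- E - delta`) once, then a
#' single linking/activity/firing pass:
#' `L = mL * (W * Y)` (zero-padded correlation),
#' `U = f U + S (1 + beta L)`, `Y = 1` where `U > E` (strict), and the
#' threshold of newly fired neurons is raised by `h` immediately so they
#' cannot fire again. Set `decay = FALSE` for the extra fast-linking
#' passes inside one outer iteration.
#'
#' @param state Lattice state as returned by a previous step (or created
#'   internally by [fl_mscm()]): fields `L`, `U`, `E`, `Y`, `first_fire`,
#'   `n`.
#' @param S Input image matrix on `[0, 1]`.
#' @param params An [mscm_params()] with `beta` and `h` filled.
#' @param decay Apply the once-per-outer-iteration decay and advance `n`?
#' @return The updated state.
#' @export
mscm_step <- function(state, S, params, decay = TRUE) {
  S <- if (inherits(S, "image2d")) S$pixels else as.matrix(S)
  if (decay) {
    state$E <- state$E - params$delta
    state$n <- state$n + 1L
  }
  L <- params$mL * linking_corr_cpp(state$Y, params$W)
  U <- params$f * state$U + S * (1 + params$beta * L)
  Ynew <- (U > state$E) + 0
  newly <- Ynew == 1 & state$first_fire == 0L
  if (any(newly)) {
    h <- if (length(params$h) == 1L)
      matrix(params$h, nrow(S), ncol(S)) else params$h
    state$E[newly] <- state$E[newly] + h[newly]
    state$first_fire[newly] <- state$n
  }
  state$L <- L; state$U <- U; state$Y <- Ynew
  state
}

#' Fast-linking modified spiking cortical model segmentation
#'
#' Runs the two-loop fast-linking iteration on a (normalized) image:
#' the outer loop decays every neuron's threshold linearly by `delta`
#' once per iteration; the inner loop re-updates linking, internal
#' activity, and the firing map until the firing map is unchanged, so
#' that neurons with similar stimuli fire synchronously in one wave.
#' Brighter structures (e.g. T2-hyperintense tumors) fire in earlier
#' waves; the tumor mask is extracted from the first-fire map with
#' [extract_firing_mask()].
#'
#' Parameters default to the automatic settings: `beta` from
#' [linking_strength()], `h` from [threshold_magnitude()], `N` from
#' [mscm_iterations()]. Input is min-max normalized to `[0, 1]` first.
#'
#' @param img An [image2d()] (any scale; normalized internally) or
#'   matrix on `[0, 1]`.
#' @param params An [mscm_params()]; data-dependent fields are filled
#'   from the image when `NULL`.
#' @param strategy Mask extraction rule, see [extract_firing_mask()].
#' @param k For `strategy = "k-waves"`, the number of early waves.
#' @return An object of class `fl_mscm`: `tumor_mask` ([binary_mask()]),
#'   `first_fire` (iteration map, 0 = never fired), `n_used`, `waves`
#'   (distinct firing iterations), `inner_passes` (per outer iteration),
#'   and `params`.
#' @export
#' @examples
#' S <- matrix(0.3, 24, 24); S[8:14, 8:14] <- 0.9
#' seg <- fl_mscm(image2d(S, range = c(0, 1)))
#' seg
fl_mscm <- function(img, params = mscm_params(), strategy = "first-wave",
                    k = 1L) {
  S <- if (inherits(img, "image2d")) {
    normalize_image(img, c(0, 1))$pixels
  } else {
    as.matrix(img)
  }
  if (max(S) > 1 + 1e-9 || min(S) < -1e-9)
    stop("fl_mscm: matrix input must already lie on [0, 1]")
  p <- params
  if (max(S) == min(S) && (is.null(p$N) || is.null(p$h)))
    stop("fl_mscm: constant image, automatic parameter setting undefined")
  if (is.null(p$beta)) p$beta <- linking_strength(S)
  if (is.null(p$h))
    p$h <- threshold_magnitude(S, p$beta, p$W, p$f, p$beta_reduce)
  if (is.null(p$N)) p$N <- mscm_iterations(S, p$f, p$delta)
  state <- mscm_init_state(nrow(S), ncol(S), p$E0)
  inner_passes <- integer(p$N)
  capped <- FALSE
  for (n in seq_len(p$N)) {
    state <- mscm_step(state, S, p, decay = TRUE)
    passes <- 1L
    repeat {
      Yprev <- state$Y
      state <- mscm_step(state, S, p, decay = FALSE)
      passes <- passes + 1L
      if (identical(state$Y, Yprev)) break
      if (passes >= p$inner_cap) { capped <- TRUE; break }
    }
    inner_passes[n] <- passes
  }
  if (capped)
    warning("fl_mscm: fast-linking inner loop hit inner_cap; ",
            "firing map may not have settled")
  ff <- state$first_fire
  mask <- extract_firing_mask(ff, strategy = strategy, k = k)
  structure(list(tumor_mask = mask, first_fire = ff, n_used = p$N,
                 waves = sort(unique(ff[ff > 0L])),
                 inner_passes = inner_passes, params = p),
            class = "fl_mscm")
}

#' Extract a mask from a first-fire map
#'
#' `"first-wave"` (default) keeps the pixels whose first firing
#' iteration equals the earliest positive one; `"k-waves"` keeps the
#' union of the `k` earliest distinct firing iterations.
#'
#' @param first_fire Integer matrix of first firing iterations
#'   (0 = never fired).
#' @param strategy `"first-wave"` or `"k-waves"`.
#' @param k Number of waves for `"k-waves"`.
#' @return A [binary_mask()].
#' @export
extract_firing_mask <- function(first_fire,
                                strategy = c("first-wave", "k-waves"),
                                k = 1L) {
  strategy <- match.arg(strategy)
  waves <- sort(unique(first_fire[first_fire > 0L]))
  if (length(waves) == 0L)
    return(binary_mask(matrix(0, nrow(first_fire), ncol(first_fire))))
  sel <- switch(strategy,
                "first-wave" = waves[1L],
                "k-waves" = waves[seq_len(min(k, length(waves)))])
  binary_mask(matrix(as.numeric(first_fire %in% sel), nrow(first_fire)))
}

#' @export
print.fl_mscm <- function(x, ...) {
  cat(sprintf(paste0("fl_mscm: %dx%d lattice, N=%d outer iterations, ",
                     "%d firing waves, mask %d px\n"),
              nrow(x$first_fire), ncol(x$first_fire), x$n_used,
              length(x$waves), sum(x$tumor_mask$pixels)))
  invisible(x)
}

#' @export
plot.fl_mscm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  ff <- x$first_fire
  show_gray(1 - ff / max(1, max(ff)), "first-fire map (bright = early)")
  show_gray(x$tumor_mask$pixels, "extracted mask")
  invisible(x)
}
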