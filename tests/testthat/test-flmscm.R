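bl <- asNamespace("brainlite")

test_that("the Gaussian linking kernel is normalized, symmetric, unimodal", {
  W <- gaussian_linking_weights(7, 1)
  expect_equal(sum(W), 1)
  expect_equal(W, t(W))
  expect_equal(W, W[7:1, ])
  expect_equal(which.max(W), 25L)  # center of the 7x7
  expect_true(all(W >= 0))
})

test_that("linking strength is a sigmoid of the gradient magnitude", {
  expect_true(all(linking_strength(matrix(0.4, 8, 8)) == 0.5))
  # vertical unit step: central difference 0.5 at both step columns
  S <- matrix(0, 6, 6); S[, 4:6] <- 1
  b <- linking_strength(S)
  expect_equal(b[3, 3], 1 / (1 + exp(-0.5)))
  expect_equal(b[3, 4], 1 / (1 + exp(-0.5)))
  expect_true(all(b >= 0.5 & b < 1))
})

test_that("threshold magnitude follows the closed form", {
  S <- matrix(c(0, 1), 2, 2)
  expect_equal(threshold_magnitude(S, beta = 0.5, f = 0.2,
                                   beta_reduce = "mean"),
               1 / 0.8 + 1 * 1.5)  # 2.75
  # constant image: first term vanishes, h = c * (1 + beta)
  expect_equal(threshold_magnitude(matrix(0.6, 3, 3), beta = 0.5, f = 0.2,
                                   beta_reduce = "mean"), 0.6 * 1.5)
})

test_that("iteration budget derives from the Otsu level", {
  # two levels placed so the Otsu threshold is exactly 0.5:
  # TS = 0.5 / 0.8 = 0.625, N = ceil((1 - 0.625)/0.02 + 1) = 20
  S <- matrix(c(rep(0.4999, 128), rep(1, 128)), 16, 16)
  expect_equal(otsu_threshold(S, range = c(0, 1)), 0.5)
  expect_equal(mscm_iterations(S), 20L)
  # halving delta roughly doubles the budget
  expect_equal(mscm_iterations(S, delta = 0.01), 39L)
  # threshold at or above the maximum: a single iteration
  S2 <- matrix(c(rep(0.9, 128), rep(1, 128)), 16, 16)
  expect_equal(mscm_iterations(S2), 1L)
  expect_error(mscm_iterations(matrix(0.5, 4, 4)), "constant")
})

test_that("Otsu matches exhaustive search and an independent package", {
  set.seed(14)
  for (rep in 1:5) {
    x <- matrix(c(rnorm(100, 0.3, 0.05), rnorm(156, 0.7, 0.08)), 16, 16)
    x <- pmin(pmax(x, 0), 1)
    t_pkg <- otsu_threshold(x, range = c(0, 1))
    # brute force over all 256 candidate split points
    w <- 1 / 256
    bin <- pmin(floor(x / w), 255)
    best <- -Inf; kbest <- NA
    for (k in 1:255) {
      g1 <- x[bin < k]; g2 <- x[bin >= k]
      if (!length(g1) || !length(g2)) next
      sb <- length(g1) * length(g2) / length(x)^2 *
        (mean(g1) - mean(g2))^2
      if (sb > best + 1e-15) { best <- sb; kbest <- k }
    }
    expect_equal(t_pkg, kbest * w)
    # independent implementation: tie-break conventions differ on
    # near-flat plateaus, so compare the induced binarizations
    t_eb <- EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = 256)
    expect_lt(mean((x < t_pkg) != (x < t_eb)), 0.02)
  }
  expect_error(otsu_threshold(matrix(1, 3, 3)), "constant")
})

test_that("a single step follows the lattice equations", {
  S <- matrix(0.5, 5, 5)
  p <- mscm_params(N = 10L)
  p$beta <- matrix(0.5, 5, 5)
  p$h <- 2
  st <- bl$mscm_init_state(5, 5)
  # no previous pulses: linking is zero everywhere
  st1 <- mscm_step(st, S, p, decay = TRUE)
  expect_true(all(st1$L == 0))
  expect_equal(st1$U, 0.2 * st$U + S, ignore_attr = TRUE)
  # U = 0.5 < E = 0.98: no firing, E decayed by exactly delta
  expect_true(all(st1$Y == 0))
  expect_true(all(st1$E == 0.98))
  # an isolated fired pixel spreads mL * W to its neighborhood
  st1$Y[3, 3] <- 1
  st2 <- mscm_step(st1, S, p, decay = FALSE)
  expect_equal(st2$L[2, 3], p$mL * p$W[3, 4])
  expect_equal(st2$L[3, 3], p$mL * p$W[4, 4])
})

test_that("no pixel fires twice within the automatic budget", {
  set.seed(50)
  for (rep in 1:5) {
    S <- matrix(runif(256), 16, 16)
    p <- mscm_params()
    p$beta <- linking_strength(S)
    p$h <- threshold_magnitude(S, p$beta)
    p$N <- mscm_iterations(S)
    st <- bl$mscm_init_state(16, 16)
    rising <- matrix(0L, 16, 16)  # 0 -> 1 pulse transitions per pixel
    yprev <- st$Y
    for (n in seq_len(p$N)) {
      st <- mscm_step(st, S, p, decay = TRUE)
      rising <- rising + (st$Y == 1 & yprev == 0)
      yprev <- st$Y
      repeat {
        yp <- st$Y
        st <- mscm_step(st, S, p, decay = FALSE)
        rising <- rising + (st$Y == 1 & yp == 0)
        yprev <- st$Y
        if (identical(st$Y, yp)) break
      }
    }
    expect_lte(max(rising), 1L)
    seg <- fl_mscm(S)
    expect_true(all(seg$first_fire[seg$tumor_mask$pixels == 1] ==
                      min(seg$first_fire[seg$first_fire > 0])))
  }
})

test_that("firing order follows intensity when linking is disabled", {
  set.seed(60)
  S <- matrix(runif(256), 16, 16)
  seg <- fl_mscm(S, mscm_params(mL = 0))
  ff <- seg$first_fire
  ord <- order(S, decreasing = TRUE)
  fired_seq <- ff[ord][ff[ord] > 0]
  expect_false(is.unsorted(fired_seq))
  # and all unfired pixels are dimmer than every fired pixel
  if (any(ff == 0) && any(ff > 0))
    expect_lt(max(S[ff == 0]), min(S[ff > 0]))
})

test_that("fast linking synchronizes a noiseless two-level image", {
  S <- matrix(0.3, 20, 20); S[6:12, 6:12] <- 1
  seg <- fl_mscm(S)
  expect_length(seg$waves, 2L)
  expect_equal((seg$first_fire == seg$waves[1]) + 0, (S == 1) + 0)
})

test_that("identical neurons fire in one shared wave", {
  p <- mscm_params(N = 40L, h = 2)
  p$beta <- matrix(0.5, 10, 10)
  seg <- fl_mscm(matrix(0.5, 10, 10), p)
  expect_length(unique(as.vector(seg$first_fire)), 1L)
  expect_true(all(seg$tumor_mask$pixels == 1))  # one wave = full mask
})

test_that("the threshold decays by exactly delta on non-firing steps", {
  set.seed(70)
  S <- matrix(runif(64), 8, 8)
  p <- mscm_params()
  p$beta <- linking_strength(S)
  p$h <- threshold_magnitude(S, p$beta)
  p$N <- 6L
  st <- bl$mscm_init_state(8, 8)
  for (n in 1:6) {
    E0 <- st$E
    st <- mscm_step(st, S, p, decay = TRUE)
    newly <- st$first_fire == st$n & st$first_fire > 0
    expect_true(all(abs((E0 - st$E)[!newly] - p$delta) < 1e-12))
  }
})

test_that("mask extraction strategies follow their rules", {
  ff <- matrix(0L, 4, 4)
  ff[1, ] <- 3L
  expect_equal(sum(extract_firing_mask(ff)$pixels), 4)
  ff2 <- matrix(c(2L, 9L), 4, 4)
  m <- extract_firing_mask(ff2, "first-wave")
  expect_equal(m$pixels, (ff2 == 2L) + 0)
  expect_true(all(extract_firing_mask(ff2, "k-waves", k = 2)$pixels == 1))
  all3 <- matrix(3L, 2, 2)
  expect_true(all(extract_firing_mask(all3)$pixels == 1))
})

test_that("degenerate input errors unless parameters are supplied", {
  expect_error(fl_mscm(matrix(0.5, 6, 6)), "constant")
  expect_error(fl_mscm(matrix(2, 6, 6)), "\\[0, 1\\]")
})
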