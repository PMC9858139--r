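bl <- asNamespace("brainlite")

degenerate_pars <- function(...) {
  utils::modifyList(list(reflect_r = FALSE, reflect_c = FALSE, rotation = 0,
                         shear_x = 0, shear_y = 0, scale = 1,
                         translate = c(0, 0)),
                    list(...))
}

test_that("degenerate configuration draws the identity transform", {
  cfg <- augment_config(rotation = c(0, 0), translate = c(0, 0),
                        reflect_prob = 0, scale = c(1, 1), shear = c(0, 0))
  set.seed(1)
  tf <- random_affine(cfg)
  expect_equal(tf$M, diag(2))
  expect_equal(tf$t, c(0, 0))
})

test_that("transforms are reproducible under a fixed seed", {
  cfg <- augment_config()
  set.seed(33); a <- random_affine(cfg)
  set.seed(33); b <- random_affine(cfg)
  expect_identical(a, b)
})

test_that("a collapsed rotation interval yields the exact rotation matrix", {
  cfg <- augment_config(rotation = c(90, 90), translate = c(0, 0),
                        reflect_prob = 0, scale = c(1, 1), shear = c(0, 0))
  set.seed(2)
  tf <- random_affine(cfg)
  th <- pi / 2
  expect_equal(tf$M, matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2))
})

test_that("warping: identity, reflection involution, pixel translation", {
  px <- matrix(0, 9, 9); px[5, 4] <- 100
  img <- image2d(px)
  expect_equal(apply_affine(img, bl$identity_affine())$pixels, px)
  refl <- bl$affine2d(degenerate_pars(reflect_c = TRUE))
  twice <- apply_affine(apply_affine(img, refl), refl)
  expect_equal(twice$pixels, px, tolerance = 1e-12)
  shift <- bl$affine2d(degenerate_pars(translate = c(0, 3)))
  moved <- apply_affine(img, shift)
  expect_equal(moved$pixels[5, 7], 100)
  expect_equal(sum(moved$pixels), 100)
})

test_that("augmentation multiplies dataset and label counts exactly", {
  set.seed(5)
  imgs <- replicate(37, image2d(matrix(runif(64, 0, 255), 8, 8)),
                    simplify = FALSE)
  labels <- rep(c("normal", "abnormal"), c(12, 25))
  ds <- labeled_dataset(imgs, labels)
  aug <- augment_dataset(ds, augment_config(per_image = 9, seed = 4))
  expect_length(aug, 37 * 9)
  expect_equal(sum(aug$labels == "normal"), 12 * 9)
  expect_equal(sum(aug$labels == "abnormal"), 25 * 9)
  # per_image = 1 returns the dataset unchanged
  same <- augment_dataset(ds, augment_config(per_image = 1, seed = 4))
  expect_equal(same$images[[10]]$pixels, imgs[[10]]$pixels)
  expect_error(augment_config(per_image = 0), "per_image")
})

test_that("the published counts follow from per_image = 9", {
  # 60 normal and 125 abnormal originals expand to 540 and 1125
  imgs <- replicate(185, image2d(matrix(0:3 + 0, 2, 2)), simplify = FALSE)
  ds <- labeled_dataset(imgs, rep(c("normal", "abnormal"), c(60, 125)))
  aug <- augment_dataset(ds, augment_config(per_image = 9, seed = 1))
  expect_equal(sum(aug$labels == "normal"), 540)
  expect_equal(sum(aug$labels == "abnormal"), 1125)
})

test_that("augmentation is reproducible end to end under one seed", {
  imgs <- replicate(3, image2d(matrix(runif(256, 0, 255), 16, 16)),
                    simplify = FALSE)
  ds <- labeled_dataset(imgs, c("normal", "abnormal", "abnormal"))
  a <- augment_dataset(ds, augment_config(per_image = 4, seed = 11))
  b <- augment_dataset(ds, augment_config(per_image = 4, seed = 11))
  for (i in seq_along(a$images))
    expect_identical(a$images[[i]]$pixels, b$images[[i]]$pixels)
})
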