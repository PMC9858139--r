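cc_of <- function(TP, FP, TN, FN)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN),
            class = "confusion_counts")

test_that("confusion tallies labels and masks", {
  p <- rep(c("abnormal", "normal"), c(10, 10))
  cc <- confusion_counts(p, p)
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 10, TN = 10, FP = 0, FN = 0))
  compl <- rep(c("normal", "abnormal"), c(10, 10))
  cc2 <- confusion_counts(compl, p)
  expect_equal(cc2$TP + cc2$TN, 0)
  # 3x3 masks with one overlapping pixel
  a <- matrix(0, 3, 3); a[1, 1] <- 1; a[2, 2] <- 1
  b <- matrix(0, 3, 3); b[2, 2] <- 1; b[3, 3] <- 1
  cc3 <- confusion_counts(binary_mask(a), binary_mask(b))
  expect_equal(unclass(cc3)[c("TP", "FP", "FN", "TN")],
               list(TP = 1, FP = 1, FN = 1, TN = 6))
})

test_that("classification metrics follow the printed formulas", {
  m <- classification_metrics(cc_of(3, 1, 5, 1))
  expect_equal(m$ppv, 75)
  expect_equal(m$tpr, 75)
  expect_equal(m$f_score, 75)
  expect_equal(m$accuracy, 80)
  expect_equal(m$tnr, 500 / 6)
  expect_equal(m$auc, (75 + 500 / 6) / 2)
  perfect <- classification_metrics(cc_of(7, 0, 3, 0))
  expect_true(all(unlist(unclass(perfect)) == 100))
  # zero-denominator policy: undefined marker, report still emitted
  nopos <- classification_metrics(cc_of(0, 2, 5, 0))
  expect_true(is.na(nopos$tpr))
  expect_true(is.na(nopos$auc))
  expect_false(is.na(nopos$tnr))
})

test_that("balanced AUC reproduces the published worked example", {
  # second-fold rates 99.11 / 98.15 arise from 111/112 and 53/54
  m <- classification_metrics(cc_of(111, 1, 53, 1))
  expect_equal(round(m$tpr, 2), 99.11)
  expect_equal(round(m$tnr, 2), 98.15)
  expect_equal(round(m$auc, 2), 98.63)
  expect_equal(round((99.11 + 98.15) / 2, 2), 98.63)
})

test_that("DSC: symmetry, identity, disjoint, arithmetic", {
  a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
  b <- matrix(0, 4, 4); b[2:3, 1:2] <- 1  # |a|=|b|=4, overlap 2
  expect_equal(dice_coefficient(a, b), 0.5)
  expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
  expect_equal(dice_coefficient(a, a), 1)
  disj <- matrix(0, 4, 4); disj[3:4, 3:4] <- 1
  expect_equal(dice_coefficient(a, disj), 0)
  # |S| = 4, |SG| = 4, overlap 3 -> 0.75
  b3 <- a; b3[1, 1] <- 0; b3[3, 3] <- 1
  expect_equal(dice_coefficient(a, b3), 0.75)
  expect_true(is.na(dice_coefficient(matrix(0, 2, 2), matrix(0, 2, 2))))
  expect_error(dice_coefficient(a, matrix(0, 2, 2)), "shape")
})

test_that("DSC equals the F-score of the pixel confusion", {
  set.seed(8)
  for (rep in 1:10) {
    a <- matrix(rbinom(64, 1, 0.4), 8, 8)
    b <- matrix(rbinom(64, 1, 0.4), 8, 8)
    if (sum(a) + sum(b) == 0) next
    cc <- confusion_counts(binary_mask(a), binary_mask(b))
    f <- classification_metrics(cc)$f_score
    if (!is.na(f))
      expect_equal(100 * dice_coefficient(a, b), f)
  }
})

test_that("accuracy is invariant under swapping the classes", {
  m1 <- classification_metrics(cc_of(13, 4, 22, 7))
  m2 <- classification_metrics(cc_of(22, 7, 13, 4))
  expect_equal(m1$accuracy, m2$accuracy)
})

test_that("fold summaries use means and sample SD", {
  s <- summarize_folds(data.frame(accuracy = c(100, 100, 98.5, 100, 99.4)))
  expect_equal(s["mean", "accuracy"], 99.58)
  ident <- replicate(3, classification_metrics(cc_of(5, 0, 5, 0)),
                     simplify = FALSE)
  si <- summarize_folds(ident)
  expect_equal(si["sd", "accuracy"], 0)
  s2 <- summarize_folds(data.frame(accuracy = c(0, 100)))
  expect_equal(s2["mean", "accuracy"], 50)
})
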