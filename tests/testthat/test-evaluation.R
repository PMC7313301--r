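test_that("confusion counts match the documented identities", {
  truth <- matrix(0L, 8, 8); truth[2:3, 2:4] <- 1L
  c_id <- confusion(truth, truth, 1)
  expect_equal(c_id[["FP"]] + c_id[["FN"]], 0)
  c_empty <- confusion(matrix(0L, 8, 8), truth, 1)
  expect_equal(c_empty[["TP"]], 0)
  expect_equal(c_empty[["FN"]], 6)
  expect_error(confusion(matrix(0L, 8, 8), matrix(0L, 8, 9), 1),
               class = "ccparcel_validation_error")
})

test_that("metric formulas reproduce hand-computed ratios", {
  c1 <- structure(c(TP = 5, TN = 0, FP = 0, FN = 0), class = "confusion_counts")
  expect_equal(dice(c1), 1)
  c2 <- structure(c(TP = 2, TN = 0, FP = 1, FN = 1), class = "confusion_counts")
  expect_equal(dice(c2), 2 / 3, tolerance = 1e-12)
  c3 <- structure(c(TP = 0, TN = 0, FP = 3, FN = 3), class = "confusion_counts")
  expect_equal(dice(c3), 0)
  c4 <- structure(c(TP = 50, TN = 50, FP = 0, FN = 0), class = "confusion_counts")
  expect_equal(c(accuracy(c4), sensitivity(c4), specificity(c4), precision(c4)),
               rep(1, 4))
  c5 <- structure(c(TP = 1, TN = 0, FP = 0, FN = 3), class = "confusion_counts")
  expect_equal(sensitivity(c5), 0.25)
})

test_that("empty-vs-empty Dice is 1 and zero denominators give NA markers", {
  c0 <- structure(c(TP = 0, TN = 10, FP = 0, FN = 0), class = "confusion_counts")
  expect_message(d <- dice(c0), "absence")
  expect_equal(d, 1)
  expect_true(is.na(precision(c0)))
  expect_true(is.na(sensitivity(c0)))
  expect_equal(specificity(c0), 1)
})

test_that("all five metrics match the per-pixel tally oracle exactly", {
  set.seed(10)
  for (i in 1:20) {
    pred <- matrix(sample(0:5, 256, replace = TRUE), 16, 16)
    truth <- matrix(sample(0:5, 256, replace = TRUE), 16, 16)
    for (p in 1:5) {
      got <- confusion(pred, truth, p)
      want <- tally_oracle(pred, truth, p)
      expect_equal(unname(unclass(got)[c("TP", "TN", "FP", "FN")]),
                   unname(as.numeric(want)))
    }
  }
})

test_that("Dice is symmetric in its two maps", {
  set.seed(2)
  a <- matrix(sample(0:5, 144, replace = TRUE), 12, 12)
  b <- matrix(sample(0:5, 144, replace = TRUE), 12, 12)
  for (p in 1:5)
    expect_equal(suppressMessages(dice(confusion(a, b, p))),
                 suppressMessages(dice(confusion(b, a, p))))
})

test_that("the report's mean row equals the recomputed mean", {
  set.seed(3)
  pred <- matrix(sample(0:5, 400, replace = TRUE), 20, 20)
  truth <- matrix(sample(0:5, 400, replace = TRUE), 20, 20)
  rep <- metric_report(pred, truth)
  expect_identical(rep$parcel, c("1", "2", "3", "4", "5", "mean", "sd"))
  for (col in c("dice", "accuracy", "sensitivity", "specificity", "precision")) {
    expect_equal(rep[[col]][6], mean(rep[[col]][1:5]), tolerance = 1e-12)
    expect_true(all(rep[[col]][1:5] >= 0 & rep[[col]][1:5] <= 1))
  }
})

test_that("pairwise Dice tables have the documented geometry", {
  rect <- matrix(TRUE, 10, 60)
  w <- geometric_parcellate(rect, "witelson")
  h <- geometric_parcellate(rect, "hofer")
  self <- pairwise_dice_table(list(a = w, b = w))
  expect_equal(self[["a vs b"]], rep(1, 5))
  tab <- pairwise_dice_table(list(witelson = w, hofer = h))
  expect_equal(tab[["witelson vs hofer"]][3], 1)          # shared 1/2 and 2/3 cuts
  expect_equal(tab[["witelson vs hofer"]][1], 2 / 3, tolerance = 1e-12)
  # brute-force check of parcel 1: overlap of [0,1/6) within [0,1/3)
  o <- tally_oracle(w$labels, h$labels, 1)
  expect_equal(tab[["witelson vs hofer"]][1],
               2 * o[["TP"]] / (2 * o[["TP"]] + o[["FP"]] + o[["FN"]]))
  expect_error(pairwise_dice_table(list(w)), class = "ccparcel_validation_error")
})
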