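# Brute-force oracle: rebuild per-class binary vectors from the confusion
# matrix and count TP/FP/TN/FN directly, then apply the printed formulas.
brute_force_metrics <- function(Z) {
  obs <- rep(rep(localization_classes(), each = 8), times = as.vector(t(Z)))
  pred <- rep(rep(localization_classes(), times = 8), times = as.vector(t(Z)))
  lapply(seq_len(8), function(i) {
    cl <- localization_classes()[i]
    TP <- sum(obs == cl & pred == cl)
    FP <- sum(obs != cl & pred == cl)
    FN <- sum(obs == cl & pred != cl)
    TN <- sum(obs != cl & pred != cl)
    spec <- if (TP + FP == 0) 0 else TP / (TP + FP)
    sens <- if (TP + FN == 0) 0 else TP / (TP + FN)
    acc <- (TP + TN) / length(obs)
    den <- sqrt(as.numeric(TP + FP)) * sqrt(as.numeric(TP + FN)) *
      sqrt(as.numeric(TN + FP)) * sqrt(as.numeric(TN + FN))
    mcc <- if (den == 0) 0 else (as.numeric(TP) * TN - as.numeric(FP) * FN) / den
    f1 <- if (spec + sens == 0) 0 else 2 * spec * sens / (spec + sens)
    list(TP = TP, FP = FP, TN = TN, FN = FN, Spec = spec, Sens = sens,
         Acc = acc, MCC = mcc, F1 = f1)
  })
}

test_that("confusion tallies match a brute-force pairwise count", {
  cls <- localization_classes()
  set.seed(5)
  for (rep_i in 1:5) {
    n <- sample(20:60, 1)
    obs <- sample(cls, n, replace = TRUE)
    pred <- sample(cls, n, replace = TRUE)
    Z <- confusion(pred, obs)
    for (i in 1:8) {
      for (j in 1:8) {
        expect_equal(Z[i, j], sum(obs == cls[i] & pred == cls[j]))
      }
    }
    expect_equal(sum(Z), n)
  }
  expect_error(confusion(cls[1:3], cls[1:2]), "differ in length")

  Zp <- confusion(cls, cls)  # perfect prediction, one per class
  expect_equal(Zp, diag(8), ignore_attr = TRUE)
  Z1 <- confusion(cls[6], cls[3])
  expect_equal(Z1[3, 6], 1L)
  expect_equal(sum(Z1), 1L)
})

test_that("per-class metrics equal the binary-recount oracle on random matrices", {
  set.seed(17)
  for (rep_i in 1:40) {
    Z <- matrix(rpois(64, lambda = sample(c(0.5, 3, 20), 1)), 8, 8)
    m <- per_class_metrics(Z)
    oracle <- brute_force_metrics(Z)
    for (i in 1:8) {
      expect_identical(as.integer(m$TP[i]), as.integer(oracle[[i]]$TP))
      expect_identical(as.integer(m$FP[i]), as.integer(oracle[[i]]$FP))
      expect_identical(as.integer(m$TN[i]), as.integer(oracle[[i]]$TN))
      expect_identical(as.integer(m$FN[i]), as.integer(oracle[[i]]$FN))
      expect_equal(m$Spec[i], oracle[[i]]$Spec)
      expect_equal(m$Sens[i], oracle[[i]]$Sens)
      expect_equal(m$Acc[i], oracle[[i]]$Acc)
      expect_equal(m$MCC[i], oracle[[i]]$MCC)
      expect_equal(m$F1[i], oracle[[i]]$F1)
    }
    # the four counts always sum to the grand total
    expect_equal(m$TP + m$FP + m$TN + m$FN, rep(sum(Z), 8))
  }
})

test_that("metric edge cases: perfect, no-association and empty classes", {
  Zp <- diag(c(10, 10, 0, 0, 0, 0, 0, 0))
  m <- per_class_metrics(Zp)
  expect_equal(m$MCC[1:2], c(1, 1))
  expect_equal(m$F1[1:2], c(1, 1))
  # empty classes have 0/0 metrics defined as 0 and flagged
  expect_equal(m$MCC[3:8], rep(0, 6))
  expect_true(all(m$degenerate[3:8]))

  Zu <- matrix(0, 8, 8); Zu[1:2, 1:2] <- 5
  m2 <- per_class_metrics(Zu)
  expect_equal(m2$MCC[1:2], c(0, 0))  # no association

  expect_true(all(per_class_metrics(matrix(5L, 8, 8))$MCC == 0))
})

test_that("overall Q is the trace over the total", {
  expect_equal(overall_Q(diag(8)), 1)
  expect_equal(overall_Q(matrix(1, 8, 8)), 0.125)
  set.seed(3)
  Z <- matrix(rpois(64, 4), 8, 8)
  expect_equal(overall_Q(Z), sum(diag(Z)) / sum(Z))
  m <- per_class_metrics(Z)
  expect_equal(overall_Q(Z), sum(m$TP) / sum(Z))  # Q = sum TP_i / total
  expect_error(overall_Q(matrix(0, 8, 8)), "empty")
})

test_that("the report formats every class in frozen order", {
  Z <- diag(rep(5L, 8))
  rep_tab <- metrics_report(Z)
  expect_equal(rep_tab$class, localization_classes())
  expect_equal(rep_tab$MCC, rep("1.00", 8))
  expect_equal(rep_tab$Accuracy, rep("100.00%", 8))
  expect_equal(attr(rep_tab, "Q"), 1)

  set.seed(8)
  Z2 <- matrix(rpois(64, 6), 8, 8)
  m <- per_class_metrics(Z2)
  rep2 <- metrics_report(Z2)
  expect_equal(rep2$MCC, sprintf("%.2f", m$MCC))
  expect_equal(rep2$Sens, sprintf("%.2f%%", 100 * m$Sens))
  f <- withr::local_tempfile(fileext = ".tsv")
  metrics_report(Z2, path = f)
  expect_equal(utils::read.delim(f)$MCC, as.numeric(rep2$MCC))
})

test_that("MCC is symmetric under swapping positives and negatives", {
  set.seed(21)
  Z <- matrix(rpois(64, 5), 8, 8)
  m <- per_class_metrics(Z)
  for (i in 1:8) {
    # swap: treat "not class i" as positive by permuting counts
    TP <- m$TN[i]; TN <- m$TP[i]; FP <- m$FN[i]; FN <- m$FP[i]
    den <- sqrt(as.numeric(TP + FP)) * sqrt(as.numeric(TP + FN)) *
      sqrt(as.numeric(TN + FP)) * sqrt(as.numeric(TN + FN))
    swapped <- if (den == 0) 0 else
      (as.numeric(TP) * TN - as.numeric(FP) * FN) / den
    expect_equal(m$MCC[i], swapped)
  }
})
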