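test_that("pair confusion counts the strict upper triangle once", {
  truth <- pairs_to_matrix(rbind(c(1, 4), c(2, 3)), 4)
  pred <- pairs_to_matrix(rbind(c(1, 4)), 4)
  cc <- pair_confusion(pred, truth)
  expect_equal(cc$TP, 1)
  expect_equal(cc$FP, 0)
  expect_equal(cc$FN, 1)
  expect_equal(cc$TN, choose(4, 2) - 2)
  ident <- pair_confusion(truth, truth)
  expect_equal(ident$FP + ident$FN, 0)
  expect_equal(ident$TP, 2)
  empty <- pair_confusion(matrix(0, 4, 4), truth)
  expect_equal(empty$TP, 0)
  expect_equal(empty$FN, 2)
  expect_error(pair_confusion(matrix(0, 3, 3), truth), "dimensions")
})

test_that("PPV, sensitivity and F1 reproduce closed forms", {
  v <- ppv_sen_f1(confusion_counts(TP = 3, FP = 1, FN = 2))
  expect_equal(unname(v["PPV"]), 0.75)
  expect_equal(unname(v["SEN"]), 0.6)
  expect_equal(unname(v["F1"]), 2 * 0.75 * 0.6 / 1.35)
  expect_equal(unname(ppv_sen_f1(confusion_counts(5, 0, 0))), c(1, 1, 1))
  expect_equal(unname(ppv_sen_f1(confusion_counts(0, 2, 3))), c(0, 0, 0))
  expect_equal(unname(ppv_sen_f1(confusion_counts(0, 0, 0))), c(0, 0, 0))
})

test_that("F1 lies between PPV and sensitivity when both positive", {
  set.seed(41)
  for (rep in 1:20) {
    cc <- confusion_counts(sample(1:30, 1), sample(0:30, 1), sample(0:30, 1))
    v <- ppv_sen_f1(cc)
    if (v["PPV"] > 0 && v["SEN"] > 0) {
      expect_gte(v[["F1"]], min(v[["PPV"]], v[["SEN"]]) - 1e-12)
      expect_lte(v[["F1"]], max(v[["PPV"]], v[["SEN"]]) + 1e-12)
    }
  }
})

test_that("MCC and ACC follow their definitions and conventions", {
  expect_equal(mcc(confusion_counts(5, 0, 0, 5)), 1)
  expect_equal(mcc(confusion_counts(0, 1, 1, 0)), -1)
  expect_equal(mcc(confusion_counts(3, 0, 2, 0)), 0)  # all predicted positive
  expect_equal(acc(confusion_counts(2, 1, 4, 3)), 0.5)
  expect_equal(acc(confusion_counts(4, 0, 0, 6)), 1)
  expect_equal(acc(confusion_counts(0, 3, 2, 0)), 0)
  expect_error(mcc(confusion_counts(1, 1, 1)), "TN")
  expect_error(acc(confusion_counts(0, 0, 0, 0)), "empty")
  set.seed(13)
  for (rep in 1:20) {
    cc <- confusion_counts(sample(0:9, 1), sample(0:9, 1),
                           sample(0:9, 1), sample(0:9, 1))
    expect_gte(mcc(cc), -1)
    expect_lte(mcc(cc), 1)
  }
})

test_that("MCC is invariant under swapping prediction and truth", {
  # swapping roles exchanges FP and FN, which Matthews' formula ignores
  cc <- confusion_counts(7, 3, 5, 11)
  sw <- confusion_counts(7, 5, 3, 11)
  expect_equal(mcc(cc), mcc(sw))
})

test_that("AUROC uses mid-rank ties and monotone invariance", {
  sc <- c(0.9, 0.8, 0.3, 0.2)
  lb <- c(1, 1, 0, 0)
  expect_equal(auroc(sc, lb), 1)
  expect_equal(auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auroc(-sc, lb), 0)
  set.seed(17)
  s <- runif(40); l <- rbinom(40, 1, 0.4)
  expect_equal(auroc(s, l), auroc(exp(3 * s), l))
  expect_error(auroc(s, rep(1, 40)), "positive and one negative")
})

test_that("AUPRC under all-tied scores equals positive prevalence", {
  lb <- c(1, 0, 0, 1, 0, 0, 0, 0)
  expect_equal(auprc(rep(0.7, 8), lb), mean(lb))
  expect_equal(auprc(c(0.9, 0.8, 0.1, 0.1), c(1, 1, 0, 0)), 1)
})

test_that("ranking metrics agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  s <- runif(60); l <- rbinom(60, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(l, s, direction = "<",
                                        quiet = TRUE)))
  expect_equal(auroc(s, l), ref, tolerance = 1e-12)
})

test_that("pair metrics agree with a naive per-cell recount", {
  set.seed(29)
  for (rep in 1:5) {
    pred <- pairs_to_matrix(matrix_to_pairs(matrix(runif(400), 20, 20) > 0.85), 20)
    truth <- pairs_to_matrix(matrix_to_pairs(matrix(runif(400), 20, 20) > 0.85), 20)
    cc <- pair_confusion(pred, truth)
    tp <- fp <- fn <- tn <- 0
    for (i in 1:19) for (j in (i + 1):20) {
      p <- pred[i, j] > 0.5; t <- truth[i, j] > 0.5
      tp <- tp + (p && t); fp <- fp + (p && !t)
      fn <- fn + (!p && t); tn <- tn + (!p && !t)
    }
    expect_equal(c(cc$TP, cc$FP, cc$FN, cc$TN), c(tp, fp, fn, tn))
  }
})

test_that("metric reports serialize as TSV and JSON", {
  m <- c(PPV = 0.75, SEN = 0.6, F1 = 2 / 3)
  base <- tempfile()
  write_metric_report(m, base)
  tsv <- read.table(paste0(base, ".tsv"), header = TRUE, sep = "\t")
  expect_equal(tsv$metric, names(m))
  js <- jsonlite::read_json(paste0(base, ".json"))
  expect_equal(js$F1, 2 / 3, tolerance = 1e-12)
})
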