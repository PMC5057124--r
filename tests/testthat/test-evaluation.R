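test_that("metric formulas reproduce hand-computed values", {
  m <- classification_metrics(107, 32, 87, 18)
  expect_equal(m$Sn, 100 * 107 / 125)
  expect_equal(m$Sp, 100 * 87 / 119)
  expect_equal(m$Acc, 100 * 194 / 244)
  expect_equal(m$MCC, (107 * 87 - 32 * 18) /
                 sqrt(139 * 125 * 119 * 105))

  perfect <- classification_metrics(10, 0, 7, 0)
  expect_equal(perfect$Sn, 100)
  expect_equal(perfect$Sp, 100)
  expect_equal(perfect$Acc, 100)
  expect_equal(perfect$MCC, 1)
})

test_that("degenerate confusion counts follow the documented conventions", {
  expect_warning(m <- classification_metrics(5, 0, 0, 2), "Sp undefined")
  expect_true(is.nan(m$Sp))
  expect_equal(m$Sn, 100 * 5 / 7)
  expect_equal(m$MCC, 0)  # zero marginal
  expect_error(classification_metrics(0, 0, 0, 0), "all-zero")
  expect_error(classification_metrics(-1, 0, 3, 0), "non-negative")
})

test_that("metrics are scale-free and MCC stays in [-1, 1]", {
  set.seed(21)
  for (i in 1:30) {
    cnt <- as.list(rpois(4, 20) + 1)
    names(cnt) <- c("TP", "FP", "TN", "FN")
    a <- classification_metrics(cnt$TP, cnt$FP, cnt$TN, cnt$FN)
    b <- classification_metrics(3 * cnt$TP, 3 * cnt$FP, 3 * cnt$TN, 3 * cnt$FN)
    expect_equal(a[c("Sn", "Sp", "Acc", "MCC")], b[c("Sn", "Sp", "Acc", "MCC")])
    expect_true(a$MCC >= -1 && a$MCC <= 1)
    expect_true(a$Acc >= min(a$Sn, a$Sp) - 1e-9 && a$Acc <= max(a$Sn, a$Sp) + 1e-9)
  }
  expect_equal(classification_metrics(9, 0, 4, 0)$MCC, 1)  # FP = FN = 0
})

test_that("confusion counting respects class margins", {
  set.seed(8)
  truth <- sample(c(1, -1), 60, replace = TRUE, prob = c(0.6, 0.4))
  pred <- ifelse(runif(60) < 0.8, truth, -truth)
  cc <- confusion_counts(truth, pred)
  expect_equal(cc$TP + cc$FN, sum(truth == 1))
  expect_equal(cc$TN + cc$FP, sum(truth == -1))
})

test_that("k-fold CV is deterministic and pools counts across folds", {
  ds <- generate_dataset(synthetic_spec(n_pos = 20, n_neg = 20,
                                        separation = 1, seed = 5))
  r1 <- kfold_cv(ds$windows, ds$labels, C = 8, gamma = 2, k = 4, seed = 2)
  r2 <- kfold_cv(ds$windows, ds$labels, C = 8, gamma = 2, k = 4, seed = 2)
  expect_identical(r1, r2)
  with(r1$counts, expect_equal(TP + FP + TN + FN, 40))
  expect_error(kfold_cv(ds$windows, ds$labels, k = 25), "class size")
})

test_that("jackknife equals k-fold CV with k = n", {
  ds <- generate_dataset(synthetic_spec(n_pos = 12, n_neg = 10,
                                        separation = 0.8, seed = 31))
  jk <- jackknife(ds$windows, ds$labels, C = 8, gamma = 2)
  loo <- kfold_cv(ds$windows, ds$labels, C = 8, gamma = 2,
                  k = length(ds$labels), seed = 77)
  expect_identical(jk$counts, loo$counts)
  expect_equal(jk$Acc, loo$Acc)
})

test_that("the two-sample jackknife exposes the single-class training contract", {
  wins <- list(site_window(strrep("A", 51)),
               site_window(paste0(strrep("C", 25), "A", strrep("G", 25))))
  expect_error(jackknife(wins, c(1, -1), C = 1, gamma = 1), "both classes")
})

test_that("parameter sweep evaluates the full grid and breaks ties predictably", {
  ds <- generate_dataset(synthetic_spec(n_pos = 14, n_neg = 14,
                                        separation = 1, seed = 9))
  one <- parameter_sweep(ds$windows, ds$labels, w_values = 0.3,
                         lambda_values = 4, C = 8, gamma = 2, k = 2, seed = 1)
  expect_identical(nrow(one$grid), 1L)
  expect_equal(one$best_w, 0.3)
  expect_equal(one$best_lambda, 4L)

  sw <- parameter_sweep(ds$windows, ds$labels,
                        w_values = c(0, 0.5, 1), lambda_values = c(1, 3),
                        C = 8, gamma = 2, k = 2, seed = 1)
  expect_identical(nrow(sw$grid), 6L)
  expect_equal(sw$best_accuracy, max(sw$grid$accuracy))
  # tie-break: the best cell is the (lambda, w)-smallest among maxima
  maxima <- sw$grid[sw$grid$accuracy == sw$best_accuracy, ]
  first <- maxima[order(maxima$lambda, maxima$w)[1], ]
  expect_equal(sw$best_w, first$w)
  expect_equal(sw$best_lambda, first$lambda)
})

test_that("the default sweep ranges span the 110-cell grid", {
  ds <- generate_dataset(synthetic_spec(n_pos = 8, n_neg = 8,
                                        separation = 1, seed = 13,
                                        window_length = 15))
  sw <- parameter_sweep(ds$windows, ds$labels, C = 8, gamma = 2, k = 2, seed = 1)
  expect_identical(nrow(sw$grid), 110L)
  expect_identical(sort(unique(sw$grid$lambda)), 1:10)
  expect_equal(sort(unique(sw$grid$w)), seq(0, 1, by = 0.1))
})
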