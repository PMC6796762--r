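test_that("stratified folds balance both classes and are reproducible", {
  y <- rep(c(1L, 0L), each = 880)
  a <- stratified_kfold(y, k = 10, seed = 4)
  expect_setequal(unique(a), 1:10)
  for (f in 1:10) {
    expect_equal(sum(a == f & y == 1L), 88)
    expect_equal(sum(a == f & y == 0L), 88)
  }
  expect_identical(a, stratified_kfold(y, k = 10, seed = 4))
  expect_false(identical(a, stratified_kfold(y, k = 10, seed = 5)))

  # uneven sizes: per-fold class counts differ by at most one
  y2 <- c(rep(1L, 23), rep(0L, 31))
  a2 <- stratified_kfold(y2, k = 5, seed = 1)
  for (f in 1:5) {
    expect_lte(abs(sum(a2 == f & y2 == 1L) - 23 / 5), 1)
    expect_lte(abs(sum(a2 == f & y2 == 0L) - 31 / 5), 1)
  }
  expect_error(stratified_kfold(c(1L, 0L, 0L, 0L), k = 2), "fewer")
})

test_that("threshold metrics follow the confusion-count formulas", {
  perfect <- compute_metrics(c(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(perfect$ACC, 1)
  expect_equal(perfect$MCC, 1)

  m <- compute_metrics(c(TP = 8, TN = 9, FP = 1, FN = 2))
  expect_equal(m$SN, 0.8)
  expect_equal(m$SP, 0.9)
  expect_equal(m$ACC, 0.85)
  expect_equal(m$MCC, 70 / sqrt(9900), tolerance = 1e-12)
  expect_equal(m$MCC, 0.7035, tolerance = 1e-3)

  # everything predicted positive on a balanced set
  expect_warning(
    ap <- compute_metrics(c(TP = 10, TN = 0, FP = 10, FN = 0)),
    "MCC"
  )
  expect_equal(ap$SN, 1)
  expect_equal(ap$SP, 0)
  expect_equal(ap$ACC, 0.5)
  expect_equal(ap$MCC, 0)

  expect_error(compute_metrics(c(TP = 0, TN = 5, FP = 0, FN = 0)),
               "actual positive")
})

test_that("on balanced data accuracy is the mean of sensitivity and specificity", {
  set.seed(9)
  for (i in 1:20) {
    tp <- sample(0:50, 1); fn <- 50 - tp
    tn <- sample(0:50, 1); fp <- 50 - tn
    if (tp + fn == 0 || tn + fp == 0) next
    m <- suppressWarnings(compute_metrics(c(TP = tp, TN = tn, FP = fp,
                                            FN = fn)))
    expect_equal(m$ACC, (m$SN + m$SP) / 2)
  }
})

test_that("AUC equals the pairwise Mann-Whitney count, with tie-averaging", {
  y <- rep(c(1L, 0L), each = 20)
  expect_equal(roc_auc(c(rep(1, 20), rep(0, 20)), y)$auc, 1)

  set.seed(31)
  for (i in 1:10) {
    yy <- rbinom(60, 1, 0.5)
    if (length(unique(yy)) < 2) next
    ss <- round(runif(60), 2) # rounding forces ties
    expect_equal(roc_auc(ss, yy)$auc, oracle_auc(ss, yy), tolerance = 1e-12)
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")

  # label-independent scores sit at chance
  set.seed(77)
  y0 <- rep(c(1L, 0L), each = 1000)
  s0 <- runif(2000)
  expect_lt(abs(roc_auc(s0, y0)$auc - 0.5), 0.05)
})

test_that("AUC and ROC agree with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  y <- rep(c(1L, 0L), each = 50)
  s <- y * 0.8 + runif(100)
  ours <- roc_auc(s, y)
  theirs <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours$auc, theirs, tolerance = 1e-12)
  expect_equal(ours$roc$fpr[1], 0)
  expect_equal(ours$roc$tpr[nrow(ours$roc)], 1)
  expect_true(all(diff(ours$roc$fpr) >= 0))
  expect_true(all(diff(ours$roc$tpr) >= 0))
})

test_that("McNemar's test follows the discordant-pair chi-square", {
  y <- rep(1L, 20)
  a <- c(rep(1L, 10), rep(0L, 10))
  b <- rep(0L, 20)
  r <- mcnemar_test(a, b, y) # b = 10, c = 0
  expect_equal(r$statistic, 10)
  expect_equal(r$p_value, pchisq(10, 1, lower.tail = FALSE))
  expect_lt(abs(r$p_value - 0.00157), 1e-4)

  # symmetric in the two methods
  r2 <- mcnemar_test(b, a, y)
  expect_equal(r2$p_value, r$p_value)

  # b == c -> no evidence of difference
  y3 <- rep(c(1L, 0L), 10)
  a3 <- y3; a3[1] <- 1L - a3[1]
  b3 <- y3; b3[2] <- 1L - b3[2]
  r3 <- mcnemar_test(a3, b3, y3)
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p_value, 1)

  # a method against itself
  expect_equal(mcnemar_test(a, a, y)$p_value, 1)

  # exact variant matches the binomial closed form
  re <- mcnemar_test(a, b, y, exact = TRUE)
  expect_equal(re$p_value, binom.test(10, 10, 0.5)$p.value)
})

test_that("the robustness gap is a symmetric percentage-point difference", {
  r1 <- list(ACC = 0.88)
  r2 <- list(ACC = 0.885)
  expect_equal(delta_acc(r1, r2), 0.5)
  expect_equal(delta_acc(r2, r1), 0.5)
  expect_equal(delta_acc(r1, r1), 0)
})

test_that("pipeline cross-validation pools fold-internal predictions", {
  ds <- simulate_dataset(sim_config(n_pos = 45, n_neg = 45,
                                    motif_rate_pos = 1, motif_rate_neg = 0,
                                    seed = 19))
  cv <- cross_validate(ds, light_config(encodings = c("NUM", "MBE"),
                                        folds = 3, seed = 2), k = 3,
                       seed = 2, macro = TRUE)
  expect_equal(sum(cv$metrics$counts), nrow(ds))
  expect_length(cv$scores, nrow(ds))
  expect_setequal(unique(cv$fold), 1:3)
  expect_gte(cv$metrics$ACC, 0.8) # strong planted signal
  expect_false(is.na(cv$metrics$AUC))
  expect_true(is.numeric(cv$macro_acc))
})
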