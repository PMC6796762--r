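# Evaluation machinery: stratified folds, confusion-based metrics
# (SN/SP/ACC/MCC), rank-based AUC with ROC points, full-pipeline
# cross-validation, McNemar's test and the CV-vs-holdout robustness gap.

#' Stratified k-fold assignment
#'
#' Splits records into k folds so that per fold the positive and negative
#' counts each differ by at most one from n_pos/k and n_neg/k. The
#' assignment is a deterministic function of the seed.
#'
#' @param labels Binary labels (or an `m6a_dataset`).
#' @param k Number of folds.
#' @param seed Seed fixing the shuffle.
#' @return Integer fold id (1..k) per record.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  if (inherits(labels, "m6a_dataset")) labels <- labels$label
  labels <- as.integer(labels)
  k <- as.integer(k)
  if (anyNA(labels)) stop("labels contain NA", call. = FALSE)
  if (min(table(labels)) < k) {
    stop(sprintf("smallest class has fewer records than k = %d", k),
         call. = FALSE)
  }
  assign <- integer(length(labels))
  rng <- .seeded_rng(seed)
  for (cls in c(1L, 0L)) {
    idx <- which(labels == cls)
    idx <- rng$shuffle(idx)
    assign[idx] <- rep_len(seq_len(k), length(idx))
  }
  assign
}

# Local RNG helper: runs seeded draws without clobbering the caller's
# global RNG state.
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    s
  })
  run <- function(expr_fun) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    })
    expr_fun()
  }
  list(
    shuffle = function(x) run(function() sample(x)),
    runif = function(n) run(function() runif(n)),
    sample_int = function(n, size, replace = FALSE, prob = NULL) {
      run(function() sample.int(n, size, replace = replace, prob = prob))
    }
  )
}

#' Confusion counts from predictions and labels
#'
#' @param pred Predicted classes (0/1).
#' @param labels True classes (0/1).
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion_counts <- function(pred, labels) {
  pred <- as.integer(pred)
  labels <- as.integer(labels)
  stopifnot(length(pred) == length(labels))
  c(
    TP = sum(pred == 1L & labels == 1L),
    TN = sum(pred == 0L & labels == 0L),
    FP = sum(pred == 1L & labels == 0L),
    FN = sum(pred == 0L & labels == 1L)
  )
}

#' Threshold-based performance metrics
#'
#' Sensitivity SN = TP/(TP+FN), specificity SP = TN/(TN+FP), accuracy
#' ACC = (TP+TN)/N and the Matthews correlation coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FN)(TP+FP)(TN+FP)(TN+FN)}}.}
#' A zero MCC denominator yields MCC = 0 with a warning.
#'
#' @param counts Named vector with `TP`, `TN`, `FP`, `FN` (as from
#'   [confusion_counts()]).
#' @param auc Optional AUC to carry in the report.
#' @return An `m6a_metrics` object (list with `SN`, `SP`, `ACC`, `MCC`,
#'   `AUC`, `counts`).
#' @export
compute_metrics <- function(counts, auc = NA_real_) {
  tp <- as.numeric(counts[["TP"]])
  tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]])
  fn <- as.numeric(counts[["FN"]])
  if (tp + fn == 0 || tn + fp == 0) {
    stop("need at least one actual positive and one actual negative",
         call. = FALSE)
  }
  den <- sqrt((tp + fn) * (tp + fp) * (tn + fp) * (tn + fn))
  mcc <- if (den == 0) {
    warning("zero MCC denominator; MCC set to 0", call. = FALSE)
    0
  } else {
    (tp * tn - fp * fn) / den
  }
  structure(
    list(
      SN = tp / (tp + fn),
      SP = tn / (tn + fp),
      ACC = (tp + tn) / (tp + tn + fp + fn),
      MCC = mcc,
      AUC = auc,
      counts = c(TP = tp, TN = tn, FP = fp, FN = fn)
    ),
    class = "m6a_metrics"
  )
}

#' @export
print.m6a_metrics <- function(x, ...) {
  cat(sprintf(
    "m6a_metrics: ACC %.4f | MCC %.4f | SN %.4f | SP %.4f | AUC %s\n",
    x$ACC, x$MCC, x$SN, x$SP,
    if (is.na(x$AUC)) "NA" else sprintf("%.4f", x$AUC)
  ))
  cat(sprintf("  counts: TP %d TN %d FP %d FN %d\n",
              x$counts[["TP"]], x$counts[["TN"]], x$counts[["FP"]],
              x$counts[["FN"]]))
  invisible(x)
}

#' ROC curve and AUC
#'
#' AUC via the rank (Mann-Whitney) formulation with tie-averaging, which
#' equals trapezoidal integration of the ROC curve over all thresholds.
#'
#' @param scores Numeric scores, higher = more likely positive.
#' @param labels Binary labels.
#' @return List with `auc` and `roc` (data frame `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores) # average ranks on ties <-> Mann-Whitney convention
  auc <- (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(scores, decreasing = TRUE)
  tpr <- cumsum(labels[ord] == 1L) / np
  fpr <- cumsum(labels[ord] == 0L) / nn
  thr <- scores[ord]
  last <- !duplicated(thr, fromLast = TRUE) # one point per distinct score
  roc <- data.frame(
    threshold = c(Inf, thr[last]),
    fpr = c(0, fpr[last]),
    tpr = c(0, tpr[last])
  )
  list(auc = auc, roc = roc)
}

#' McNemar's test between two sets of predictions
#'
#' Chi-square statistic on the discordant counts b (A correct, B wrong) and
#' c (A wrong, B correct): (b - c)^2 / (b + c) on 1 df, without continuity
#' correction. When b + c = 0 the methods are indistinguishable and p = 1.
#' `exact = TRUE` switches to the two-sided exact binomial version,
#' recommended when b + c < 25.
#'
#' @param pred_a,pred_b Class predictions from the two methods.
#' @param labels True classes.
#' @param exact Use the exact binomial test on the discordant pairs?
#' @return List with `statistic`, `p_value`, `b`, `c`.
#' @export
mcnemar_test <- function(pred_a, pred_b, labels, exact = FALSE) {
  pred_a <- as.integer(pred_a)
  pred_b <- as.integer(pred_b)
  labels <- as.integer(labels)
  stopifnot(length(pred_a) == length(labels),
            length(pred_b) == length(labels))
  right_a <- pred_a == labels
  right_b <- pred_b == labels
  b <- sum(right_a & !right_b)
  cc <- sum(!right_a & right_b)
  if (b + cc == 0L) {
    return(list(statistic = 0, p_value = 1, b = b, c = cc))
  }
  if (exact) {
    p <- binom.test(b, b + cc, p = 0.5)$p.value
    return(list(statistic = NA_real_, p_value = p, b = b, c = cc))
  }
  stat <- (b - cc)^2 / (b + cc)
  list(statistic = stat, p_value = pchisq(stat, df = 1L, lower.tail = FALSE),
       b = b, c = cc)
}

#' Robustness gap between cross-validation and independent evaluation
#'
#' Absolute difference of the two accuracies, in percentage points.
#'
#' @param cv_report,independent_report `m6a_metrics` objects (or anything
#'   with an `ACC` element).
#' @return Non-negative scalar, percentage points.
#' @export
delta_acc <- function(cv_report, independent_report) {
  abs(cv_report$ACC - independent_report$ACC) * 100
}

#' Cross-validate the full pipeline
#'
#' Outer stratified k-fold CV in which each fold's model is trained from
#' scratch on the remaining folds ([train_ensemble()]), so KNN references,
#' feature subsets, hyperparameters and layer-1 weights are all
#' fold-internal; out-of-fold scores are pooled into a single confusion
#' table (micro-averaging, the default for MCC stability) with AUC from the
#' pooled scores. `macro = TRUE` additionally reports the mean of per-fold
#' accuracies. `k = nrow(ds)` would be the jackknife; in practice use
#' moderate k.
#'
#' @param ds Labeled `m6a_dataset`.
#' @param config A [run_config()].
#' @param k Outer folds.
#' @param seed Seed for the outer fold assignment.
#' @param macro Also compute macro-averaged accuracy?
#' @return List with `metrics` (`m6a_metrics`), `scores`, `predicted`,
#'   `fold`, and optionally `macro_acc`.
#' @export
cross_validate <- function(ds, config = run_config(), k = config$folds,
                           seed = config$seed, macro = FALSE) {
  labels <- ds$label
  assign <- stratified_kfold(labels, k = k, seed = seed)
  scores <- numeric(nrow(ds))
  for (f in seq_len(k)) {
    tr <- assign != f
    fit <- tryCatch(
      train_ensemble(ds[tr, ], config),
      error = function(e) {
        stop(sprintf("fold %d: %s", f, conditionMessage(e)), call. = FALSE)
      }
    )
    pred <- predict(fit, ds[!tr, ])
    scores[!tr] <- pred$probability
  }
  predicted <- classify(scores, config$threshold)
  metrics <- compute_metrics(confusion_counts(predicted, labels),
                             auc = roc_auc(scores, labels)$auc)
  out <- list(metrics = metrics, scores = scores, predicted = predicted,
              fold = assign)
  if (macro) {
    out$macro_acc <- mean(vapply(seq_len(k), function(f) {
      mean(predicted[assign == f] == labels[assign == f])
    }, numeric(1L)))
  }
  out
}
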