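# Base classifiers behind a common surface: SVM (RBF kernel, e1071/libsvm)
# and extremely randomized trees (ranger with splitrule "extratrees", no
# bagging, one random split per candidate feature). RF and XGB are optional
# plug-ins with library-default settings. Hyperparameters are chosen by
# exhaustive grid search under stratified CV accuracy.

#' Hyperparameter grids for the base classifiers
#'
#' The full SVM grid spans cost C in 2^-5..2^15 (exponent step 2) and RBF
#' gamma in 2^-15..2^-5 (exponent step 1), an 11 x 11 grid. The full ERT
#' grid spans ntree 50..2000 (step 25), mtry 1..15 and nsplit (minimum
#' samples to split a node) 1..12. `reduced = TRUE` gives coarse subsets of
#' the same ranges (5 x 5 for SVM) suitable for routine runs; the full grids
#' are exhaustive and correspondingly slow. RF and XGB have single-row
#' grids at library defaults and are flagged experimental.
#'
#' @param kind `"SVM"`, `"ERT"`, `"RF"` or `"XGB"`.
#' @param reduced Use the coarse sub-grid?
#' @return A data frame, one row per hyperparameter combination.
#' @export
default_param_grid <- function(kind = c("SVM", "ERT", "RF", "XGB"),
                               reduced = TRUE) {
  kind <- match.arg(kind)
  switch(kind,
    SVM = if (reduced) {
      expand.grid(cost = 2^c(-5, 0, 5, 10, 15),
                  gamma = 2^c(-15, -13, -10, -8, -5))
    } else {
      expand.grid(cost = 2^seq(-5, 15, by = 2),
                  gamma = 2^seq(-15, -5, by = 1))
    },
    ERT = if (reduced) {
      expand.grid(ntree = c(100, 300), mtry = c(3, 8), nsplit = c(2, 8))
    } else {
      expand.grid(ntree = seq(50, 2000, by = 25), mtry = 1:15, nsplit = 1:12)
    },
    RF = data.frame(ntree = 500, mtry = NA_real_, nsplit = 1),
    XGB = data.frame(nrounds = 100, eta = 0.3, max_depth = 6)
  )
}

#' Declare a classifier and its search grid
#'
#' @param kind Classifier family.
#' @param param_grid Data frame of hyperparameter combinations searched by
#'   [tune_and_fit()]; defaults to [default_param_grid()] (reduced).
#' @param seed Seed used for fold assignment and tree randomization.
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(kind = c("SVM", "ERT", "RF", "XGB"),
                            param_grid = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(param_grid)) param_grid <- default_param_grid(kind)
  structure(
    list(kind = kind, param_grid = param_grid, seed = as.integer(seed)),
    class = "classifier_spec"
  )
}

# Platt sigmoid calibration: p = 1 / (1 + exp(A f + B)) fitted on decision
# values with the regularized targets of Platt (1999). Deterministic.
.platt_fit <- function(dv, y) {
  np <- sum(y == 1L)
  nn <- sum(y == 0L)
  tt <- ifelse(y == 1L, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    p <- 1 / (1 + exp(par[1L] * dv + par[2L]))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(tt * log(p) + (1 - tt) * log(1 - p))
  }
  opt <- optim(c(0, log((nn + 1) / (np + 1))), nll, method = "BFGS")
  opt$par
}

.platt_predict <- function(par, dv) {
  1 / (1 + exp(par[1L] * dv + par[2L]))
}

# Min-max scaling fitted on training data (SVM inputs only; tree models are
# scale-free). Constant columns map to 0.
.minmax_fit <- function(x) {
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  list(lo = lo, span = pmax(hi - lo, .Machine$double.eps))
}

.minmax_apply <- function(sc, x) {
  sweep(sweep(x, 2L, sc$lo, "-"), 2L, sc$span, "/")
}

# Fit one classifier with fixed hyperparameters; returns an object usable by
# .predict_single(). `params` is a single-row data frame.
.fit_single <- function(kind, params, x, y, seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("training data contains a single class", call. = FALSE)
  }
  x <- as.matrix(x)
  obj <- list(kind = kind, params = params, dim = ncol(x))
  if (kind == "SVM") {
    sc <- .minmax_fit(x)
    xs <- .minmax_apply(sc, x)
    fit <- e1071::svm(
      x = xs, y = factor(y, levels = c(0L, 1L)),
      kernel = "radial", cost = params$cost, gamma = params$gamma,
      scale = FALSE
    )
    dv <- drop(attr(predict(fit, xs, decision.values = TRUE),
                    "decision.values"))
    flip <- if (mean(dv[y == 1L]) < mean(dv[y == 0L])) -1 else 1
    obj$scaling <- sc
    obj$fit <- fit
    obj$flip <- flip
    obj$platt <- .platt_fit(flip * dv, y)
  } else if (kind %in% c("ERT", "RF")) {
    mtry <- params$mtry
    if (is.na(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
    mtry <- min(as.integer(mtry), ncol(x))
    args <- list(
      x = as.data.frame(x), y = factor(y, levels = c(0L, 1L)),
      num.trees = params$ntree, mtry = mtry,
      min.node.size = params$nsplit, probability = TRUE,
      seed = seed, num.threads = 1L, verbose = FALSE
    )
    if (kind == "ERT") {
      args$splitrule <- "extratrees"
      args$num.random.splits <- 1L
      args$replace <- FALSE
      args$sample.fraction <- 1
    }
    obj$fit <- do.call(ranger::ranger, args)
  } else if (kind == "XGB") {
    if (!requireNamespace("xgboost", quietly = TRUE)) {
      stop("the XGB learner requires the xgboost package", call. = FALSE)
    }
    obj$fit <- xgboost::xgboost(
      data = x, label = y, nrounds = params$nrounds,
      params = list(objective = "binary:logistic", eta = params$eta,
                    max_depth = params$max_depth, nthread = 1L,
                    seed = seed),
      verbose = 0
    )
  } else {
    stop("unknown classifier kind: ", kind, call. = FALSE)
  }
  obj
}

.predict_single <- function(obj, x) {
  x <- as.matrix(x)
  if (ncol(x) != obj$dim) {
    stop(sprintf("feature matrix has %d columns, model expects %d",
                 ncol(x), obj$dim), call. = FALSE)
  }
  if (obj$kind == "SVM") {
    xs <- .minmax_apply(obj$scaling, x)
    dv <- drop(attr(predict(obj$fit, xs, decision.values = TRUE),
                    "decision.values"))
    .platt_predict(obj$platt, obj$flip * dv)
  } else if (obj$kind %in% c("ERT", "RF")) {
    predict(obj$fit, data = as.data.frame(x),
            num.threads = 1L)$predictions[, "1"]
  } else {
    predict(obj$fit, x)
  }
}

# Mean out-of-fold accuracy of one hyperparameter combination under a fixed
# fold assignment.
.cv_accuracy <- function(kind, params, x, y, assign, seed = 1L,
                         threshold = 0.5) {
  pred <- numeric(length(y))
  for (f in sort(unique(assign))) {
    tr <- assign != f
    m <- .fit_single(kind, params, x[tr, , drop = FALSE], y[tr], seed = seed)
    pred[!tr] <- .predict_single(m, x[!tr, , drop = FALSE])
  }
  mean(as.integer(pred >= threshold) == y)
}

#' Grid-search hyperparameters and fit a single-encoding model
#'
#' Every row of the classifier spec's grid is scored by stratified k-fold
#' CV accuracy (fold assignment fixed by its seed, shared across the grid);
#' the
#' winning combination (first row on ties, in grid order) is refitted on all
#' data. SVM inputs are min-max scaled with parameters learned from the
#' training data; probabilities come from a Platt sigmoid fitted on the
#' training decision values. Tree models are used unscaled.
#'
#' @param spec A [classifier_spec()].
#' @param mat Feature matrix from [encode_dataset()].
#' @param labels Binary labels aligned with the rows.
#' @param folds CV folds used during tuning.
#' @param fold_assign Optional precomputed fold assignment (overrides
#'   `folds`).
#' @return An `m6a_model`: the fitted classifier plus the winning
#'   hyperparameters, encoding tag and grid CV accuracies.
#' @export
tune_and_fit <- function(spec, mat, labels, folds = 10L, fold_assign = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("labels contain a single class", call. = FALSE)
  }
  if (!all(is.finite(mat))) stop("feature matrix must be finite", call. = FALSE)
  if (is.null(fold_assign)) {
    fold_assign <- stratified_kfold(labels, k = folds, seed = spec$seed)
  }
  grid <- spec$param_grid
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    .cv_accuracy(spec$kind, grid[i, , drop = FALSE], mat, labels,
                 fold_assign, seed = spec$seed)
  }, numeric(1L))
  best <- which.max(acc) # first max: deterministic tie-break in grid order
  structure(
    list(
      kind = spec$kind,
      spec = spec,
      params = grid[best, , drop = FALSE],
      grid_accuracy = data.frame(grid, accuracy = acc),
      encoding = attr(mat, "encoding"),
      selected = seq_len(ncol(mat)),
      dim = ncol(mat),
      model = .fit_single(spec$kind, grid[best, , drop = FALSE], mat, labels,
                          seed = spec$seed)
    ),
    class = "m6a_model"
  )
}

#' @export
print.m6a_model <- function(x, ...) {
  cat(sprintf("m6a_model: %s on %s (%d features)\n", x$kind,
              x$encoding %||% "?", x$dim))
  cat("  params:", paste(names(x$params), signif(unlist(x$params), 4),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict class probabilities from a fitted single-encoding model
#'
#' @param model An `m6a_model` from [tune_and_fit()].
#' @param mat Feature matrix with the model's encoding and feature subset.
#' @return Probabilities of the positive (6mA) class, one per row.
#' @export
predict_probability <- function(model, mat) {
  stopifnot(inherits(model, "m6a_model"))
  enc <- attr(mat, "encoding")
  if (!is.null(enc) && !is.null(model$encoding) && enc != model$encoding) {
    stop(sprintf("matrix encoding %s does not match model encoding %s",
                 enc, model$encoding), call. = FALSE)
  }
  if (ncol(mat) != model$dim) {
    stop(sprintf("expected %d features for encoding %s, got %d",
                 model$dim, model$encoding %||% "?", ncol(mat)),
         call. = FALSE)
  }
  .predict_single(model$model, mat)
}
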