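# End-to-end training and prediction: encode -> (optional) F-score + SFS
# per encoding -> tuned per-encoding models per classifier -> layer-1
# weight search on out-of-fold probabilities -> layer-2 average.

#' Pipeline configuration
#'
#' The defaults reproduce the selected architecture: five encodings (NUM,
#' MBE, DBE_LPF, RFHC, KNN), SVM + ERT classifiers, 10 stratified folds,
#' layer-1 weight grid step 0.1 and decision threshold 0.5. KNN is always
#' exempt from feature optimization (7 features). `sfs_step` strides the
#' SFS accuracy curve (1 = evaluate every prefix size); `reduced_grids`
#' selects the coarse hyperparameter grids (see [default_param_grid()]).
#'
#' @param encodings Encodings to use (subset of the registry).
#' @param classifiers Classifier families combined in layer 2.
#' @param folds Stratified CV folds used for tuning, SFS and the
#'   out-of-fold probabilities behind the weight search.
#' @param seed Master seed; all pipeline randomness derives from it.
#' @param grid_step Layer-1 simplex grid resolution.
#' @param threshold Decision threshold on the final score.
#' @param sfs Run F-score ranking + sequential forward search?
#' @param sfs_step Prefix stride during SFS.
#' @param reduced_grids Use the coarse hyperparameter grids?
#' @param param_grids Optional named list (`SVM = ..., ERT = ...`) of grids
#'   overriding the defaults.
#' @return An `m6a_config` object.
#' @export
run_config <- function(encodings = c("NUM", "MBE", "DBE_LPF", "RFHC", "KNN"),
                       classifiers = c("SVM", "ERT"),
                       folds = 10L, seed = 1L, grid_step = 0.1,
                       threshold = 0.5, sfs = TRUE, sfs_step = 1L,
                       reduced_grids = TRUE, param_grids = NULL) {
  encodings <- match.arg(toupper(encodings), ENCODINGS, several.ok = TRUE)
  classifiers <- match.arg(toupper(classifiers),
                           c("SVM", "ERT", "RF", "XGB"), several.ok = TRUE)
  grids <- lapply(stats::setNames(nm = classifiers), function(cl) {
    if (!is.null(param_grids[[cl]])) {
      param_grids[[cl]]
    } else {
      default_param_grid(cl, reduced = reduced_grids)
    }
  })
  structure(
    list(
      encodings = encodings, classifiers = classifiers,
      folds = as.integer(folds), seed = as.integer(seed),
      grid_step = grid_step, threshold = threshold,
      sfs = isTRUE(sfs), sfs_step = as.integer(sfs_step),
      param_grids = grids
    ),
    class = "m6a_config"
  )
}

#' @export
print.m6a_config <- function(x, ...) {
  cat("m6a_config:\n")
  cat("  encodings:  ", paste(x$encodings, collapse = ", "), "\n")
  cat("  classifiers:", paste(x$classifiers, collapse = ", "), "\n")
  cat(sprintf("  folds %d | seed %d | grid_step %g | threshold %g | sfs %s (step %d)\n",
              x$folds, x$seed, x$grid_step, x$threshold, x$sfs, x$sfs_step))
  invisible(x)
}

#' Train the two-layer ensemble
#'
#' For every classifier and encoding: hyperparameters are grid-searched
#' once on the full feature set, then frozen; for the non-KNN encodings an
#' F-score ranking plus sequential forward search picks the feature subset.
#' Out-of-fold probabilities (same stratified split throughout; per-fold
#' refits with fold-internal KNN references and self-exclusion) feed the
#' layer-1 weight search, and the per-classifier out-of-fold ensemble
#' scores are averaged for the training-time summary. The returned model
#' carries everything needed for prediction: fitted models, selected
#' feature indices, scaling and calibration parameters, weights and the
#' full-data KNN reference.
#'
#' @param ds Labeled `m6a_dataset` with both classes present.
#' @param config An [run_config()].
#' @return An `m6a_ensemble` object.
#' @export
train_ensemble <- function(ds, config = run_config()) {
  stopifnot(inherits(ds, "m6a_dataset"))
  labels <- ds$label
  if (anyNA(labels)) stop("training data must be fully labeled", call. = FALSE)
  if (n_pos(ds) < config$folds || n_neg(ds) < config$folds) {
    stop("each class needs at least `folds` records", call. = FALSE)
  }
  assign <- stratified_kfold(labels, k = config$folds, seed = config$seed)

  knn_ref <- NULL
  if ("KNN" %in% config$encodings) knn_ref <- build_knn_reference(ds)
  feats <- lapply(stats::setNames(nm = config$encodings), function(enc) {
    encode_dataset(ds, enc, knn_ref = knn_ref, exclude_self = TRUE)
  })

  classifiers <- list()
  oof_layer1 <- list()
  for (cl in config$classifiers) {
    spec <- classifier_spec(cl, config$param_grids[[cl]], seed = config$seed)
    models <- list()
    selected <- list()
    oof <- matrix(NA_real_, nrow(ds), length(config$encodings),
                  dimnames = list(NULL, config$encodings))
    for (enc in config$encodings) {
      mat <- feats[[enc]]
      tuned <- tune_and_fit(spec, mat, labels, fold_assign = assign)
      if (config$sfs && enc != "KNN") {
        ranked <- rank_features(mat, labels)
        sfs <- sequential_forward_search(
          mat, labels, ranked, spec,
          folds = config$folds, seed = config$seed,
          step = config$sfs_step, params = tuned$params
        )
        sel <- sort(sfs$selected)
      } else {
        sel <- seq_len(ncol(mat))
      }
      # out-of-fold probabilities, strictly fold-internal
      for (f in seq_len(config$folds)) {
        tr <- assign != f
        if (enc == "KNN") {
          ref_f <- build_knn_reference(ds[tr, ])
          xtr <- encode_dataset(ds[tr, ], "KNN", ref_f, exclude_self = TRUE)
          xte <- encode_dataset(ds[!tr, ], "KNN", ref_f,
                                exclude_self = FALSE)
        } else {
          xtr <- mat[tr, sel, drop = FALSE]
          xte <- mat[!tr, sel, drop = FALSE]
        }
        m <- .fit_single(cl, tuned$params, xtr, labels[tr],
                         seed = config$seed)
        oof[!tr, enc] <- .predict_single(m, xte)
      }
      final <- tuned
      final$selected <- sel
      final$dim <- length(sel)
      final$model <- .fit_single(cl, tuned$params, mat[, sel, drop = FALSE],
                                 labels, seed = config$seed)
      models[[enc]] <- final
      selected[[enc]] <- sel
    }
    w <- optimize_layer1_weights(oof, labels, grid_step = config$grid_step,
                                 threshold = config$threshold)
    classifiers[[cl]] <- list(models = models, selected = selected,
                              weights = w, oof = oof)
    oof_layer1[[cl]] <- layer1_combine(oof, w)
  }

  oof_final <- layer2_combine(oof_layer1)
  training <- compute_metrics(
    confusion_counts(classify(oof_final, config$threshold), labels),
    auc = roc_auc(oof_final, labels)$auc
  )

  structure(
    list(
      config = config,
      classifiers = classifiers,
      knn_ref = knn_ref,
      threshold = config$threshold,
      n_train = nrow(ds),
      oof_score = oof_final,
      training_metrics = training,
      version = as.character(utils::packageVersion("sixma"))
    ),
    class = "m6a_ensemble"
  )
}

#' @export
print.m6a_ensemble <- function(x, ...) {
  cat(sprintf(
    "m6a_ensemble: %s over %s (n = %d, threshold %g)\n",
    paste(x$config$classifiers, collapse = " + "),
    paste(x$config$encodings, collapse = ", "),
    x$n_train, x$threshold
  ))
  for (cl in names(x$classifiers)) {
    w <- x$classifiers[[cl]]$weights$w
    cat(sprintf("  %s weights: %s\n", cl,
                paste(names(w), format(w), sep = "=", collapse = ", ")))
  }
  cat("  out-of-fold "); print(x$training_metrics)
  invisible(x)
}

#' Predict 6mA probabilities for new windows
#'
#' @param object A trained `m6a_ensemble`.
#' @param newdata An `m6a_dataset`, a character vector of 41-nt windows, or
#'   a single longer sequence to scan via [extract_adenine_windows()]
#'   (`scan = TRUE`).
#' @param explain Add per-classifier and per-encoding component scores?
#' @param threshold Decision threshold (defaults to the trained one).
#' @param scan Treat a single input string as a sequence to scan rather
#'   than a window.
#' @param ... Unused.
#' @return Data frame with `id`, `position`, `probability`,
#'   `predicted_class` (plus component columns when `explain = TRUE`).
#' @export
predict.m6a_ensemble <- function(object, newdata, explain = FALSE,
                                 threshold = object$threshold,
                                 scan = FALSE, ...) {
  if (is.character(newdata)) {
    newdata <- if (scan && length(newdata) == 1L) {
      extract_adenine_windows(newdata)
    } else {
      as_dataset(newdata)
    }
  }
  stopifnot(inherits(newdata, "m6a_dataset"))
  if (nrow(newdata) == 0L) {
    return(data.frame(id = character(0L), position = integer(0L),
                      probability = numeric(0L),
                      predicted_class = integer(0L)))
  }
  cfg <- object$config
  feats <- lapply(stats::setNames(nm = cfg$encodings), function(enc) {
    encode_dataset(newdata, enc, knn_ref = object$knn_ref,
                   exclude_self = FALSE)
  })
  per_cl <- list()
  components <- list()
  for (cl in names(object$classifiers)) {
    slot <- object$classifiers[[cl]]
    probs <- vapply(cfg$encodings, function(enc) {
      x <- feats[[enc]][, slot$selected[[enc]], drop = FALSE]
      .predict_single(slot$models[[enc]]$model, x)
    }, numeric(nrow(newdata)))
    probs <- matrix(probs, nrow = nrow(newdata),
                    dimnames = list(NULL, cfg$encodings))
    per_cl[[cl]] <- layer1_combine(probs, slot$weights)
    if (explain) {
      colnames(probs) <- paste0(cl, "_", cfg$encodings)
      components[[cl]] <- probs
    }
  }
  final <- layer2_combine(per_cl)
  out <- data.frame(
    id = newdata$id,
    position = newdata$source_pos,
    probability = final,
    predicted_class = classify(final, threshold)
  )
  if (explain) {
    for (cl in names(per_cl)) out[[paste0("score_", cl)]] <- per_cl[[cl]]
    out <- cbind(out, do.call(cbind, unname(lapply(components,
                                                   as.data.frame))))
  }
  out
}

#' Evaluate a trained ensemble on a labeled dataset
#'
#' @param object A trained `m6a_ensemble`.
#' @param ds Labeled `m6a_dataset`.
#' @param threshold Decision threshold.
#' @return An `m6a_metrics` report.
#' @export
evaluate_ensemble <- function(object, ds, threshold = object$threshold) {
  stopifnot(!anyNA(ds$label))
  pred <- predict(object, ds, threshold = threshold)
  compute_metrics(
    confusion_counts(pred$predicted_class, ds$label),
    auc = roc_auc(pred$probability, ds$label)$auc
  )
}

#' Persist / restore a trained ensemble
#'
#' The archive is a single RDS file containing the full model object
#' (fitted classifiers, feature subsets, scaling and calibration
#' parameters, weights, KNN reference, configuration and package version).
#'
#' @param object A trained `m6a_ensemble`.
#' @param path Archive path.
#' @return `path` (save) or the restored `m6a_ensemble` (load).
#' @export
save_ensemble <- function(object, path) {
  stopifnot(inherits(object, "m6a_ensemble"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, "m6a_ensemble")) {
    stop("not an m6a_ensemble archive: ", path, call. = FALSE)
  }
  object
}

#' Write predictions as TSV
#'
#' @param pred Data frame from [predict.m6a_ensemble()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  utils::write.table(pred, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
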