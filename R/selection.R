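# Two-step feature optimization: univariate F-score ranking followed by a
# classifier-in-the-loop sequential forward search over prefixes of the
# ranked list.

#' F-score of one feature
#'
#' Ratio of the squared deviations of the class means from the overall mean
#' to the sum of the within-class sample variances:
#' \deqn{F(i) = \frac{(\bar{x}^{+}_i - \bar{x}_i)^2 + (\bar{x}^{-}_i -
#'   \bar{x}_i)^2}{s^{2,+}_i + s^{2,-}_i}}
#' where the variances use the 1/(n-1) convention. This is the univariate
#' selection statistic, not the F1 classification metric. It is invariant
#' under affine transforms of the feature and zero when the class means
#' coincide.
#'
#' @param x Numeric feature values, one per record.
#' @param labels Binary labels (1/0) aligned with `x`.
#' @return Non-negative scalar; 0 (with a warning) when the feature is
#'   constant within both classes.
#' @examples
#' f_score(c(0.9, 1.1, -0.1, 0.1), c(1, 1, 0, 0)) # 12.5
#' @export
f_score <- function(x, labels) {
  labels <- as.integer(labels)
  xp <- x[labels == 1L]
  xn <- x[labels == 0L]
  if (length(xp) < 2L || length(xn) < 2L) {
    stop("each class needs >= 2 records", call. = FALSE)
  }
  den <- var(xp) + var(xn)
  if (den == 0) {
    warning("constant feature within both classes; F-score set to 0",
            call. = FALSE)
    return(0)
  }
  m <- mean(x)
  ((mean(xp) - m)^2 + (mean(xn) - m)^2) / den
}

#' Rank all features of a matrix by F-score
#'
#' Columns are scored with [f_score()] and sorted in stable descending
#' order (ties keep column order).
#'
#' @param mat Feature matrix (rows = records).
#' @param labels Binary labels aligned with the rows.
#' @return A `ranked_features` object: list with `order` (column indices,
#'   best first) and `scores` (per original column).
#' @export
rank_features <- function(mat, labels) {
  labels <- as.integer(labels)
  p <- labels == 1L
  n <- labels == 0L
  if (sum(p) < 2L || sum(n) < 2L) {
    stop("each class needs >= 2 records", call. = FALSE)
  }
  mp <- colMeans(mat[p, , drop = FALSE])
  mn <- colMeans(mat[n, , drop = FALSE])
  m <- colMeans(mat)
  vp <- apply(mat[p, , drop = FALSE], 2L, var)
  vn <- apply(mat[n, , drop = FALSE], 2L, var)
  den <- vp + vn
  scores <- ((mp - m)^2 + (mn - m)^2) / den
  if (any(den == 0)) {
    warning(sum(den == 0), " constant feature(s); F-score set to 0",
            call. = FALSE)
    scores[den == 0] <- 0
  }
  structure(
    list(order = order(-scores, seq_along(scores)), scores = unname(scores)),
    class = "ranked_features"
  )
}

#' Sequential forward search over a ranked feature list
#'
#' Starting from the two best-ranked features, prefixes of the ranked list
#' are grown (`step` features at a time; the full dimension is always
#' evaluated) and each prefix is scored by stratified k-fold CV accuracy of
#' the given classifier with frozen hyperparameters. The accuracy-maximizing
#' prefix is returned; equal-accuracy ties go to the smallest prefix
#' (parsimony). Folds are fixed by `seed` and shared across prefix sizes so
#' the accuracy curve is comparable along its length.
#'
#' @param mat Feature matrix.
#' @param labels Binary labels.
#' @param ranked A [rank_features()] result covering all columns of `mat`.
#' @param spec A [classifier_spec()]; its grid must be a single row, or
#'   `params` must supply the frozen hyperparameters.
#' @param folds Number of CV folds.
#' @param seed Seed fixing the fold assignment.
#' @param step Prefix growth in features per evaluation (1 reproduces the
#'   per-dimension accuracy curve; larger values stride the curve).
#' @param params Optional single-row data frame of frozen hyperparameters.
#' @return An `sfs_result`: list with `selected` (column indices), `k`,
#'   and `curve` (data frame of prefix size and CV accuracy).
#' @export
sequential_forward_search <- function(mat, labels, ranked, spec,
                                      folds = 10L, seed = 1L, step = 1L,
                                      params = NULL) {
  if (length(ranked$order) != ncol(mat)) {
    stop("ranking does not cover all columns", call. = FALSE)
  }
  if (is.null(params)) {
    if (nrow(spec$param_grid) != 1L) {
      stop("spec grid has several rows; pass frozen `params`", call. = FALSE)
    }
    params <- spec$param_grid
  }
  labels <- as.integer(labels)
  D <- ncol(mat)
  sizes <- unique(c(seq(2L, D, by = as.integer(step)), D))
  assign <- stratified_kfold(labels, k = folds, seed = seed)
  acc <- vapply(sizes, function(k) {
    cols <- ranked$order[seq_len(k)]
    tryCatch(
      .cv_accuracy(spec$kind, params, mat[, cols, drop = FALSE], labels,
                   assign, seed = spec$seed),
      error = function(e) {
        stop(sprintf("classifier failed at prefix size %d: %s", k,
                     conditionMessage(e)), call. = FALSE)
      }
    )
  }, numeric(1L))
  best <- sizes[which.max(acc)] # which.max -> first max -> smallest prefix
  structure(
    list(
      selected = ranked$order[seq_len(best)],
      k = best,
      curve = data.frame(size = sizes, accuracy = acc)
    ),
    class = "sfs_result"
  )
}

#' @export
print.sfs_result <- function(x, ...) {
  cat(sprintf("sfs_result: %d features selected (CV accuracy %.4f)\n",
              x$k, max(x$curve$accuracy)))
  invisible(x)
}
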