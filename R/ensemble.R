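# Two-layer ensemble. Layer 1: within each classifier, the five
# per-encoding probability streams are combined as a weighted sum with
# non-negative weights summing to one, found by exhaustive search over a
# simplex grid. Layer 2: the per-classifier ensemble scores are averaged
# with equal weights and thresholded at 0.5.

#' Enumerate the layer-1 weight grid
#'
#' All m-tuples of non-negative multiples of `grid_step` summing to exactly
#' 1, in lexicographic order (ascending in the first weight, then the
#' second, ...). With 5 streams and step 0.1 this is 1001 points.
#'
#' @param m Number of probability streams.
#' @param grid_step Grid resolution (1/grid_step must be a whole number).
#' @return Matrix with one weight vector per row.
#' @export
weight_grid <- function(m = 5L, grid_step = 0.1) {
  total <- round(1 / grid_step)
  if (abs(total - 1 / grid_step) > 1e-9) {
    stop("1/grid_step must be a whole number", call. = FALSE)
  }
  rec <- function(parts, left) {
    if (parts == 1L) return(matrix(left, ncol = 1L))
    out <- lapply(0:left, function(v) cbind(v, rec(parts - 1L, left - v)))
    do.call(rbind, out)
  }
  w <- rec(as.integer(m), total) * grid_step
  dimnames(w) <- NULL
  w
}

.as_prob_matrix <- function(probs) {
  if (is.list(probs) && !is.data.frame(probs)) {
    len <- vapply(probs, length, integer(1L))
    if (length(unique(len)) != 1L) {
      stop("probability streams have different lengths", call. = FALSE)
    }
    probs <- do.call(cbind, probs)
  }
  as.matrix(probs)
}

#' Layer-1 weighted combination of probability streams
#'
#' @param probs Matrix (rows = records, columns = streams) or list of
#'   equal-length probability vectors.
#' @param w Weight vector (or `layer1_weights` object) matching the number
#'   of streams.
#' @return Combined probability per record.
#' @export
layer1_combine <- function(probs, w) {
  P <- .as_prob_matrix(probs)
  if (inherits(w, "layer1_weights")) w <- w$w
  if (length(w) != ncol(P)) {
    stop(sprintf("%d weights for %d streams", length(w), ncol(P)),
         call. = FALSE)
  }
  drop(P %*% w)
}

#' Grid-search the layer-1 weights
#'
#' Exhaustively scores every simplex grid point by classification accuracy
#' of the weighted sum at the given threshold and returns the best; ties go
#' to the first point in lexicographic order. To avoid optimistic weights,
#' feed out-of-fold probabilities, never resubstitution ones.
#'
#' @inheritParams layer1_combine
#' @param labels Binary labels aligned with the rows.
#' @param grid_step Simplex grid resolution.
#' @param threshold Decision threshold used while scoring.
#' @return A `layer1_weights` object: weights `w` (named by stream),
#'   `grid_step` and the achieved `accuracy`.
#' @export
optimize_layer1_weights <- function(probs, labels, grid_step = 0.1,
                                    threshold = 0.5) {
  P <- .as_prob_matrix(probs)
  labels <- as.integer(labels)
  stopifnot(nrow(P) == length(labels))
  W <- weight_grid(ncol(P), grid_step)
  scores <- P %*% t(W)
  acc <- colMeans((scores >= threshold) == (labels == 1L))
  best <- which.max(acc) # first max = lexicographically first tie
  w <- W[best, ]
  names(w) <- colnames(P)
  structure(
    list(w = w, grid_step = grid_step, accuracy = acc[best]),
    class = "layer1_weights"
  )
}

#' @export
print.layer1_weights <- function(x, ...) {
  cat("layer1_weights:", paste(names(x$w) %||% seq_along(x$w),
                               format(x$w), sep = "=", collapse = ", "),
      sprintf("(accuracy %.4f)\n", x$accuracy))
  invisible(x)
}

#' Layer-2 combination: equal-weight average across classifiers
#'
#' @param scores Matrix or list of per-classifier combined probabilities.
#' @return Final probability per record.
#' @export
layer2_combine <- function(scores) {
  S <- .as_prob_matrix(scores)
  rowMeans(S)
}

#' Threshold probabilities into class calls
#'
#' A score exactly equal to the threshold is called positive (documented
#' boundary convention).
#'
#' @param final_probs Probabilities in \[0, 1\].
#' @param threshold Decision cut-off, default 0.5.
#' @return Integer vector of 0/1 calls.
#' @export
classify <- function(final_probs, threshold = 0.5) {
  stopifnot(all(final_probs >= 0 & final_probs <= 1))
  as.integer(final_probs >= threshold)
}
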