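# Shared fixtures and independent oracles. Oracles are deliberately naive
# (per-element loops, brute-force enumeration) and never reuse the code
# paths they check.

random_window <- function(seed) {
  set.seed(seed)
  ch <- sample(c("A", "C", "G", "T"), 41, replace = TRUE)
  ch[21] <- "A"
  paste(ch, collapse = "")
}

random_windows <- function(n, seed) {
  vapply(seq_len(n), function(i) random_window(seed * 1000 + i),
         character(1))
}

# Two well-separated Gaussian blobs as a feature matrix.
make_blobs <- function(n_per_class = 50, d = 2, sep = 4, seed = 1,
                       encoding = "NUM") {
  set.seed(seed)
  x <- rbind(
    matrix(rnorm(n_per_class * d, mean = sep / 2), ncol = d),
    matrix(rnorm(n_per_class * d, mean = -sep / 2), ncol = d)
  )
  colnames(x) <- paste0("f", seq_len(d))
  attr(x, "encoding") <- encoding
  list(x = x, y = rep(c(1L, 0L), each = n_per_class))
}

# Naive two-pass F-score oracle.
oracle_fscore <- function(x, labels) {
  xp <- x[labels == 1]
  xn <- x[labels == 0]
  m <- mean(x); mp <- mean(xp); mn <- mean(xn)
  sp <- sum((xp - mp)^2) / (length(xp) - 1)
  sn <- sum((xn - mn)^2) / (length(xn) - 1)
  ((mp - m)^2 + (mn - m)^2) / (sp + sn)
}

# Per-position similarity oracle.
oracle_similarity <- function(p1, p2) {
  a <- strsplit(p1, "")[[1]]
  b <- strsplit(p2, "")[[1]]
  s <- 0L
  for (i in seq_along(a)) s <- s + if (a[i] == b[i]) 2L else -1L
  s
}

# Pairwise Mann-Whitney AUC oracle (ties count 1/2).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Brute-force layer-1 weight search by nested loops over the simplex grid
# (lexicographic, step 0.1), independent of weight_grid().
oracle_weight_search <- function(P, labels, threshold = 0.5) {
  best_acc <- -1
  best_w <- NULL
  for (i1 in 0:10) for (i2 in 0:(10 - i1)) for (i3 in 0:(10 - i1 - i2)) {
    for (i4 in 0:(10 - i1 - i2 - i3)) {
      i5 <- 10 - i1 - i2 - i3 - i4
      w <- c(i1, i2, i3, i4, i5) / 10
      acc <- mean((drop(P %*% w) >= threshold) == (labels == 1))
      if (acc > best_acc + 1e-12) {
        best_acc <- acc
        best_w <- w
      }
    }
  }
  list(w = best_w, accuracy = best_acc)
}

# Brute-force prefix LPF oracle: count dinucleotide occurrences by substring
# scanning.
oracle_lpf <- function(seq) {
  n <- nchar(seq)
  out <- numeric(n - 1)
  for (j in 2:n) {
    di <- substr(seq, j - 1, j)
    cnt <- 0
    for (m in 2:j) if (substr(seq, m - 1, m) == di) cnt <- cnt + 1
    out[j - 1] <- cnt / j
  }
  out
}

# Single-hyperparameter specs for cheap deterministic fits.
svm_spec1 <- function(cost = 32, gamma = 2^-7, seed = 1) {
  classifier_spec("SVM", data.frame(cost = cost, gamma = gamma), seed = seed)
}

ert_spec1 <- function(ntree = 100, mtry = 3, nsplit = 2, seed = 1) {
  classifier_spec("ERT", data.frame(ntree = ntree, mtry = mtry,
                                    nsplit = nsplit), seed = seed)
}

# Light pipeline configurations for end-to-end tests.
light_config <- function(encodings = c("NUM", "MBE"), classifiers = "SVM",
                         folds = 3, seed = 1, sfs = FALSE) {
  run_config(
    encodings = encodings, classifiers = classifiers, folds = folds,
    seed = seed, sfs = sfs,
    param_grids = list(
      SVM = data.frame(cost = 32, gamma = 2^-7),
      ERT = data.frame(ntree = 100, mtry = 3, nsplit = 2)
    )
  )
}
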