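# Feature encodings. Each maps a 41-nt adenine-centered window to a fixed-
# length numeric vector; encode_dataset() stacks them into a feature matrix
# tagged with the encoding name. Dimensions are part of the contract:
#   NUM 40, MBE 164, DBE 160, LPF 40, DBE_LPF 200, RFHC 164, KNN 7, KMER 1364.

ENCODINGS <- c("NUM", "MBE", "DBE", "LPF", "DBE_LPF", "RFHC", "KNN", "KMER")

#' Feature dimensions of the available encodings
#'
#' @return Named integer vector mapping encoding name to output dimension.
#' @export
encoder_dims <- function() {
  c(NUM = 40L, MBE = 164L, DBE = 160L, LPF = 40L, DBE_LPF = 200L,
    RFHC = 164L, KNN = 7L, KMER = 1364L)
}

.check_window <- function(seq) {
  v <- validate_window(seq)
  if (!v$valid) stop("invalid window: ", v$reason, call. = FALSE)
  strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
}

#' Numerical representation of nucleotides
#'
#' Maps bases alphabetically to A = 0.25, C = 0.50, G = 0.75, T = 1.0 for
#' the 20 upstream and 20 downstream positions; the central adenine is
#' constant by construction and omitted, giving 40 values.
#'
#' @param seq A valid 41-nt window.
#' @return Numeric vector of length 40.
#' @export
encode_num <- function(seq) {
  chars <- .check_window(seq)
  map <- c(A = 0.25, C = 0.50, G = 0.75, T = 1.0)
  unname(map[chars[-CENTER_POS]])
}

#' Mononucleotide binary encoding
#'
#' One-hot code per position in base order A, C, G, T: A = (1,0,0,0),
#' C = (0,1,0,0), G = (0,0,1,0), T = (0,0,0,1). All 41 positions are kept,
#' giving a 164-dimensional vector.
#'
#' @inheritParams encode_num
#' @return Numeric vector of length 164.
#' @export
encode_mbe <- function(seq) {
  chars <- .check_window(seq)
  m <- matrix(0, nrow = WINDOW_LEN, ncol = 4L)
  m[cbind(seq_len(WINDOW_LEN), match(chars, DNA_BASES))] <- 1
  as.vector(t(m))
}

# Dinucleotide index under letter order A,T,C,G for both letters, the unique
# order consistent with the reference codes AA=(0,0,0,0), AT=(0,0,0,1),
# AC=(0,0,1,0). Values 0..15.
.dinuc_index <- function(chars) {
  idx <- match(chars, c("A", "T", "C", "G")) - 1L
  4L * idx[-length(idx)] + idx[-1L]
}

#' Dinucleotide binary encoding
#'
#' Each of the 40 overlapping dinucleotides is written as the 4-bit binary
#' form (most significant bit first) of its index 0-15 under letter order
#' A, T, C, G, so AA = (0,0,0,0), AT = (0,0,0,1), AC = (0,0,1,0), ...,
#' GG = (1,1,1,1). 160 values in total.
#'
#' @inheritParams encode_num
#' @return Numeric vector of length 160.
#' @export
encode_dbe <- function(seq) {
  chars <- .check_window(seq)
  di <- .dinuc_index(chars)
  bits <- vapply(di, function(v) as.numeric(bitwAnd(bitwShiftR(v, 3:0), 1L)),
                 numeric(4L))
  as.vector(bits)
}

#' Local position-specific dinucleotide frequency
#'
#' For each position j = 2..41, the number of occurrences of the
#' dinucleotide ending at j among the dinucleotides of the length-j prefix,
#' divided by the prefix length j. Values lie in (0, 1]; a poly-A window
#' gives (1/2, 2/3, ..., 40/41).
#'
#' @inheritParams encode_num
#' @return Numeric vector of length 40.
#' @export
encode_lpf <- function(seq) {
  chars <- .check_window(seq)
  di <- .dinuc_index(chars) # di[m] is the dinucleotide ending at position m+1
  vapply(seq_along(di), function(m) {
    sum(di[seq_len(m)] == di[m]) / (m + 1)
  }, numeric(1L))
}

#' Combined dinucleotide binary / local frequency encoding
#'
#' Concatenation of [encode_dbe()] (160 binary values) and [encode_lpf()]
#' (40 prefix frequencies): 200 features.
#'
#' @inheritParams encode_num
#' @return Numeric vector of length 200.
#' @export
encode_dbe_lpf <- function(seq) {
  c(encode_dbe(seq), encode_lpf(seq))
}

#' Ring-function-hydrogen chemical encoding with prefix density
#'
#' Per position i a 4-tuple (a, b, c, d): a = 1 for purines (A, G; one vs
#' two rings), b = 1 for weak pairing (A, T; two vs three hydrogen bonds),
#' c = 1 for amino bases (A, C; amino vs keto group), so A = (1,1,1),
#' C = (0,0,1), G = (1,0,0), T = (0,1,0); d is the density of the current
#' base within the prefix 1..i (count / i). 4 x 41 = 164 values.
#'
#' @inheritParams encode_num
#' @return Numeric vector of length 164.
#' @export
encode_rfhc <- function(seq) {
  chars <- .check_window(seq)
  a <- as.numeric(chars %in% c("A", "G"))
  b <- as.numeric(chars %in% c("A", "T"))
  cc <- as.numeric(chars %in% c("A", "C"))
  d <- stats::ave(seq_along(chars), chars, FUN = seq_along) /
    seq_along(chars)
  as.vector(rbind(a, b, cc, d))
}

#' k-mer composition (k = 1..5)
#'
#' Normalized frequency blocks for mono- through penta-nucleotides
#' (4 + 16 + 64 + 256 + 1024 = 1364 values); each k-block sums to 1.
#'
#' @inheritParams encode_num
#' @return Named numeric vector of length 1364.
#' @export
encode_kmer <- function(seq) {
  .check_window(seq)
  x <- Biostrings::DNAString(toupper(seq))
  unlist(lapply(1:5, function(k) {
    Biostrings::oligonucleotideFrequency(x, width = k, as.prob = TRUE)
  }))
}

#' Pairwise sequence similarity score
#'
#' Position-wise sum of +2 for a match and -1 for a mismatch. For 41-mers
#' the range is [-41, 82]; the score is symmetric in its arguments.
#'
#' @param p1,p2 Equal-length DNA strings.
#' @return Integer score.
#' @export
similarity_score <- function(p1, p2) {
  a <- strsplit(toupper(p1), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(p2), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) {
    stop("sequences differ in length (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  }
  sum(ifelse(a == b, 2L, -1L))
}

.seq_int_matrix <- function(seqs) {
  t(vapply(strsplit(toupper(seqs), "", fixed = TRUE),
           function(ch) match(ch, DNA_BASES),
           integer(nchar(seqs[1L]))))
}

#' Build the nearest-neighbour reference for the KNN encoding
#'
#' Snapshots the labeled training windows against which query similarity is
#' measured. The neighbourhood sizes are fixed at n = 2, 4, 8, 16, 32, 64,
#' 128, so at least 128 labeled records are required (129 when training
#' records will be encoded with self-exclusion).
#'
#' @param train Labeled `m6a_dataset`.
#' @return A `knn_reference` object.
#' @export
build_knn_reference <- function(train) {
  n_values <- c(2L, 4L, 8L, 16L, 32L, 64L, 128L)
  lab <- train$label
  if (anyNA(lab)) stop("KNN reference requires labeled records", call. = FALSE)
  if (nrow(train) < max(n_values)) {
    stop(sprintf(
      "KNN reference needs >= %d labeled records, got %d",
      max(n_values), nrow(train)
    ), call. = FALSE)
  }
  structure(
    list(
      ids = train$id,
      seqs = train$seq,
      labels = as.integer(lab),
      mat = .seq_int_matrix(train$seq),
      n_values = n_values
    ),
    class = "knn_reference"
  )
}

#' @export
print.knn_reference <- function(x, ...) {
  cat(sprintf(
    "knn_reference: %d sequences (%d positive), n = %s\n",
    length(x$seqs), sum(x$labels == 1L), paste(x$n_values, collapse = ",")
  ))
  invisible(x)
}

# Similarity of every query row to every reference row, via four boolean
# matrix products (matches m -> score 3m - L).
.similarity_matrix <- function(Q, R) {
  M <- matrix(0, nrow(Q), nrow(R))
  for (b in 1:4) M <- M + (Q == b) %*% t(R == b)
  3 * M - ncol(Q)
}

.encode_knn_matrix <- function(ds, ref, exclude_self = TRUE) {
  Q <- .seq_int_matrix(ds$seq)
  S <- .similarity_matrix(Q, ref$mat)
  if (exclude_self) {
    hit <- match(ds$id, ref$ids)
    ok <- !is.na(hit) & ds$seq == ref$seqs[pmax(hit, 1L)]
    if (any(ok)) S[cbind(which(ok), hit[ok])] <- -Inf
    if (any(ok) && length(ref$seqs) - 1L < max(ref$n_values)) {
      stop("too few reference sequences after self-exclusion", call. = FALSE)
    }
  }
  pos <- ref$labels == 1L
  nv <- ref$n_values
  out <- matrix(NA_real_, nrow(S), length(nv))
  for (i in seq_len(nrow(S))) {
    ord <- order(S[i, ], decreasing = TRUE) # stable: ties by insertion order
    cum <- cumsum(pos[ord])
    out[i, ] <- cum[nv] / nv
  }
  colnames(out) <- paste0("KNN_n", nv)
  out
}

#' Nearest-neighbour encoding of a single window
#'
#' For each neighbourhood size n in (2, 4, ..., 128), the fraction of
#' positive-labeled sequences among the n reference sequences most similar
#' to the query under [similarity_score()]. Ties are broken by reference
#' insertion order. With `exclude_self = TRUE` an exact identity match to
#' the query's own record (same id and sequence) is removed before ranking,
#' which is essential when encoding training data.
#'
#' @param rec A valid 41-nt window (character) or one-row `m6a_dataset`.
#' @param ref A [build_knn_reference()] object.
#' @param exclude_self Drop the query's own record from the reference?
#' @param id Record id used for self-matching when `rec` is a bare string.
#' @return Numeric vector of length 7, values in \[0, 1\].
#' @export
encode_knn <- function(rec, ref, exclude_self = TRUE, id = NA_character_) {
  if (is.character(rec)) {
    rec <- as_dataset(rec, id = if (is.na(id)) "query" else id)
  }
  drop(.encode_knn_matrix(rec, ref, exclude_self = exclude_self)[1L, ])
}

#' Encode a dataset under one encoding
#'
#' @param ds An `m6a_dataset`.
#' @param encoding One of `"NUM"`, `"MBE"`, `"DBE"`, `"LPF"`, `"DBE_LPF"`,
#'   `"RFHC"`, `"KNN"`, `"KMER"`.
#' @param knn_ref Reference from [build_knn_reference()] (KNN only).
#' @param exclude_self Passed to the KNN encoder; keep `TRUE` whenever `ds`
#'   rows are part of `knn_ref`.
#' @return Numeric matrix, rows = records, with attribute `encoding`; column
#'   names identify features (e.g. `MBE_pos07_C`).
#' @export
encode_dataset <- function(ds, encoding, knn_ref = NULL, exclude_self = TRUE) {
  encoding <- match.arg(toupper(encoding), ENCODINGS)
  if (encoding == "KNN") {
    if (is.null(knn_ref)) stop("KNN encoding requires knn_ref", call. = FALSE)
    out <- .encode_knn_matrix(ds, knn_ref, exclude_self = exclude_self)
  } else {
    fun <- switch(encoding,
      NUM = encode_num, MBE = encode_mbe, DBE = encode_dbe,
      LPF = encode_lpf, DBE_LPF = encode_dbe_lpf, RFHC = encode_rfhc,
      KMER = encode_kmer
    )
    dim <- encoder_dims()[[encoding]]
    out <- t(vapply(ds$seq, fun, numeric(dim)))
    colnames(out) <- .feature_names(encoding)
  }
  rownames(out) <- ds$id
  attr(out, "encoding") <- encoding
  out
}

.feature_names <- function(encoding) {
  switch(encoding,
    NUM = sprintf("NUM_pos%02d", setdiff(1:41, CENTER_POS)),
    MBE = as.vector(t(outer(sprintf("MBE_pos%02d_", 1:41), DNA_BASES,
                            paste0))),
    DBE = as.vector(t(outer(sprintf("DBE_di%02d_", 1:40), paste0("b", 1:4),
                            paste0))),
    LPF = sprintf("LPF_j%02d", 2:41),
    DBE_LPF = c(.feature_names("DBE"), .feature_names("LPF")),
    RFHC = as.vector(t(outer(sprintf("RFHC_pos%02d_", 1:41),
                             c("ring", "hbond", "func", "dens"), paste0))),
    KMER = unlist(lapply(1:5, function(k) {
      paste0("KMER_", Biostrings::mkAllStrings(DNA_BASES, k))
    }))
  )
}

#' Export a feature matrix as TSV
#'
#' @param mat Matrix from [encode_dataset()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_features <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
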