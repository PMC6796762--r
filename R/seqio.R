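#' Validate a candidate adenine-centered window
#'
#' A window is usable by the predictor when it is exactly 41 nt long,
#' contains only the four unambiguous DNA bases, and carries an adenine at
#' the central (21st) position. Lowercase input is accepted and treated as
#' uppercase; `U` and IUPAC ambiguity codes are rejected (this is a DNA
#' tool).
#'
#' @param seq Character scalar, the candidate window.
#' @return A list with elements `valid` (logical) and `reason` (character,
#'   `"ok"` when valid).
#' @examples
#' validate_window(strrep("A", 41))
#' validate_window(paste0(strrep("C", 20), "G", strrep("C", 20)))
#' @export
validate_window <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    return(list(valid = FALSE, reason = "not a single sequence string"))
  }
  s <- toupper(seq)
  if (nchar(s) != WINDOW_LEN) {
    return(list(
      valid = FALSE,
      reason = sprintf("length %d, expected %d", nchar(s), WINDOW_LEN)
    ))
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% DNA_BASES)) {
    bad <- setdiff(unique(chars), DNA_BASES)
    return(list(
      valid = FALSE,
      reason = paste0("ambiguous base: ", paste(bad, collapse = ","))
    ))
  }
  if (chars[CENTER_POS] != "A") {
    return(list(valid = FALSE, reason = "central base not A"))
  }
  list(valid = TRUE, reason = "ok")
}

#' Assemble a labeled window dataset
#'
#' The central container of the package: a data frame with one row per
#' 41-nt adenine-centered window and columns `id`, `seq`, `label`
#' (1 = methylated, 0 = unmethylated, `NA` = unknown) and `source_pos`
#' (1-based genomic coordinate of the central adenine, when known).
#'
#' @param seq Character vector of window sequences.
#' @param label Binary labels (recycled), `NA` for unlabeled data.
#' @param id Record identifiers; generated when `NULL`.
#' @param source_pos Optional 1-based coordinates of the central adenine.
#' @param validate Check every window against [validate_window()]?
#' @return An object of class `m6a_dataset`.
#' @export
as_dataset <- function(seq, label = NA_integer_, id = NULL,
                       source_pos = NA_integer_, validate = TRUE) {
  seq <- toupper(as.character(seq))
  n <- length(seq)
  if (is.null(id)) id <- sprintf("seq%05d", seq_len(n))
  ds <- data.frame(
    id = as.character(id),
    seq = seq,
    label = as.integer(rep_len(label, n)),
    source_pos = as.integer(rep_len(source_pos, n)),
    stringsAsFactors = FALSE
  )
  class(ds) <- c("m6a_dataset", "data.frame")
  if (validate && n > 0L) {
    checks <- lapply(ds$seq, validate_window)
    bad <- !vapply(checks, `[[`, logical(1L), "valid")
    if (any(bad)) {
      msgs <- vapply(which(bad), function(i) {
        sprintf("%s: %s", ds$id[i], checks[[i]]$reason)
      }, character(1L))
      stop("invalid window(s):\n  ", paste(head(msgs, 10L), collapse = "\n  "),
           if (sum(bad) > 10L) sprintf("\n  ... and %d more", sum(bad) - 10L),
           call. = FALSE)
    }
  }
  ds
}

#' @export
print.m6a_dataset <- function(x, ...) {
  cat(sprintf(
    "m6a_dataset: %d windows (%d positive, %d negative, %d unlabeled)\n",
    nrow(x), n_pos(x), n_neg(x), sum(is.na(x$label))
  ))
  if (nrow(x) > 0L) {
    print.data.frame(head(as.data.frame(x), 5L))
    if (nrow(x) > 5L) cat(sprintf("... %d more rows\n", nrow(x) - 5L))
  }
  invisible(x)
}

#' Class counts of a dataset
#'
#' @param ds An `m6a_dataset`.
#' @return Number of positive (`n_pos`) or negative (`n_neg`) records.
#' @export
n_pos <- function(ds) sum(ds$label == 1L, na.rm = TRUE)

#' @rdname n_pos
#' @export
n_neg <- function(ds) sum(ds$label == 0L, na.rm = TRUE)

#' Read 41-nt windows from a FASTA file
#'
#' Entries are uppercased and validated as adenine-centered windows. The
#' common distribution format for 6mA benchmarks is a pair of FASTA files
#' (positives and negatives); use `label` to tag all entries of one file,
#' or [read_dataset()] for the pair.
#'
#' @param path FASTA file.
#' @param label Optional binary label applied to every entry.
#' @return An `m6a_dataset`.
#' @export
read_fasta <- function(path, label = NA_integer_) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  ids <- sub("\\s.*$", "", names(set))
  as_dataset(as.character(set), label = label, id = ids)
}

#' Write a dataset to FASTA
#'
#' @param ds An `m6a_dataset`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ds, path) {
  set <- Biostrings::BStringSet(stats::setNames(ds$seq, ds$id))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read a labeled benchmark from paired FASTA files
#'
#' @param positive FASTA of methylated (6mA) windows.
#' @param negative FASTA of unmethylated windows.
#' @return An `m6a_dataset` with labels 1 and 0.
#' @export
read_dataset <- function(positive, negative) {
  pos <- read_fasta(positive, label = 1L)
  neg <- read_fasta(negative, label = 0L)
  ds <- rbind(pos, neg)
  if (anyDuplicated(ds$id)) ds$id <- make.unique(ds$id, sep = "_")
  class(ds) <- c("m6a_dataset", "data.frame")
  ds
}

#' Extract adenine-centered windows from a longer sequence
#'
#' Scans the forward strand and emits one window per adenine far enough
#' from the sequence ends for a full window; windows containing `N` are
#' dropped. Coordinates are 1-based positions of the central adenine.
#' Adenines closer than `flank` to either end are skipped (no padding).
#'
#' @param genome Character scalar over `A,C,G,T,N` (case-insensitive).
#' @param flank Nucleotides on each side of the adenine (20 gives the
#'   standard 41-nt window).
#' @return An `m6a_dataset` of unlabeled windows with `source_pos` set.
#' @examples
#' extract_adenine_windows(paste0(strrep("C", 20), "A", strrep("C", 20)))
#' @export
extract_adenine_windows <- function(genome, flank = 20L) {
  stopifnot(is.character(genome), length(genome) == 1L)
  flank <- as.integer(flank)
  g <- toupper(genome)
  L <- nchar(g)
  empty <- as_dataset(character(0L), validate = FALSE)
  if (L < 2L * flank + 1L) return(empty)
  chars <- strsplit(g, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% c(DNA_BASES, "N"))) {
    stop("sequence contains characters outside A,C,G,T,N", call. = FALSE)
  }
  centers <- which(chars == "A")
  centers <- centers[centers > flank & centers <= L - flank]
  if (length(centers) == 0L) return(empty)
  win <- substring(g, centers - flank, centers + flank)
  keep <- !grepl("N", win, fixed = TRUE)
  as_dataset(
    win[keep],
    id = sprintf("pos%d", centers[keep]),
    source_pos = centers[keep],
    validate = (flank == 20L)
  )
}
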