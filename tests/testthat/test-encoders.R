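test_that("every encoder honours its dimension contract on random windows", {
  ds <- simulate_dataset(sim_config(n_pos = 70, n_neg = 70, seed = 5))
  ref <- build_knn_reference(ds)
  dims <- encoder_dims()
  for (enc in names(dims)) {
    mat <- encode_dataset(ds, enc, knn_ref = ref)
    expect_equal(ncol(mat), unname(dims[[enc]]), info = enc)
    expect_equal(nrow(mat), nrow(ds), info = enc)
    expect_true(all(is.finite(mat)), info = enc)
  }
})

test_that("numerical encoding maps bases alphabetically and skips the center", {
  expect_equal(encode_num(strrep("A", 41)), rep(0.25, 40))
  w <- paste0("T", substr(strrep("A", 41), 2, 41))
  expect_equal(encode_num(w)[1], 1.0)
  w2 <- paste0("CG", strrep("A", 39))
  expect_equal(encode_num(w2)[1:2], c(0.50, 0.75))
})

test_that("mononucleotide binary encoding is positionwise one-hot", {
  v <- encode_mbe(strrep("A", 41))
  expect_equal(v[1:4], c(1, 0, 0, 0))
  wt <- paste0("T", strrep("A", 40))
  expect_equal(encode_mbe(wt)[1:4], c(0, 0, 0, 1))
  for (w in random_windows(5, 11)) {
    blocks <- matrix(encode_mbe(w), ncol = 4, byrow = TRUE)
    expect_true(all(rowSums(blocks) == 1))
  }
})

test_that("dinucleotide binary codes are a bijection fixed by the reference codes", {
  codes <- list()
  bases <- c("A", "C", "G", "T")
  for (b1 in bases) for (b2 in bases) {
    w <- paste0(b1, b2, strrep("A", 39))
    codes[[paste0(b1, b2)]] <- encode_dbe(w)[1:4]
  }
  expect_equal(codes[["AA"]], c(0, 0, 0, 0))
  expect_equal(codes[["AT"]], c(0, 0, 0, 1))
  expect_equal(codes[["AC"]], c(0, 0, 1, 0))
  expect_equal(codes[["GG"]], c(1, 1, 1, 1))
  ints <- vapply(codes, function(b) sum(b * c(8, 4, 2, 1)), numeric(1))
  expect_setequal(ints, 0:15) # all 16 dinucleotides get distinct 4-bit codes
})

test_that("local dinucleotide frequencies follow the prefix formula", {
  expect_equal(encode_lpf(strrep("A", 41)), (1:40) / (2:41))
  # frozen from the brute-force oracle: "ACAC..." has AC at j = 4, seen
  # twice among the first three dinucleotides -> 2/4
  acac <- paste0(strrep("AC", 10), "A", strrep("CA", 10))
  expect_equal(encode_lpf(acac)[3], 0.5)
  expect_equal(encode_lpf(acac), oracle_lpf(acac))
  for (w in random_windows(10, 23)) {
    v <- encode_lpf(w)
    expect_equal(v, oracle_lpf(w))
    expect_true(all(v > 0 & v <= 1))
    expect_equal(v[1], 1 / 2) # the first dinucleotide has always occurred once
  }
})

test_that("combined DBE_LPF encoding concatenates its parts", {
  w <- random_window(3)
  v <- encode_dbe_lpf(w)
  expect_length(v, 200)
  expect_equal(v[1:160], encode_dbe(w))
  expect_equal(v[161:200], encode_lpf(w))
  expect_true(all(v[1:160] %in% c(0, 1)))
})

test_that("chemical-property encoding matches the base coordinates and densities", {
  v <- encode_rfhc(strrep("A", 41))
  expect_equal(v[1:3], c(1, 1, 1)) # A = (1,1,1)
  expect_true(all(matrix(v, ncol = 4, byrow = TRUE)[, 4] == 1)) # homopolymer
  coords <- list(A = c(1, 1, 1), C = c(0, 0, 1), G = c(1, 0, 0),
                 T = c(0, 1, 0))
  for (b in names(coords)) {
    w <- paste0(b, substr(random_window(4), 2, 41))
    expect_equal(encode_rfhc(w)[1:3], coords[[b]], info = b)
  }
  # "AACA...": position 4 holds an A, the third A among four bases -> 0.75
  w <- paste0("AACA", strrep("C", 16), "A", strrep("C", 20))
  expect_equal(encode_rfhc(w)[16], 0.75)
  for (w in random_windows(5, 31)) {
    d <- matrix(encode_rfhc(w), ncol = 4, byrow = TRUE)[, 4]
    expect_equal(d[1], 1)
    expect_true(all(d > 0 & d <= 1))
  }
})

test_that("k-mer composition is normalized per block", {
  v <- encode_kmer(strrep("A", 41))
  expect_length(v, 1364)
  expect_equal(unname(v[["A"]]), 1)
  expect_equal(unname(v[["AAAAA"]]), 1)
  sizes <- c(4, 16, 64, 256, 1024)
  for (w in random_windows(4, 47)) {
    v <- encode_kmer(w)
    off <- 0
    for (k in seq_along(sizes)) {
      expect_equal(sum(v[(off + 1):(off + sizes[k])]), 1, tolerance = 1e-9)
      off <- off + sizes[k]
    }
    # hand-counted dinucleotide block
    di <- substring(w, 1:40, 2:41)
    expect_equal(unname(v[paste0("GA")]), sum(di == "GA") / 40)
  }
})

test_that("similarity score is +2/-1 per position and symmetric", {
  w <- random_window(8)
  expect_equal(similarity_score(w, w), 82)
  expect_equal(similarity_score(strrep("A", 41), strrep("C", 41)), -41)
  expect_error(similarity_score(strrep("A", 41), strrep("A", 40)), "length")
  for (i in 1:50) {
    p1 <- random_window(100 + i)
    p2 <- random_window(200 + i)
    expect_equal(similarity_score(p1, p2), oracle_similarity(p1, p2))
    expect_equal(similarity_score(p1, p2), similarity_score(p2, p1))
  }
})

test_that("KNN reference requires enough labeled records and is immutable", {
  ds <- simulate_dataset(sim_config(n_pos = 70, n_neg = 70, seed = 13))
  expect_error(build_knn_reference(ds[1:100, ]), ">= 128")
  unl <- ds
  unl$label[1] <- NA_integer_
  expect_error(build_knn_reference(unl), "labeled")
  ref <- build_knn_reference(ds)
  before <- ref$labels
  invisible(encode_dataset(ds, "KNN", knn_ref = ref))
  expect_identical(ref$labels, before)
})

test_that("KNN features are positive fractions of the nearest neighbours", {
  base <- strrep("C", 20)
  q <- paste0(base, "A", base)
  mutate_at <- function(seq, pos, to) {
    vapply(seq_along(pos), function(i) {
      s <- seq
      substr(s, pos[i], pos[i]) <- to
      s
    }, character(1))
  }
  near_pos <- mutate_at(q, 1:2, "G")        # 1 mismatch each
  far <- vapply(1:128, function(i) {
    set.seed(300 + i)                        # ~30 mismatches
    ch <- strsplit(q, "")[[1]]
    at <- sample(setdiff(1:41, 21), 30)
    ch[at] <- "T"
    paste(ch, collapse = "")
  }, character(1))
  ref <- build_knn_reference(as_dataset(
    c(near_pos, far),
    label = c(1L, 1L, rep(0L, 128)),
    id = sprintf("ref%03d", 1:130)
  ))
  f <- encode_knn(q, ref, exclude_self = FALSE)
  expect_equal(unname(f[1]), 1.0)  # both nearest neighbours positive
  expect_true(all(f >= 0 & f <= 1))
  expect_length(f, 7)

  # converse: when only the two farthest references are positive, the
  # top-2 .. top-64 neighbourhoods contain no positives at all
  ref3 <- build_knn_reference(as_dataset(
    c(mutate_at(q, 1:2, "G"), far),
    label = c(0L, 0L, rep(0L, 126), 1L, 1L),
    id = sprintf("s%03d", 1:130)
  ))
  f3 <- encode_knn(q, ref3, exclude_self = FALSE)
  expect_equal(unname(f3[1:6]), rep(0, 6)) # positives are farthest
})

test_that("self-exclusion removes the trivially leaked nearest neighbour", {
  ds <- null_dataset(300, seed = 77)
  ref <- build_knn_reference(ds)
  leaky <- encode_dataset(ds, "KNN", knn_ref = ref, exclude_self = FALSE)
  guarded <- encode_dataset(ds, "KNN", knn_ref = ref, exclude_self = TRUE)
  # with the self-match allowed, the n = 2 feature is >= 0.5 for every
  # positive and <= 0.5 for every negative: label leakage
  expect_true(all(leaky[ds$label == 1L, 1] >= 0.5))
  expect_true(all(leaky[ds$label == 0L, 1] <= 0.5))
  # the guarded encoding carries no such certificate on null data
  expect_false(all(guarded[ds$label == 1L, 1] >= 0.5) &&
                 all(guarded[ds$label == 0L, 1] <= 0.5))
})

test_that("encoders are pure functions", {
  w <- random_window(99)
  for (fun in list(encode_num, encode_mbe, encode_dbe_lpf, encode_rfhc,
                   encode_kmer)) {
    expect_identical(fun(w), fun(w))
  }
})

test_that("invalid windows are rejected by every encoder", {
  bad <- strrep("C", 41) # central base not A
  for (fun in list(encode_num, encode_mbe, encode_dbe, encode_lpf,
                   encode_rfhc, encode_kmer)) {
    expect_error(fun(bad), "invalid window")
  }
})
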