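test_that("window validation enforces length, alphabet and central adenine", {
  expect_true(validate_window(strrep("A", 41))$valid)
  expect_true(validate_window(tolower(strrep("a", 41)))$valid)

  g_center <- paste0(strrep("A", 20), "G", strrep("A", 20))
  v <- validate_window(g_center)
  expect_false(v$valid)
  expect_match(v$reason, "central base not A")

  v40 <- validate_window(strrep("A", 40))
  expect_false(v40$valid)
  expect_match(v40$reason, "length 40")

  with_n <- paste0(strrep("A", 20), "A", strrep("N", 20))
  vn <- validate_window(with_n)
  expect_false(vn$valid)
  expect_match(vn$reason, "ambiguous")

  with_u <- paste0(strrep("U", 20), "A", strrep("A", 20))
  expect_false(validate_window(with_u)$valid)
})

test_that("FASTA roundtrip preserves sequences and ids; labels are applied", {
  ds <- simulate_dataset(sim_config(n_pos = 15, n_neg = 15, seed = 42))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(ds, f)
  back <- read_fasta(f, label = 1L)
  expect_identical(back$seq, ds$seq)
  expect_identical(back$id, ds$id)
  expect_true(all(back$label == 1L))

  # writing the re-read windows reproduces the file byte-identically
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("invalid FASTA entries fail with the offending record named", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">good", strrep("A", 41), ">short_one", strrep("A", 40)), f)
  expect_error(read_fasta(f), "short_one")
  expect_error(read_fasta("/nonexistent/x.fa"), "no such file")
})

test_that("paired FASTA files become one labeled dataset", {
  ds <- simulate_dataset(sim_config(n_pos = 12, n_neg = 14, seed = 9))
  fp <- withr::local_tempfile(fileext = ".fasta")
  fn <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(ds[ds$label == 1L, ], fp)
  write_fasta(ds[ds$label == 0L, ], fn)
  both <- read_dataset(fp, fn)
  expect_equal(n_pos(both), 12)
  expect_equal(n_neg(both), 14)
})

test_that("adenine window extraction enumerates eligible centers", {
  one <- extract_adenine_windows(strrep("A", 41))
  expect_equal(nrow(one), 1L)
  expect_equal(one$source_pos, 21L)

  expect_equal(nrow(extract_adenine_windows(strrep("C", 100))), 0L)

  centered <- extract_adenine_windows(
    paste0(strrep("C", 20), "A", strrep("C", 20))
  )
  expect_equal(nrow(centered), 1L)
  expect_equal(centered$source_pos, 21L)
  expect_identical(centered$seq, paste0(strrep("C", 20), "A", strrep("C", 20)))

  # too short for any window
  expect_equal(nrow(extract_adenine_windows(strrep("A", 40))), 0L)

  # windows containing N are dropped
  with_n <- paste0(strrep("C", 20), "A", strrep("C", 19), "N",
                   strrep("C", 10), "A", strrep("C", 20))
  out <- extract_adenine_windows(with_n)
  expect_false(any(grepl("N", out$seq)))
})

test_that("every extracted window passes validation and bookkeeping holds on reversal", {
  set.seed(7)
  genome <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                  collapse = "")
  wins <- extract_adenine_windows(genome)
  expect_true(all(vapply(wins$seq, function(s) validate_window(s)$valid,
                         logical(1))))
  # reported coordinates point at real adenines
  chars <- strsplit(genome, "")[[1]]
  expect_true(all(chars[wins$source_pos] == "A"))

  rev_genome <- paste(rev(chars), collapse = "")
  rev_wins <- extract_adenine_windows(rev_genome)
  eligible <- rev(chars)[21:(300 - 20)]
  expect_equal(nrow(rev_wins), sum(eligible == "A"))
})
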