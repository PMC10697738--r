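test_that("DRACH consensus matches its degenerate definition", {
  expect_true(is_drach("GGACU"))
  expect_true(is_drach("AAACA"))
  expect_false(is_drach("UUACG")) # R='U' invalid, H='G' invalid
  expect_false(is_drach("CGACU")) # D='C' invalid
  expect_true(is_drach("GGACT")) # DNA synonym
  expect_error(is_drach("GGAC"), "5-mer")
  expect_error(is_drach("GGACN"), "A,C,G,U")
  # brute-force cross-check against the rule on all 4^5 5-mers
  all5 <- apply(
    expand.grid(rep(list(c("A", "C", "G", "U")), 5)), 1, paste0,
    collapse = ""
  )
  oracle <- vapply(all5, function(s) {
    b <- strsplit(s, "")[[1]]
    b[1] %in% c("A", "G", "U") && b[2] %in% c("A", "G") && b[3] == "A" &&
      b[4] == "C" && b[5] %in% c("A", "C", "U")
  }, logical(1))
  expect_equal(unname(is_drach(all5)), unname(oracle))
  expect_length(drach_kmers(), sum(oracle))
})

test_that("sites TSV reading validates structure and positions", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "transcript_id\tposition\tlabel",
    "tx1\t100\tpositive",
    "tx2\t7\tnegative"
  ), f)
  s <- read_sites(f)
  expect_equal(s$transcript_id, c("tx1", "tx2"))
  expect_equal(s$position, c(100L, 7L))
  expect_equal(s$label, c("positive", "negative"))

  writeLines("transcript_id\tposition\tlabel", f)
  expect_equal(nrow(read_sites(f)), 0)

  writeLines(c("transcript_id\tposition\tlabel", "tx1\tabc\tpositive"), f)
  expect_error(read_sites(f), "line.*2")

  writeLines(c("transcript_id\tlabel", "tx1\tpositive"), f)
  expect_error(read_sites(f), "position")
})

test_that("window extraction enforces bounds, central A and DRACH", {
  set.seed(5)
  tx <- paste0(
    paste(sample(c("A", "C", "G", "U"), 198, TRUE), collapse = ""),
    "GGACU",
    paste(sample(c("A", "C", "G", "U"), 198, TRUE), collapse = "")
  ) # central A of GGACU at 0-based position 200, length 401
  w <- extract_window(tx, 200, flank = 100)
  expect_s3_class(w, "data.frame")
  expect_equal(nchar(w$sequence), 201)
  expect_equal(substr(w$sequence, 101, 101), "A")
  expect_true(is_drach(substr(w$sequence, 99, 103)))

  r <- extract_window(tx, 50, flank = 100)
  expect_s3_class(r, "window_rejection")
  expect_equal(r$reason, "out_of_bounds")

  tx2 <- paste0(strrep("C", 150), "CCACG", strrep("C", 150))
  expect_equal(extract_window(tx2, 150, flank = 100)$reason, "center_not_A")
  # central A sits in a CCACG context, which fails DRACH
  expect_equal(extract_window(tx2, 152, flank = 100)$reason, "not_drach")
})

test_that("negative sampling respects the distance and DRACH rules", {
  gt <- generate_transcripts(
    n = 6, length_range = c(1500, 2500),
    sites_per_transcript = 2, seed = 3
  )
  neg <- sample_negatives(gt$transcripts, gt$sites,
    min_distance = 200,
    n_target = 12, seed = 9
  )
  expect_equal(nrow(neg), 12)
  # brute-force re-check of every emitted negative
  for (i in seq_len(nrow(neg))) {
    tx <- gt$transcripts[[neg$transcript_id[i]]]
    p <- neg$position[i]
    expect_equal(substr(tx, p + 1, p + 1), "A")
    expect_true(is_drach(substr(tx, p - 1, p + 3)))
    ppos <- gt$sites$position[gt$sites$transcript_id == neg$transcript_id[i]]
    expect_gte(min(abs(p - ppos)), 200)
  }
  # candidates 150 nt from a positive are excluded, >= min_distance kept
  tx_small <- paste0(strrep("C", 100), "GGACU", strrep("C", 144), "GGACU",
    strrep("C", 100))
  pos <- data.frame(transcript_id = "t", position = 102L, label = "positive")
  neg2 <- suppressWarnings(sample_negatives(c(t = tx_small), pos,
    min_distance = 200,
    n_target = 5, seed = 1
  ))
  # second GGACU center sits 149 nt downstream -> excluded
  expect_equal(nrow(neg2), 0)
  expect_error(sample_negatives(character(0), pos, n_target = 1), "empty")
})

test_that("fewer candidates than requested returns all with a warning", {
  tx <- paste0(strrep("C", 300), "GGACU", strrep("C", 300))
  nopos <- data.frame(
    transcript_id = character(), position = integer(),
    label = character()
  )
  expect_warning(
    neg <- sample_negatives(c(t = tx), nopos, n_target = 10, seed = 1),
    "eligible"
  )
  expect_equal(nrow(neg), 1)
})

test_that("identity-based redundancy removal follows the greedy rule", {
  base <- strrep("ACGU", 50) # length 200
  base <- paste0(base, "A") # length 201
  mutate <- function(s, k, seed) {
    set.seed(seed)
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), k)
    ch[idx] <- vapply(ch[idx], function(b) {
      setdiff(c("A", "C", "G", "U"), b)[1]
    }, character(1))
    paste0(ch, collapse = "")
  }
  s30 <- mutate(base, 30, 1) # identity 171/201 ~ 0.851 -> redundant
  s50 <- mutate(base, 50, 2) # identity 151/201 ~ 0.751 -> kept
  expect_equal(seq_identity(base, s30), 171 / 201)
  expect_equal(seq_identity(base, s50), 151 / 201)

  df <- data.frame(
    id = c("a", "b", "c", "d"),
    sequence = c(base, base, s30, s50),
    label = "positive", stringsAsFactors = FALSE
  )
  kept <- reduce_redundancy(df, 0.8)
  expect_equal(kept$id, c("a", "d"))

  # no retained pair at or above the threshold (brute force all pairs)
  samples <- random_drach_samples(60, length = 21, seed = 11)
  kept2 <- reduce_redundancy(samples, 0.6)
  if (nrow(kept2) > 1) {
    for (i in seq_len(nrow(kept2) - 1)) {
      for (j in (i + 1):nrow(kept2)) {
        expect_lt(
          seq_identity(kept2$sequence[i], kept2$sequence[j]), 0.6
        )
      }
    }
  }
  df$sequence[2] <- substr(df$sequence[2], 1, 100)
  expect_error(reduce_redundancy(df), "same length")
})

test_that("stratified 9:1 split is exact, disjoint and reproducible", {
  samples <- random_drach_samples(100, length = 21, seed = 2)
  sp <- split_train_test(samples, 0.9, seed = 4)
  expect_equal(nrow(sp$train), 90)
  expect_equal(nrow(sp$test), 10)
  expect_equal(sum(sp$train$label == "positive"), 45)
  expect_equal(sum(sp$test$label == "positive"), 5)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  expect_setequal(c(sp$train$id, sp$test$id), samples$id)

  sp2 <- split_train_test(samples, 0.9, seed = 4)
  expect_identical(sp, sp2)
  sp3 <- split_train_test(samples, 0.9, seed = 5)
  expect_false(identical(sp$test$id, sp3$test$id))
  expect_equal(nrow(sp3$train), 90)
})

test_that("FASTA round trip preserves ids, sequences and labels", {
  samples <- random_drach_samples(10, length = 15, seed = 6)
  f <- withr::local_tempfile(fileext = ".fa")
  write_sample_fasta(samples, f)
  back <- read_sample_fasta(f)
  expect_equal(back$id, samples$id)
  expect_equal(back$sequence, samples$sequence)
  expect_equal(back$label, samples$label)

  writeLines(c(">s1|pos", "GGACT", ">s2", "ACGT"), f)
  mixed <- read_sample_fasta(f)
  expect_equal(mixed$sequence, c("GGACU", "ACGU")) # T read as U
  expect_equal(mixed$label, c("positive", NA))

  writeLines(c(">a", "ACGU", ">a", "GGAC"), f)
  expect_warning(read_sample_fasta(f), "duplicate")
})

test_that("end-to-end dataset build keeps every invariant", {
  gt <- generate_transcripts(
    n = 10, length_range = c(1500, 2500),
    sites_per_transcript = 3, seed = 8
  )
  ds <- build_dataset(gt$transcripts, gt$sites,
    flank = 100, min_distance = 200,
    identity_threshold = 0.8, seed = 2
  )
  all_samples <- rbind(ds$train, ds$test)
  expect_true(all(nchar(all_samples$sequence) == 201))
  expect_true(all(substr(all_samples$sequence, 101, 101) == "A"))
  expect_true(all(is_drach(substr(all_samples$sequence, 99, 103))))
  # balanced up to redundancy removal and extraction rejections
  expect_equal(
    abs(sum(all_samples$label == "positive") -
      sum(all_samples$label == "negative")) <= 2, TRUE
  )
})
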