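# A tiny trained-free model whose first-layer behaviour is fully
# controlled: one conv block, weights set by hand.
hand_conv_model <- function(rows = 14, n_filters = 2, kernel = 4) {
  cfg <- model_config(
    conv_blocks = list(conv_block(n_filters, kernel, 2, 0)),
    fc_units = integer(0), fc_dropout = 0, max_epochs = 1, seed = 3
  )
  mod <- build_model(cfg, c(rows, 4L))
  mod$trained <- TRUE
  mod
}

test_that("first-layer activations are rectified and shaped by valid conv", {
  samples <- random_drach_samples(6, length = 15, seed = 1)
  mod <- hand_conv_model()
  acts <- first_layer_activations(mod, samples)
  expect_true(all(acts$act >= 0))
  expect_equal(acts$T, 14 - 4 + 1) # valid convolution length
  expect_equal(dim(acts$act), c(6 * 11, 2))

  mod0 <- nullify_filters(mod, "all")
  acts0 <- first_layer_activations(mod0, samples)
  expect_true(all(acts0$act == 0))

  lin <- linear_scorer(14)
  expect_error(first_layer_activations(lin, samples), "no convolutional")
})

test_that("activated subsequences obey the half-maximum threshold rule", {
  samples <- data.frame(
    id = c("s1", "s2"),
    sequence = c("GGACUAAAAA", "AAAAAGGACU"),
    label = "positive", stringsAsFactors = FALSE
  )
  mod <- hand_conv_model(rows = 9, n_filters = 1, kernel = 4)
  # filter that fires on the encoded GGACU prefix: detect G-rich rows
  mod$params[["conv1.W"]][] <- 0
  # encoded row channel order within a kernel row block: A,C,G,U
  W <- numeric(16)
  W[3] <- 2 # G channel, kernel row 1
  W[4 + 3] <- 2 # G channel, kernel row 2
  mod$params[["conv1.W"]][, 1] <- W
  mod$params[["conv1.b"]][1] <- 0

  acts <- first_layer_activations(mod, samples)
  subs <- extract_activated_subsequences(acts, samples)
  thr <- attr(subs, "thresholds")
  expect_equal(thr[1], 0.5 * max(acts$act[, 1]))
  # kernel 4 + window 2 -> 5-nt subsequences
  expect_true(all(nchar(subs[[1]]) == 5))
  # the GG-containing placements activate most; threshold keeps only them
  expect_true(all(grepl("GG", subs[[1]])))

  # activation exactly at the threshold is excluded (strict >)
  a2 <- acts
  a2$act[, 1] <- c(rep(1, 3), rep(0.5, 3), rep(0, 2 * acts$T - 6))
  subs2 <- extract_activated_subsequences(a2, samples)
  expect_length(subs2[[1]], 3)
})

test_that("PFM construction counts column frequencies and handles empties", {
  pfm <- build_pfm(c("GGACU", "GGACU", "AGACU"), filter_index = 1)
  expect_equal(pfm$freq[1, ], c(A = 1 / 3, C = 0, G = 2 / 3, U = 0))
  expect_equal(unname(pfm$freq[2, ]), c(0, 0, 1, 0))
  expect_equal(unname(pfm$freq[3, ]), c(1, 0, 0, 0))
  expect_equal(unname(pfm$freq[4, ]), c(0, 1, 0, 0))
  expect_equal(unname(pfm$freq[5, ]), c(0, 0, 0, 1))
  expect_equal(pfm$support, 3L)
  expect_true(all(abs(rowSums(pfm$freq) - 1) < 1e-12))

  one <- build_pfm("ACGU")
  expect_true(all(one$freq %in% c(0, 1)))

  expect_warning(u <- build_pfm(character(0), motif_length = 4), "uniform")
  expect_equal(u$support, 0L)
  expect_true(all(u$freq == 0.25))
  expect_error(build_pfm(c("AC", "ACG")), "equal length")
})

test_that("activated amount averages above-threshold placements", {
  acts <- structure(
    list(act = matrix(c(
      # filter 1: counts 3 then 1 across two sequences (max 1 -> thr 0.5)
      1, 0.9, 0.8, 0, 0.7, 0, 0, 0,
      # filter 2: dead
      rep(0, 8)
    ), ncol = 2), n = 2, T = 4, F = 2, k = 3),
    class = "filter_activations"
  )
  am <- activated_amount(acts)
  expect_equal(am[1], 2.0)
  expect_equal(am[2], 0)
})

test_that("virtual pruning is pure and zero for disconnected filters", {
  spec <- sim_spec(40, 40,
    length = 21,
    planted_motifs = list(planted_motif("GGACU", "5p", 1)), seed = 2
  )
  d <- generate_dataset(spec)
  cfg <- model_config(
    conv_blocks = list(conv_block(4, 3, 2, 0)),
    fc_units = 4L, fc_dropout = 0, max_epochs = 3, seed = 1
  )
  mod <- train_on_samples(d$samples, cfg)
  X <- enac_encode_set(d$samples)
  p_before <- predict(mod, X)
  s <- impact_score(mod, X, 2)
  expect_gte(s, 0)
  # purity: the model is untouched by pruning
  expect_identical(predict(mod, X), p_before)

  # disconnect filter 1 downstream: zero its rows of the first FC layer
  Tl <- mod$arch$blocks[[1]]$T_pool
  mod2 <- mod
  mod2$params[["fc1.W"]][1:Tl, ] <- 0
  expect_equal(impact_score(mod2, X, 1), 0)

  # nullifying every filter makes predictions input-independent
  pall <- predict(nullify_filters(mod, "all"), X)
  expect_equal(length(unique(round(pall, 12))), 1)

  expect_error(impact_score(mod, X, 99), "out of range")
})

test_that("motif PCC, best-offset alignment and clustering behave", {
  a <- motif_pfm("GGACU")
  b <- motif_pfm("GGACU")
  expect_equal(motif_pcc(a, b), 1.0)

  uni <- motif_pfm(matrix(0.25, 5, 4))
  expect_true(is.na(motif_pcc(uni, a)))

  # anti-correlated pair: complementary one-hot columns
  x <- motif_pfm(matrix(rep(c(1, 0, 0, 0), 4), 4, 4, byrow = TRUE))
  yv <- motif_pfm(matrix(rep(c(0, 1 / 3, 1 / 3, 1 / 3), 4), 4, 4, byrow = TRUE))
  expect_lt(motif_pcc(x, yv), 0)

  # best-offset alignment finds the planted position
  long <- motif_pfm("AAGGACUAA")
  best <- motif_best_pcc(long, a)
  expect_equal(best$offset, 2)
  expect_gt(best$pcc, 0.9)

  z <- motif_pfm("AAAAA")
  cl <- cluster_motifs(list(a, b, z), k = 2)
  expect_equal(cl$labels[[1]], cl$labels[[2]]) # identical pair co-clusters
  expect_false(cl$labels[[1]] == cl$labels[[3]])
  expect_true(isSymmetric(cl$pcc))
  expect_equal(unname(diag(cl$pcc)), rep(1, 3))
  # label structure invariant under input reordering (up to relabeling)
  cl2 <- cluster_motifs(list(z, b, a), k = 2)
  expect_equal(cl2$labels[[2]], cl2$labels[[3]])
  expect_false(cl2$labels[[1]] == cl2$labels[[2]])
})

test_that("MEME export round-trips frequencies and supports empty lists", {
  f <- withr::local_tempfile(fileext = ".meme")
  pfm <- build_pfm(c("GGACU", "AGACU", "GGACU"), filter_index = 7)
  export_meme(list(pfm), f)
  back <- read_meme(f)
  expect_length(back, 1)
  expect_equal(unname(back[[1]]$freq), unname(round(pfm$freq, 6)),
    tolerance = 1e-6)
  expect_equal(back[[1]]$support, 3L)

  export_meme(list(), f)
  lines <- readLines(f)
  expect_true(any(grepl("MEME version", lines)))
  expect_false(any(grepl("MOTIF", lines)))

  bad <- pfm
  bad$freq[1, ] <- c(2, 0, 0, 0)
  expect_error(export_meme(list(bad), f), "sum to 1")
})
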