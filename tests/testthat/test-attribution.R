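# Closed-form oracles for the linear scorer: logit = <W, E> + b where E is
# the ENAC matrix and W the (rows x 4) weight matrix. Substituting base b
# at 1-based position p changes each encoded row covering p by
# (one_hot(b) - one_hot(x_p)) / window, so the logit change is
# sum over covering rows r of (W[r, b] - W[r, x_p]) / window.
linear_ism_oracle <- function(mod, sequence, output = "probability") {
  W <- linear_scorer_weights(mod)
  rows <- nrow(W)
  l <- rows + 1L
  chars <- strsplit(sequence, "")[[1]]
  bases <- c("A", "C", "G", "U")
  E <- enac_encode(sequence)
  logit0 <- sum(W * E) + mod$params[["out.b"]]
  map <- matrix(0, 4, l, dimnames = list(bases, NULL))
  for (p in seq_len(l)) {
    cover <- max(1, p - 1):min(rows, p)
    for (b in setdiff(bases, chars[p])) {
      dl <- sum(W[cover, b] - W[cover, chars[p]]) / 2
      map[b, p] <- if (output == "probability") {
        plogis(logit0 + dl) - plogis(logit0)
      } else {
        dl
      }
    }
  }
  map
}

linear_gradient_oracle <- function(mod, sequence, wrt = "probability") {
  W <- linear_scorer_weights(mod)
  rows <- nrow(W)
  l <- rows + 1L
  E <- enac_encode(sequence)
  logit0 <- sum(W * E) + mod$params[["out.b"]]
  scale <- if (wrt == "probability") plogis(logit0) * (1 - plogis(logit0)) else 1
  map <- matrix(0, 4, l, dimnames = list(c("A", "C", "G", "U"), NULL))
  for (p in seq_len(l)) {
    cover <- max(1, p - 1):min(rows, p)
    map[, p] <- scale * colSums(W[cover, , drop = FALSE]) / 2
  }
  map
}

test_that("ISM equals the closed-form weight-difference oracle exactly", {
  mod <- linear_scorer(14, seed = 11)
  samples <- random_drach_samples(3, length = 15, seed = 11)
  for (i in 1:3) {
    s <- samples$sequence[i]
    for (out in c("probability", "logit")) {
      got <- ism_attribution(mod, s, output = out)
      want <- linear_ism_oracle(mod, s, out)
      expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
    }
    # observed-base entries are structurally zero
    got <- ism_attribution(mod, s)
    chars <- strsplit(s, "")[[1]]
    expect_true(all(got[cbind(match(chars, c("A", "C", "G", "U")),
      seq_along(chars))] == 0))
  }
})

test_that("projected gradient equals its closed-form projection", {
  mod <- linear_scorer(14, seed = 12)
  samples <- random_drach_samples(3, length = 15, seed = 12)
  for (i in 1:3) {
    s <- samples$sequence[i]
    for (wrt in c("probability", "logit")) {
      got <- gradient_attribution(mod, s, wrt = wrt)
      want <- linear_gradient_oracle(mod, s, wrt)
      expect_equal(got, want, tolerance = 1e-10, ignore_attr = TRUE)
    }
  }
})

test_that("on the logit scale, ISM is the re-centered projected gradient", {
  # ENAC is affine in a single substitution, so for a linear scorer
  # ism[b, p] = grad[b, p] - grad[x_p, p] exactly (logit output).
  mod <- linear_scorer(20, seed = 13)
  s <- random_drach_samples(1, length = 21, seed = 13)$sequence
  ism <- ism_attribution(mod, s, output = "logit")
  grad <- gradient_attribution(mod, s, wrt = "logit")
  chars <- strsplit(s, "")[[1]]
  centered <- grad -
    matrix(grad[cbind(match(chars, c("A", "C", "G", "U")),
      seq_along(chars))], 4, length(chars), byrow = TRUE)
  # zero out observed-base entries to match the ISM convention
  centered[cbind(match(chars, c("A", "C", "G", "U")), seq_along(chars))] <- 0
  expect_equal(ism, centered, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("constant models yield all-zero attribution maps", {
  mod <- linear_scorer(14, seed = 14)
  mod$params[["out.W"]][] <- 0
  mod$params[["out.b"]] <- 0.3
  s <- random_drach_samples(1, length = 15, seed = 1)$sequence
  expect_true(all(ism_attribution(mod, s) == 0))
  expect_true(all(gradient_attribution(mod, s) == 0))
})

test_that("attribution maps have shape 4 x l and respect map algebra", {
  mod <- linear_scorer(200, seed = 15)
  s <- random_drach_samples(1, length = 201, seed = 2)$sequence
  g <- gradient_attribution(mod, s)
  expect_equal(dim(g), c(4, 201))

  m1 <- matrix(1:8 / 10, 4, 2)
  expect_equal(global_position_profile(list(m1, -m1)), c(0, 0))
  expect_equal(
    global_position_profile(list(m1)),
    colSums(abs(m1))
  )
  expect_error(global_position_profile(list()), "empty")
  expect_error(global_position_profile(list(m1, matrix(0, 4, 3))), "shape")
})

test_that("cosine similarity handles sign, orthogonality and zeros", {
  v <- c(1, 2, 3)
  expect_equal(attribution_similarity(v, v), 1)
  expect_equal(attribution_similarity(v, -v), -1)
  expect_equal(attribution_similarity(c(1, 0), c(0, 1)), 0)
  expect_true(is.na(attribution_similarity(v, c(0, 0, 0))))
  expect_error(attribution_similarity(v, c(1, 2)), "equal length")
})
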