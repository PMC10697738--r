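# Shared fixtures, all generated in code.

# Random A-centered DRACH windows (no planted signal).
random_drach_samples <- function(n, length = 21, seed = 42) {
  spec <- sim_spec(
    n_pos = ceiling(n / 2), n_neg = max(1, floor(n / 2)),
    length = length, seed = seed
  )
  d <- generate_dataset(spec)
  d$samples[seq_len(n), , drop = FALSE]
}

# A linear scorer over ENAC features: no conv blocks, no hidden FC layers,
# so logit = <flatten(E), w> + b. Weights are seeded random; exact closed
# forms for ISM and gradient attribution exist for this model.
linear_scorer <- function(rows, seed = 7, bias = 0.2) {
  cfg <- model_config(
    conv_blocks = list(), fc_units = integer(0), fc_dropout = 0,
    max_epochs = 1, seed = seed
  )
  mod <- build_model(cfg, c(rows, 4L))
  set.seed(seed)
  mod$params[["out.W"]] <- matrix(rnorm(rows * 4, sd = 0.5), rows * 4, 1)
  mod$params[["out.b"]] <- bias
  mod$trained <- TRUE
  mod
}

# Weight of the linear scorer reshaped to (rows x 4) in channel order
# A,C,G,U. The flatten convention is channel-major blocks of `rows`
# columns: flat index (c-1)*rows + t.
linear_scorer_weights <- function(mod) {
  rows <- mod$input_shape[1]
  matrix(mod$params[["out.W"]], nrow = rows, ncol = 4,
    dimnames = list(NULL, c("A", "C", "G", "U")))
}

# Cached heavyweight experiments shared across test files (training is the
# slow part; every consumer reads the same frozen protocol).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Planted-motif benchmark: 2000 + 2000 windows of length 101, GGACU
# planted uniformly in the 5' flank of positives at rate 0.9; small-preset
# model trained for at most 20 epochs on the 90% training split.
planted_experiment <- function() {
  cached("planted_experiment", {
    spec <- sim_spec(2000, 2000,
      length = 101,
      planted_motifs = list(planted_motif("GGACU", "5p", 0.9)), seed = 1
    )
    d <- generate_dataset(spec)
    sp <- split_train_test(d$samples, 0.9, seed = 1)
    model <- train_on_samples(sp$train, model_preset("small", seed = 1))
    prob <- predict(model, sp$test)
    list(
      data = d, train = sp$train, test = sp$test,
      model = model, prob = prob,
      auc = roc_auc(sp$test$label, prob)
    )
  })
}

# Same protocol with insertion rate 0: the two classes are exchangeable.
null_experiment <- function() {
  cached("null_experiment", {
    spec <- sim_spec(2000, 2000,
      length = 101,
      planted_motifs = list(planted_motif("GGACU", "5p", 0)), seed = 1
    )
    d <- generate_dataset(spec)
    sp <- split_train_test(d$samples, 0.9, seed = 1)
    model <- train_on_samples(sp$train, model_preset("small", seed = 1))
    prob <- predict(model, sp$test)
    list(test = sp$test, model = model, prob = prob,
      auc = roc_auc(sp$test$label, prob))
  })
}

# Filter-level interpretation report on the planted experiment's test set.
planted_filter_report <- function() {
  cached("planted_filter_report", {
    e <- planted_experiment()
    filter_report(e$model, e$test)
  })
}
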