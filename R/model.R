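#' Define one convolution block
#'
#' A block is a 1-D valid convolution along the encoded-window axis,
#' followed by ReLU, non-overlapping max pooling and dropout.
#'
#' @param n_filters number of filters (default 64, the first-layer width
#'   used for motif extraction).
#' @param kernel_rows number of encoded rows the kernel spans.
#' @param pool max-pooling width.
#' @param dropout dropout fraction in `[0, 1)`.
#' @return a `conv_block` spec list.
#' @export
conv_block <- function(n_filters = 64, kernel_rows = 5, pool = 2,
                       dropout = 0.2) {
  stopifnot(n_filters >= 1, kernel_rows >= 1, pool >= 1,
    dropout >= 0, dropout < 1)
  structure(
    list(n_filters = as.integer(n_filters),
      kernel_rows = as.integer(kernel_rows),
      pool = as.integer(pool), dropout = dropout),
    class = "conv_block"
  )
}

#' Model configuration
#'
#' Capacity and optimisation settings for the convolutional classifier:
#' a stack of convolution blocks, fully connected ReLU layers with dropout,
#' and a single sigmoid output unit trained with binary cross-entropy and
#' Adam. `conv_blocks = list()` together with `fc_units = integer(0)`
#' yields a plain linear scorer over the encoded input (useful as an exact
#' reference for attribution methods).
#'
#' @param conv_blocks list of [conv_block()] specs.
#' @param fc_units integer vector of hidden fully-connected layer widths.
#' @param fc_dropout dropout applied after each hidden FC layer.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs training epochs.
#' @param early_stop_patience if non-`NULL`, stop when the held-out
#'   validation loss has not improved for this many epochs (default off).
#' @param validation_fraction fraction held out when early stopping is on.
#' @param seed seed for parameter initialisation, shuffling and dropout.
#' @return a `model_config` list.
#' @export
model_config <- function(conv_blocks = list(conv_block()),
                         fc_units = 32L, fc_dropout = 0.3,
                         learning_rate = 1e-3, batch_size = 64L,
                         max_epochs = 20L, early_stop_patience = NULL,
                         validation_fraction = 0.1, seed = 1L) {
  stopifnot(fc_dropout >= 0, fc_dropout < 1, learning_rate > 0,
    batch_size >= 1, max_epochs >= 1)
  structure(
    list(
      conv_blocks = conv_blocks, fc_units = as.integer(fc_units),
      fc_dropout = fc_dropout, learning_rate = learning_rate,
      batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
      early_stop_patience = early_stop_patience,
      validation_fraction = validation_fraction, seed = as.integer(seed)
    ),
    class = "model_config"
  )
}

#' Capacity presets keyed on training-set size
#'
#' Three ready-made configurations aligning model complexity with data
#' volume, in the spirit of adjusting convolution-block and FC sizes per
#' condition. `small` is sized for a few thousand training windows and
#' trains in minutes on one CPU core.
#'
#' @param size one of `"small"`, `"medium"`, `"large"`.
#' @param seed seed stored in the config.
#' @return a [model_config()].
#' @export
model_preset <- function(size = c("small", "medium", "large"), seed = 1L) {
  size <- match.arg(size)
  switch(size,
    small = model_config(
      conv_blocks = list(conv_block(64, 5, 4, 0.2)),
      fc_units = 32L, fc_dropout = 0.3, learning_rate = 3e-3,
      max_epochs = 20L, seed = seed
    ),
    medium = model_config(
      conv_blocks = list(conv_block(64, 5, 2, 0.2), conv_block(32, 3, 2, 0.25)),
      fc_units = 64L, fc_dropout = 0.3, max_epochs = 30L, seed = seed
    ),
    large = model_config(
      conv_blocks = list(conv_block(64, 7, 2, 0.2), conv_block(64, 5, 2, 0.25)),
      fc_units = c(128L, 32L), fc_dropout = 0.4, max_epochs = 40L, seed = seed
    )
  )
}

# Propagate shapes through the architecture; errors if pooling exhausts the
# sequence axis.
compute_arch <- function(config, input_shape) {
  rows <- as.integer(input_shape[1])
  stopifnot(length(input_shape) == 2, input_shape[2] == 4, rows >= 1)
  Tcur <- rows
  C <- 4L
  blocks <- list()
  for (bi in seq_along(config$conv_blocks)) {
    blk <- config$conv_blocks[[bi]]
    T_conv <- Tcur - blk$kernel_rows + 1L
    if (T_conv < 1L) {
      stop(sprintf("kernel of %d rows does not fit %d input rows",
        blk$kernel_rows, Tcur))
    }
    T_pool <- T_conv %/% blk$pool
    if (T_pool < 1L) {
      stop(sprintf("pool size %d reduces %d conv rows below 1",
        blk$pool, T_conv))
    }
    blocks[[bi]] <- list(
      k = blk$kernel_rows, F = blk$n_filters, pool = blk$pool,
      dropout = blk$dropout, C_in = C, T_in = Tcur,
      T_conv = T_conv, T_pool = T_pool
    )
    Tcur <- T_pool
    C <- blk$n_filters
  }
  list(blocks = blocks, flat_dim = Tcur * C, T_last = Tcur, C_last = C)
}

#' Build an (untrained) convolutional classifier
#'
#' Instantiates the network `[conv -> ReLU -> maxpool -> dropout] x k ->
#' flatten -> FC(ReLU, dropout) -> sigmoid unit` with He-initialised
#' weights, seeded from `config$seed` so identical configs give identical
#' initial parameters.
#'
#' @param config a [model_config()].
#' @param input_shape `c(rows, 4)`: shape of the ENAC matrix (for a
#'   sequence of length L with window 2, `rows = L - 1`).
#' @return an object of class `m6a_cnn`.
#' @export
build_model <- function(config, input_shape) {
  arch <- compute_arch(config, input_shape)
  params <- list()
  with_rng_seed(config$seed, {
    for (bi in seq_along(arch$blocks)) {
      blk <- arch$blocks[[bi]]
      fan_in <- blk$k * blk$C_in
      params[[paste0("conv", bi, ".W")]] <-
        matrix(stats::rnorm(fan_in * blk$F, sd = sqrt(2 / fan_in)),
          fan_in, blk$F)
      params[[paste0("conv", bi, ".b")]] <- numeric(blk$F)
    }
    d_in <- arch$flat_dim
    for (j in seq_along(config$fc_units)) {
      u <- config$fc_units[j]
      params[[paste0("fc", j, ".W")]] <-
        matrix(stats::rnorm(d_in * u, sd = sqrt(2 / d_in)), d_in, u)
      # slightly positive biases keep ReLU units alive early; with
      # non-negative pooled inputs a dead unit receives no gradient and
      # the dead state is absorbing
      params[[paste0("fc", j, ".b")]] <- rep(0.05, u)
      d_in <- u
    }
    # small-scale head: initial predictions start near 0.5, avoiding the
    # violent first-epoch compression that can kill every hidden unit
    params[["out.W"]] <- matrix(stats::rnorm(d_in, sd = 0.01), d_in, 1)
    params[["out.b"]] <- 0
  })
  structure(
    list(config = config, input_shape = as.integer(input_shape),
      arch = arch, params = params, history = NULL, trained = FALSE),
    class = "m6a_cnn"
  )
}

# --- forward / backward ----------------------------------------------------

# Activations are stored as (N*T) x C matrices with row index
# (n-1)*T + t (position fastest within sample), which lets convolution be a
# single im2col + matmul per block.

im2col_rows <- function(N, T_in, T_conv) {
  rep((0:(N - 1)) * T_in, each = T_conv) + seq_len(T_conv)
}

cnn_forward <- function(model, X, training = FALSE, keep_cache = FALSE) {
  if (is.matrix(X)) X <- array(X, c(1L, dim(X)))
  N <- dim(X)[1]
  T0 <- dim(X)[2]
  if (T0 != model$input_shape[1]) {
    stop(sprintf("input has %d encoded rows, model expects %d",
      T0, model$input_shape[1]))
  }
  A <- matrix(aperm(X, c(2, 1, 3)), ncol = 4) # (N*T0) x 4
  cache <- if (keep_cache) list(N = N) else NULL
  Tcur <- T0
  C <- 4L
  for (bi in seq_along(model$arch$blocks)) {
    blk <- model$arch$blocks[[bi]]
    k <- blk$k; Fb <- blk$F; p <- blk$pool
    T_conv <- blk$T_conv; T_pool <- blk$T_pool
    M <- matrix(0, N * T_conv, k * C)
    base <- im2col_rows(N, Tcur, T_conv)
    for (j in seq_len(k)) {
      M[, ((j - 1L) * C + 1L):(j * C)] <- A[base + (j - 1L), , drop = FALSE]
    }
    W <- model$params[[paste0("conv", bi, ".W")]]
    b <- model$params[[paste0("conv", bi, ".b")]]
    Z <- M %*% W + matrix(b, N * T_conv, Fb, byrow = TRUE)
    H <- Z
    H[H < 0] <- 0
    startrow <- rep((0:(N - 1)) * T_conv, each = T_pool) +
      rep(seq(1L, by = p, length.out = T_pool), N)
    P <- H[startrow, , drop = FALSE]
    argrow <- matrix(startrow, N * T_pool, Fb)
    if (p > 1L) {
      for (o in seq_len(p - 1L)) {
        cand <- H[startrow + o, , drop = FALSE]
        upd <- cand > P
        if (any(upd)) {
          P[upd] <- cand[upd]
          RI <- matrix(startrow + o, N * T_pool, Fb)
          argrow[upd] <- RI[upd]
        }
      }
    }
    mask <- NULL
    if (training && blk$dropout > 0) {
      mask <- matrix(
        (stats::runif(length(P)) >= blk$dropout) / (1 - blk$dropout),
        nrow(P), ncol(P)
      )
      P <- P * mask
    }
    if (keep_cache) {
      cache[[paste0("block", bi)]] <- list(
        M = M, Zpos = Z > 0, argrow = argrow, mask = mask,
        T_in = Tcur, C_in = C
      )
    }
    A <- P
    Tcur <- T_pool
    C <- Fb
  }
  # flatten to N x (T*C), channel-major blocks of T columns
  Flat <- matrix(0, N, Tcur * C)
  for (f in seq_len(C)) {
    Flat[, ((f - 1L) * Tcur + 1L):(f * Tcur)] <-
      matrix(A[, f], nrow = N, byrow = TRUE)
  }
  if (keep_cache) {
    cache$T_last <- Tcur
    cache$C_last <- C
    cache$fc <- list()
  }
  for (j in seq_along(model$config$fc_units)) {
    W <- model$params[[paste0("fc", j, ".W")]]
    b <- model$params[[paste0("fc", j, ".b")]]
    Zf <- Flat %*% W + matrix(b, N, length(b), byrow = TRUE)
    Hf <- Zf
    Hf[Hf < 0] <- 0
    mask <- NULL
    q <- model$config$fc_dropout
    if (training && q > 0) {
      mask <- matrix((stats::runif(length(Hf)) >= q) / (1 - q),
        nrow(Hf), ncol(Hf))
      Hf <- Hf * mask
    }
    if (keep_cache) {
      cache$fc[[j]] <- list(input = Flat, Zpos = Zf > 0, mask = mask)
    }
    Flat <- Hf
  }
  logit <- drop(Flat %*% model$params[["out.W"]]) + model$params[["out.b"]]
  if (keep_cache) cache$out_input <- Flat
  list(prob = stats::plogis(logit), logit = logit, cache = cache)
}

cnn_backward <- function(model, cache, dlogit, input_grad = FALSE) {
  N <- cache$N
  grads <- list()
  d <- matrix(dlogit, ncol = 1)
  grads[["out.W"]] <- crossprod(cache$out_input, d)
  grads[["out.b"]] <- sum(d)
  dH <- d %*% t(model$params[["out.W"]])
  for (j in rev(seq_along(model$config$fc_units))) {
    fc <- cache$fc[[j]]
    if (!is.null(fc$mask)) dH <- dH * fc$mask
    dZ <- dH * fc$Zpos
    grads[[paste0("fc", j, ".W")]] <- crossprod(fc$input, dZ)
    grads[[paste0("fc", j, ".b")]] <- colSums(dZ)
    dH <- dZ %*% t(model$params[[paste0("fc", j, ".W")]])
  }
  # unflatten N x (T*C) -> (N*T) x C
  Tl <- cache$T_last
  Cl <- cache$C_last
  dA <- matrix(0, N * Tl, Cl)
  for (f in seq_len(Cl)) {
    dA[, f] <- as.vector(t(dH[, ((f - 1L) * Tl + 1L):(f * Tl), drop = FALSE]))
  }
  blocks <- model$arch$blocks
  for (bi in rev(seq_along(blocks))) {
    blk <- blocks[[bi]]
    bc <- cache[[paste0("block", bi)]]
    if (!is.null(bc$mask)) dA <- dA * bc$mask
    # scatter pooled grads back to conv rows
    dHc <- matrix(0, N * blk$T_conv, blk$F)
    for (f in seq_len(blk$F)) {
      col <- numeric(N * blk$T_conv)
      col[bc$argrow[, f]] <- dA[, f]
      dHc[, f] <- col
    }
    dZ <- dHc * bc$Zpos
    grads[[paste0("conv", bi, ".W")]] <- crossprod(bc$M, dZ)
    grads[[paste0("conv", bi, ".b")]] <- colSums(dZ)
    if (bi > 1L || input_grad) {
      W <- model$params[[paste0("conv", bi, ".W")]]
      dM <- dZ %*% t(W)
      dPrev <- matrix(0, N * bc$T_in, bc$C_in)
      base <- im2col_rows(N, bc$T_in, blk$T_conv)
      for (j in seq_len(blk$k)) {
        rows <- base + (j - 1L)
        cols <- ((j - 1L) * bc$C_in + 1L):(j * bc$C_in)
        dPrev[rows, ] <- dPrev[rows, ] + dM[, cols, drop = FALSE]
      }
      dA <- dPrev
    }
  }
  out <- list(grads = grads)
  if (input_grad) {
    T0 <- model$input_shape[1]
    out$dX <- aperm(array(dA, c(T0, N, 4)), c(2, 1, 3))
  }
  out
}

bce_loss <- function(prob, y) {
  eps <- 1e-12
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the classifier with binary cross-entropy and Adam
#'
#' Minimises BCE over minibatches with the Adam optimiser; fully seeded
#' (shuffling and dropout draw from the RNG stream seeded by
#' `config$seed`). When `config$early_stop_patience` is set, a stratified
#' validation fraction is held out and training stops once validation loss
#' has not improved for that many epochs, restoring the best parameters.
#'
#' @param model an untrained [build_model()] object.
#' @param X encoded inputs: array `(n, rows, 4)` from [enac_encode_set()].
#' @param y labels (any form accepted by [as_binary_label()]).
#' @param epochs override for `config$max_epochs`.
#' @param max_restarts networks whose hidden ReLU units all die produce
#'   constant predictions and receive no gradient, an absorbing state;
#'   when detected (zero variance of training-set predictions) training
#'   restarts from a reseeded initialisation, at most this many times.
#' @return the trained model, with `history` (per-epoch losses; epoch 0 is
#'   the loss at initialisation).
#' @export
train_model <- function(model, X, y, epochs = NULL, max_restarts = 3L) {
  for (attempt in 0:max_restarts) {
    mod <- if (attempt == 0) {
      model
    } else {
      cfg2 <- model$config
      cfg2$seed <- cfg2$seed + attempt * 1009L
      build_model(cfg2, model$input_shape)
    }
    fit <- train_model_once(mod, X, y, epochs)
    if (!fit$collapsed) return(fit$model)
  }
  warning("training ended in the dead-ReLU state after ", max_restarts,
    " restart(s); returning the final attempt")
  fit$model
}

train_model_once <- function(model, X, y, epochs = NULL) {
  y <- as_binary_label(y)
  if (length(unique(y)) < 2) stop("training set contains a single class")
  if (is.matrix(X)) X <- array(X, c(1L, dim(X)))
  stopifnot(dim(X)[1] == length(y))
  cfg <- model$config
  if (is.null(epochs)) epochs <- cfg$max_epochs
  n <- dim(X)[1]

  val_idx <- integer(0)
  patience <- cfg$early_stop_patience
  hist <- list()
  collapsed <- FALSE
  with_rng_seed(cfg$seed + 1L, {
    if (!is.null(patience)) {
      nv <- max(2L, round(cfg$validation_fraction * n))
      val_idx <- sample(n, nv)
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- X[tr_idx, , , drop = FALSE]
    ytr <- y[tr_idx]
    state <- adam_init(model$params)
    pred_sd <- NA_real_
    full_loss <- function() {
      fw <- cnn_forward(model, Xtr, training = FALSE)
      pred_sd <<- stats::sd(fw$prob)
      bce_loss(fw$prob, ytr)
    }
    val_loss <- function() {
      if (!length(val_idx)) return(NA_real_)
      fw <- cnn_forward(model, X[val_idx, , , drop = FALSE], training = FALSE)
      bce_loss(fw$prob, y[val_idx])
    }
    hist[[1]] <- data.frame(epoch = 0L, train_loss = full_loss(),
      val_loss = val_loss())
    best_val <- Inf
    best_params <- NULL
    stall <- 0L
    ntr <- length(tr_idx)
    for (ep in seq_len(epochs)) {
      ord <- sample(ntr)
      starts <- seq(1L, ntr, by = cfg$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, ntr)]
        if (length(idx) < 2L) next
        fw <- cnn_forward(model, Xtr[idx, , , drop = FALSE],
          training = TRUE, keep_cache = TRUE)
        dlogit <- (fw$prob - ytr[idx]) / length(idx)
        bw <- cnn_backward(model, fw$cache, dlogit)
        upd <- adam_step(model$params, bw$grads, state, cfg$learning_rate)
        model$params <- upd$params
        state <- upd$state
      }
      vl <- val_loss()
      hist[[ep + 1L]] <- data.frame(epoch = ep, train_loss = full_loss(),
        val_loss = vl)
      if (pred_sd < 1e-10 && ep >= 1L) {
        collapsed <- TRUE
        break
      }
      if (!is.null(patience)) {
        if (vl < best_val - 1e-6) {
          best_val <- vl
          best_params <- model$params
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= patience) break
        }
      }
    }
    if (!is.null(patience) && !is.null(best_params)) {
      model$params <- best_params
    }
  })
  model$history <- do.call(rbind, hist)
  model$trained <- TRUE
  list(model = model, collapsed = collapsed)
}

#' Predict modification probabilities
#'
#' Deterministic inference (dropout disabled). Accepts a sample data.frame
#' (encoded internally), a single ENAC matrix, or a pre-encoded array.
#'
#' @param object a trained `m6a_cnn`.
#' @param newdata samples, matrix or array.
#' @param type `"prob"` (default) for sigmoid probabilities in `[0, 1]`, or
#'   `"logit"` for the pre-sigmoid score.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.m6a_cnn <- function(object, newdata, type = c("prob", "logit"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) newdata <- enac_encode_set(newdata)
  fw <- cnn_forward(object, newdata, training = FALSE)
  if (type == "prob") fw$prob else fw$logit
}

#' Train end-to-end from a sample table
#'
#' Convenience wrapper: encodes the samples, builds the model for the
#' implied input shape and trains it.
#'
#' @param samples sample data.frame (`id`, `sequence`, `label`).
#' @param config a [model_config()]; default: the `"small"` preset.
#' @param epochs optional override of `config$max_epochs`.
#' @return trained `m6a_cnn`.
#' @export
train_on_samples <- function(samples, config = model_preset("small"),
                             epochs = NULL) {
  validate_samples(samples)
  X <- enac_encode_set(samples)
  model <- build_model(config, c(dim(X)[2], 4L))
  train_model(model, X, samples$label, epochs = epochs)
}
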