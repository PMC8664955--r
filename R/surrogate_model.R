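LAYER_REGISTRY <- c("embedding", "cnn", "pool", "birnn", "dense1", "dense2")

#' Configuration of the surrogate network
#'
#' A deliberately small hybrid network: one-hot input -> linear embedding ->
#' 1-D convolution (valid padding, ReLU) -> max pooling -> bidirectional GRU
#' -> two dense layers ending in a single sigmoid probability. Trained with
#' Adam on binary cross-entropy; dropout acts on the first dense layer
#' during training only, so interpretation passes are deterministic.
#'
#' @param embed_dim Embedding width.
#' @param n_filters Convolution feature maps.
#' @param kernel_len Convolution kernel length (nt). The default (40) spans
#'   the miRNA/target junction of the concatenated encoding, so a single
#'   ReLU filter can express a miRNA letter and its duplex partner jointly
#'   (a match conjunction); short kernels confine filters to one track and
#'   force the recurrent layer to carry the comparison over long spans,
#'   which trains far less reliably at desk-scale sample sizes.
#' @param pool_len Max-pooling window (non-overlapping).
#' @param rnn_hidden GRU hidden units per direction.
#' @param dense_sizes Dense layer widths; must end in 1.
#' @param dropout Dropout probability on the first dense layer.
#' @param epochs,batch_size,learning_rate Training regime.
#' @param weight_decay Decoupled (AdamW-style) weight decay on the weight
#'   matrices; the pressure that favours the generalising comparison
#'   features over memorisation of the training pairs.
#' @param input_mask_prob Occlusion augmentation: probability that a non-pad
#'   input row is masked to `N` during training (only). Prevents the
#'   recurrent layers from memorising exact sequences and mirrors the
#'   occlusion regime under which the model is later interrogated.
#' @param mlm_weight Weight of the masked-letter reconstruction loss: a
#'   self-supervised head on the BiRNN outputs predicts the letter at each
#'   masked row. For a true miRNA:target pair a masked target letter is
#'   predictable only through the cross-track complement relation, so this
#'   dense per-position signal steers the recurrent layers toward duplex
#'   comparison features that the single pair label alone reveals slowly.
#'   Set to 0 (or `input_mask_prob = 0`) to disable.
#' @param train_seed Seed for initialisation, shuffling and dropout masks.
#' @return An object of class `model_config`.
#' @export
model_config <- function(embed_dim = 8L, n_filters = 16L, kernel_len = 40L,
                         pool_len = 2L, rnn_hidden = 16L,
                         dense_sizes = c(16L, 1L), dropout = 0.2,
                         epochs = 60L, batch_size = 32L,
                         learning_rate = 2e-3, weight_decay = 1e-3,
                         input_mask_prob = 0.15, mlm_weight = 0,
                         train_seed = 1L) {
  stopifnot(embed_dim > 0, n_filters > 0, kernel_len > 0, pool_len > 0,
            rnn_hidden > 0, length(dense_sizes) == 2L,
            dense_sizes[[2]] == 1L, dropout >= 0, dropout < 1,
            epochs >= 0, batch_size > 0, learning_rate > 0,
            weight_decay >= 0, input_mask_prob >= 0, input_mask_prob < 1,
            mlm_weight >= 0)
  structure(list(embed_dim = as.integer(embed_dim),
                 n_filters = as.integer(n_filters),
                 kernel_len = as.integer(kernel_len),
                 pool_len = as.integer(pool_len),
                 rnn_hidden = as.integer(rnn_hidden),
                 dense_sizes = as.integer(dense_sizes),
                 dropout = dropout, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 input_mask_prob = input_mask_prob,
                 mlm_weight = mlm_weight,
                 train_seed = as.integer(train_seed)),
            class = "model_config")
}

model_dims <- function(config, profile) {
  rows <- profile$mirna_pad_len + profile$target_pad_len
  conv_pos <- rows - config$kernel_len + 1L
  if (conv_pos < config$pool_len)
    stop("input too short for the convolution/pooling geometry")
  timesteps <- conv_pos %/% config$pool_len
  list(rows = rows, conv_pos = conv_pos, timesteps = timesteps)
}

init_params <- function(config, profile) {
  d <- config$embed_dim; F <- config$n_filters; K <- config$kernel_len
  H <- config$rnn_hidden; D1 <- config$dense_sizes[[1]]
  dims <- model_dims(config, profile)
  glorot <- function(nr, nc) {
    matrix(rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
  }
  # orthogonal blocks for the recurrent weights (one per gate): preserves
  # state norms over long spans, a standard recurrent initialisation
  ortho_gates <- function(H) {
    do.call(cbind, lapply(1:3, function(i) qr.Q(qr(matrix(rnorm(H * H), H, H)))))
  }
  # update-gate bias starts negative so states persist across the long span
  # between the miRNA and target tracks (the memory-friendly analogue of
  # the LSTM forget-gate bias initialisation)
  bgru <- c(rep(-2, H), numeric(2L * H))
  with_seed(config$train_seed, list(
    E = glorot(5L, d),
    Wc = glorot(K * d, F), bc = numeric(F),
    Wf = glorot(F, 3L * H), Uf = ortho_gates(H), bf = bgru,
    Wb = glorot(F, 3L * H), Ub = ortho_gates(H), bb = bgru,
    W1 = glorot(2L * H, D1), b1 = numeric(D1),
    W2 = glorot(D1, 1L), b2 = numeric(1L),
    Wm = glorot(2L * H, 4L), bm = numeric(4L),
    kernel_len = K, pool_len = config$pool_len))
}

#' Train the surrogate network
#'
#' Encodes the pair table for the given profile, splits 80/20 into
#' training/held-out sets (derived from `train_seed`), runs Adam on binary
#' cross-entropy, and reports held-out accuracy at threshold 0.5. With
#' `epochs = 0` the randomly initialised network is returned untrained.
#'
#' @param pairs Pair table with both classes present.
#' @param profile A [dataset_profile()]; the model predicts only on inputs
#'   of this profile.
#' @param config A [model_config()].
#' @return An object of class `mitar_surrogate` with elements `params`,
#'   `config`, `profile`, `layers` (the named-layer registry),
#'   `heldout_accuracy`, `loss`.
#' @export
train_surrogate <- function(pairs, profile = dataset_profile(),
                            config = model_config()) {
  y <- as.numeric(pairs$label == "positive")
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes")
  arr <- encode_table(pairs, profile)
  n <- length(y)
  idx <- with_seed(config$train_seed, sample.int(n))
  n_tr <- max(1L, floor(0.8 * n))
  tr <- idx[seq_len(n_tr)]; ho <- idx[-seq_len(n_tr)]
  params <- init_params(config, profile)
  losses <- numeric(0)
  mlm_losses <- numeric(0)
  if (config$epochs > 0L) {
    fit <- cpp_surrogate_train(params, arr[, , tr, drop = FALSE], y[tr],
                               config$epochs, config$batch_size,
                               config$learning_rate, config$dropout,
                               config$train_seed, 5.0, config$weight_decay,
                               config$input_mask_prob, config$mlm_weight)
    params <- fit$params
    losses <- fit$loss
    mlm_losses <- fit$mlm_loss
  }
  model <- structure(list(params = params, config = config, profile = profile,
                          layers = LAYER_REGISTRY, loss = losses,
                          mlm_loss = mlm_losses),
                     class = "mitar_surrogate")
  if (length(ho)) {
    p <- predict_proba(model, arr[, , ho, drop = FALSE])
    model$heldout_accuracy <- mean((p > 0.5) == y[ho])
    model$heldout_n <- length(ho)
  }
  model
}

#' @export
print.mitar_surrogate <- function(x, ...) {
  acc <- if (is.null(x$heldout_accuracy)) "NA"
         else sprintf("%.3f", x$heldout_accuracy)
  cat(sprintf(paste0("<mitar_surrogate: profile '%s', %d filters, ",
                     "GRU %d/dir, held-out accuracy %s>\n"),
              x$profile$name, x$config$n_filters, x$config$rnn_hidden, acc))
  invisible(x)
}

as_input_array <- function(inputs, model = NULL) {
  if (is.array(inputs) && length(dim(inputs)) == 3L) return(inputs)
  if (is.matrix(inputs)) return(array(inputs, dim = c(dim(inputs), 1L)))
  if (is.list(inputs)) {
    if (!length(inputs)) return(NULL)
    arr <- array(0, dim = c(dim(inputs[[1]]), length(inputs)),
                 dimnames = c(dimnames(inputs[[1]]), list(NULL)))
    for (i in seq_along(inputs)) arr[, , i] <- inputs[[i]]
    return(arr)
  }
  stop("inputs must be an encoded matrix, a list of them, or a 3-D array")
}

#' Prediction probability of being a true target site
#'
#' A pure function of (model, input): repeated calls in evaluation mode
#' agree bitwise. Dispatches on the model class so that analytic toy models
#' (see [fn_model()]) can stand in for the network in tests and oracles.
#'
#' @param model A trained model (or [fn_model()]).
#' @param inputs Encoded matrix, list of matrices, or 3-D array from
#'   [encode_table()].
#' @param ... Passed to methods.
#' @return Numeric vector of probabilities in `[0, 1]`, one per input.
#' @export
predict_proba <- function(model, inputs, ...) UseMethod("predict_proba")

#' @export
predict_proba.mitar_surrogate <- function(model, inputs, ...) {
  arr <- as_input_array(inputs)
  if (is.null(arr)) return(numeric(0))
  expect_rows <- model$profile$mirna_pad_len + model$profile$target_pad_len
  if (dim(arr)[[1]] != expect_rows)
    stop(sprintf("input has %d rows; model profile '%s' expects %d",
                 dim(arr)[[1]], model$profile$name, expect_rows))
  as.numeric(cpp_surrogate_predict(model$params, arr))
}

#' Analytic model wrapper for tests and oracles
#'
#' Wraps an R function `fn(encoded_matrix) -> probability` as a model usable
#' wherever a trained surrogate is: constant models, additive
#' per-position-intactness models, logical-AND models.
#'
#' @param fn Function of one encoded matrix returning a probability.
#' @param profile The [dataset_profile()] the function expects.
#' @return An object of class `fn_model`.
#' @export
fn_model <- function(fn, profile = dataset_profile()) {
  structure(list(fn = fn, profile = profile), class = "fn_model")
}

#' @export
predict_proba.fn_model <- function(model, inputs, ...) {
  arr <- as_input_array(inputs)
  if (is.null(arr)) return(numeric(0))
  vapply(seq_len(dim(arr)[[3]]),
         function(i) model$fn(arr[, , i, drop = TRUE]), numeric(1))
}

#' Named-layer activations from the prediction forward pass
#'
#' Captures per-pair unit activations on the same forward pass used by
#' [predict_proba()]; re-running prediction afterwards gives identical
#' probabilities. The `cnn` (and `pool`) tensors carry a
#' `(feature_map, position)` factorisation as attribute `fmap_dims`, with
#' unit columns ordered map-major (`f1_p1 ... f1_pP, f2_p1, ...`).
#'
#' The registry is `embedding, cnn, pool, birnn, dense1, dense2`; the
#' `birnn` units are the final hidden state of each direction (one value per
#' hidden unit per pair).
#'
#' @param model A trained `mitar_surrogate`.
#' @param inputs Encoded inputs as for [predict_proba()].
#' @param layer_name One of the registry names.
#' @return Matrix `n_pairs x units` of class `activation_tensor` with
#'   attributes `layer`, `prob` (the matched probabilities), and for
#'   cnn/pool `fmap_dims = c(maps, positions)`.
#' @export
layer_outputs <- function(model, inputs, layer_name) {
  stopifnot(inherits(model, "mitar_surrogate"))
  if (!layer_name %in% LAYER_REGISTRY)
    stop(sprintf("unknown layer '%s'; registry: %s", layer_name,
                 paste(LAYER_REGISTRY, collapse = ", ")))
  arr <- as_input_array(inputs)
  cap <- cpp_surrogate_capture(model$params, arr)
  B <- dim(arr)[[3]]
  out <- switch(layer_name,
    embedding = {
      cube <- cap$embedding # R x d x B
      t(apply(cube, 3L, as.numeric))
    },
    cnn = {
      cube <- cap$cnn # P x F x B; vec(P x F) is position-fastest, map-major
      m <- t(apply(cube, 3L, as.numeric))
      attr(m, "fmap_dims") <- c(maps = dim(cube)[[2]], positions = dim(cube)[[1]])
      colnames(m) <- as.vector(outer(seq_len(dim(cube)[[1]]),
                                     seq_len(dim(cube)[[2]]),
                                     function(p, f) sprintf("f%d_p%d", f, p)))
      m
    },
    pool = {
      cube <- cap$pool # B x F x T
      Fm <- dim(cube)[[2]]; Tm <- dim(cube)[[3]]
      m <- matrix(0, B, Fm * Tm)
      for (f in seq_len(Fm))
        m[, (f - 1L) * Tm + seq_len(Tm)] <- cube[, f, ]
      attr(m, "fmap_dims") <- c(maps = Fm, positions = Tm)
      m
    },
    birnn = cap$birnn,
    dense1 = cap$dense1,
    dense2 = cap$dense2)
  if (B == 1L && is.null(dim(out))) out <- matrix(out, nrow = 1L)
  attr(out, "layer") <- layer_name
  attr(out, "prob") <- as.numeric(cap$prob)
  class(out) <- c("activation_tensor", class(out))
  out
}

#' Save / load a trained surrogate
#'
#' The network weights are written as the backend's native serialised R
#' object plus a JSON sidecar recording the configuration and profile.
#'
#' @param model A `mitar_surrogate`.
#' @param dir Directory to hold `model.rds` and `model.json`.
#' @return `save_surrogate()`: `dir`, invisibly; `load_surrogate()`: the
#'   model.
#' @export
save_surrogate <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "model.rds"))
  meta <- list(config = unclass(model$config), profile = unclass(model$profile),
               heldout_accuracy = model$heldout_accuracy)
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname save_surrogate
#' @export
load_surrogate <- function(dir) readRDS(file.path(dir, "model.rds"))
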