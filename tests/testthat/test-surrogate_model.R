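small_cfg <- function(...) {
  args <- list(embed_dim = 3L, n_filters = 4L, kernel_len = 4L, pool_len = 2L,
               rnn_hidden = 3L, dense_sizes = c(4L, 1L), dropout = 0,
               epochs = 2L, batch_size = 4L, train_seed = 5L)
  do.call(model_config, utils::modifyList(args, list(...)))
}
small_prof <- dataset_profile("small", 10, 12)
small_data <- function(seed = 19, n = 16) {
  rule <- planted_rule(regions = list(list(start = 2, len = 3, complement_prob = 1)),
                       mirna_len_range = c(8, 10), site_len = 8, flank = 2)
  generate_dataset(n / 2, n / 2, rule, small_prof, seed = seed)$pairs
}

test_that("training validates input and reports held-out accuracy", {
  pairs <- small_data()
  m <- train_surrogate(pairs, small_prof, small_cfg())
  expect_s3_class(m, "mitar_surrogate")
  expect_true(m$heldout_accuracy >= 0 && m$heldout_accuracy <= 1)
  expect_length(m$loss, 2L)
  expect_error(train_surrogate(pairs[pairs$label == "positive", ],
                               small_prof, small_cfg()), "both classes")
})

test_that("an untrained model sits at chance on balanced data", {
  pairs <- small_data(n = 40)
  m0 <- train_surrogate(pairs, small_prof, small_cfg(epochs = 0L))
  arr <- encode_table(pairs, small_prof)
  p <- predict_proba(m0, arr)
  acc <- mean((p > 0.5) == (pairs$label == "positive"))
  expect_lt(abs(acc - 0.5), 0.35) # chance level, generous band for n = 40
  expect_length(m0$loss, 0L)
})

test_that("training and prediction are deterministic given the seed", {
  pairs <- small_data()
  m1 <- train_surrogate(pairs, small_prof, small_cfg())
  m2 <- train_surrogate(pairs, small_prof, small_cfg())
  arr <- encode_table(pairs, small_prof)
  expect_identical(predict_proba(m1, arr), predict_proba(m2, arr))
  # purity: repeated calls agree bitwise, duplicated inputs agree
  p1 <- predict_proba(m1, arr)
  expect_identical(p1, predict_proba(m1, arr))
  dup <- encode_table(pairs[c(1, 1), ], small_prof)
  pd <- predict_proba(m1, dup)
  expect_identical(pd[[1]], pd[[2]])
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_length(predict_proba(m1, list()), 0L)
  expect_error(predict_proba(m1, encode_table(pairs, dataset_profile("miraw"))),
               "rows")
})

test_that("layer activations come from the prediction forward pass", {
  pairs <- small_data()
  m <- train_surrogate(pairs, small_prof, small_cfg())
  arr <- encode_table(pairs, small_prof)
  p_before <- predict_proba(m, arr)
  for (layer in c("embedding", "cnn", "pool", "birnn", "dense1", "dense2")) {
    act <- layer_outputs(m, arr, layer)
    expect_equal(nrow(act), nrow(pairs))
    expect_identical(attr(act, "prob"), p_before, label = layer)
  }
  expect_identical(predict_proba(m, arr), p_before)
  expect_error(layer_outputs(m, arr, "softmax"), "registry")
})

test_that("unit counts follow the convolution arithmetic", {
  pairs <- small_data()
  # rows = 22, kernel 4 -> 19 conv positions
  m <- train_surrogate(pairs, small_prof, small_cfg())
  cnn <- layer_outputs(m, encode_table(pairs, small_prof), "cnn")
  expect_equal(ncol(cnn), 4L * 19L)
  expect_equal(unname(attr(cnn, "fmap_dims")), c(4L, 19L))
  birnn <- layer_outputs(m, encode_table(pairs, small_prof), "birnn")
  expect_equal(ncol(birnn), 6L) # two directions x rnn_hidden
  d2 <- layer_outputs(m, encode_table(pairs, small_prof), "dense2")
  expect_equal(ncol(d2), 1L)

  # deepmirtar geometry with the default kernel: 79 rows
  cfg <- model_config(epochs = 0L, train_seed = 2L)
  prof <- dataset_profile("deepmirtar")
  m2 <- train_surrogate(tiny_pairs(8, prof), prof, cfg)
  cnn2 <- layer_outputs(m2, encode_table(tiny_pairs(8, prof), prof), "cnn")
  expect_equal(unname(attr(cnn2, "fmap_dims")),
               c(cfg$n_filters, 79L - cfg$kernel_len + 1L))
})

test_that("analytic gradients match finite differences", {
  pairs <- small_data(n = 8)
  arr <- encode_table(pairs, small_prof)
  y <- as.numeric(pairs$label == "positive")
  cfg <- small_cfg()
  params <- mirtarprobe:::init_params(cfg, small_prof)
  # include masked-letter entries so the self-supervised path is checked too
  mlm <- rbind(c(0L, 2L, 1L), c(1L, 12L, 3L), c(3L, 5L, 0L))
  g <- mirtarprobe:::cpp_surrogate_grad(params, arr, y, mlm, 1.5)
  num_grad <- function(name, i, eps = 1e-6) {
    p1 <- params; p1[[name]][i] <- p1[[name]][i] + eps
    p2 <- params; p2[[name]][i] <- p2[[name]][i] - eps
    (mirtarprobe:::cpp_surrogate_grad(p1, arr, y, mlm, 1.5)$loss -
       mirtarprobe:::cpp_surrogate_grad(p2, arr, y, mlm, 1.5)$loss) / (2 * eps)
  }
  set.seed(23)
  for (nm in c("E", "Wc", "bc", "Wf", "Uf", "bf", "Wb", "Ub", "bb",
               "W1", "b1", "W2", "b2", "Wm", "bm")) {
    for (i in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
      a <- g[[nm]][i]; b <- num_grad(nm, i)
      expect_lt(abs(a - b) / max(1e-6, abs(a) + abs(b)), 1e-4,
                label = sprintf("d%s[%d]", nm, i))
    }
  }
})

test_that("models save and load with their JSON sidecar", {
  pairs <- small_data()
  m <- train_surrogate(pairs, small_prof, small_cfg())
  dir <- withr::local_tempdir()
  save_surrogate(m, dir)
  expect_true(file.exists(file.path(dir, "model.json")))
  m2 <- load_surrogate(dir)
  arr <- encode_table(pairs, small_prof)
  expect_identical(predict_proba(m, arr), predict_proba(m2, arr))
})
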