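# Independent oracles and toy models shared across tests. Everything here is
# deliberately simple and slow; none of it reuses the code paths it checks.

# Brute-force duplex alignment score by exhaustive recursion with the same
# cost semantics as the DP: global over the miRNA, free leading/trailing
# target gaps, affine gaps costing gap_open + len * gap_extend.
bf_duplex_score <- function(mirna, target, params = energy_params()) {
  to_int <- function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    ch[ch == "T"] <- "U"
    match(ch, c("A", "C", "G", "U"))
  }
  mi <- to_int(mirna); tg <- to_int(target)
  m <- length(mi); n <- length(tg)
  pair_score <- function(a, b) {
    # 1=A 2=C 3=G 4=U
    if ((a == 3 && b == 2) || (a == 2 && b == 3)) return(params$gc)
    if ((a == 1 && b == 4) || (a == 4 && b == 1)) return(params$au)
    if ((a == 3 && b == 4) || (a == 4 && b == 3)) return(params$gu)
    params$mismatch
  }
  memo <- new.env(hash = TRUE)
  f <- function(i, j, prev) {
    if (i > m) return(0) # free target suffix
    key <- paste(i, j, prev)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (j <= n)
      best <- max(best, pair_score(mi[[i]], tg[[j]]) + f(i + 1L, j + 1L, "M"))
    gp <- if (prev == "P") params$gap_extend else params$gap_open + params$gap_extend
    best <- max(best, gp + f(i + 1L, j, "P"))
    if (j <= n) {
      if (i == 1L && prev == "start") {
        best <- max(best, f(1L, j + 1L, "start")) # free target prefix
      } else {
        gq <- if (prev == "Q") params$gap_extend
              else params$gap_open + params$gap_extend
        best <- max(best, gq + f(i, j + 1L, "Q"))
      }
    }
    memo[[key]] <- best
    best
  }
  f(1L, 1L, "start")
}

# Affine "intactness" toy model: probability = base - sum of weights over
# rows that do not carry a plain letter (N or zero rows). Weights are over
# concatenated rows; keep them small enough that probabilities stay in [0,1].
additive_model <- function(weights, base = 0.9, profile = dataset_profile()) {
  fn_model(function(enc) {
    intact <- rowSums(enc[, c("A", "C", "G", "U"), drop = FALSE]) > 0
    base - sum(weights[!intact])
  }, profile)
}

constant_model <- function(p = 0.7, profile = dataset_profile()) {
  fn_model(function(enc) p, profile)
}

# Deterministic nonlinear model: a fixed pseudo-random projection of the
# encoding through a squashing nonlinearity. Pure function of the input.
nonlinear_model <- function(profile, seed = 99) {
  rows <- profile$mirna_pad_len + profile$target_pad_len
  W <- with_seed(seed, matrix(rnorm(rows * 5), rows, 5))
  w2 <- with_seed(seed + 1, rnorm(7))
  fn_model(function(enc) {
    s <- sum(W * enc)
    h <- tanh(s / 3 + w2[1:3] * sum(enc[, "N"]))
    0.5 + 0.45 * tanh(sum(h) / 2)
  }, profile)
}

# Small fixed pair table of full-length sequences (no pads on the miRNA
# track), deterministic.
tiny_pairs <- function(n = 6, profile = dataset_profile(), seed = 42,
                       mirna_len = 26) {
  rule <- planted_rule(mirna_len_range = c(mirna_len, mirna_len))
  generate_dataset(ceiling(n / 2), floor(n / 2), rule, profile, seed = seed)$pairs
}

# One shared trained surrogate for the expensive interpretation tests; the
# training conditions match the defaults (2,000 pairs, default rule).
shared <- new.env(parent = emptyenv())
get_trained_model <- function() {
  if (is.null(shared$model)) {
    shared$data <- generate_dataset(1000, 1000, planted_rule(),
                                    dataset_profile(), seed = 7)
    shared$model <- train_surrogate(shared$data$pairs, dataset_profile(),
                                    model_config(train_seed = 7))
  }
  list(model = shared$model, data = shared$data)
}
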