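# Brute-force oracle: compute contextual impacts by mutating explicit
# position sets directly, never through ScanProfile.
bf_left <- function(model, pairs, prof, track, p, k, replacement = "N") {
  arr <- encode_table(pairs, prof)
  ref <- predict_proba(model, arr)
  win_k <- position_label(track, (p - k + 1):p)
  win_km1 <- position_label(track, (p - k + 1):(p - 1))
  dk <- mean(predict_proba(model, apply_mutation(arr, win_k, replacement, prof)) - ref)
  dkm1 <- mean(predict_proba(model, apply_mutation(arr, win_km1, replacement, prof)) - ref)
  dk - dkm1
}
bf_right <- function(model, pairs, prof, track, p, k, replacement = "N") {
  arr <- encode_table(pairs, prof)
  ref <- predict_proba(model, arr)
  win_k <- position_label(track, p:(p + k - 1))
  win_km1 <- position_label(track, (p + 1):(p + k - 1))
  dk <- mean(predict_proba(model, apply_mutation(arr, win_k, replacement, prof)) - ref)
  dkm1 <- mean(predict_proba(model, apply_mutation(arr, win_km1, replacement, prof)) - ref)
  dk - dkm1
}

toy_profile <- dataset_profile("toy40", 20, 20)
toy_pairs <- function(seed = 17, n = 4) {
  rule <- planted_rule(regions = list(list(start = 2, len = 4, complement_prob = 1)),
                       mirna_len_range = c(20, 20), site_len = 16, flank = 2)
  generate_dataset(n, 0, rule, toy_profile, seed = seed)$pairs
}

test_that("contextual impacts equal the explicit-mutation oracle", {
  pairs <- toy_pairs()
  nm <- nonlinear_model(toy_profile)
  scans <- multi_scan(nm, pairs, ks = 1:4, profile = toy_profile)
  for (k in 2:4) {
    for (track in c("L", "LT")) {
      len <- 20
      for (p in seq_len(len)) {
        pos <- position_label(track, p)
        l <- left_context_impact(scans[[as.character(k)]],
                                 scans[[as.character(k - 1)]], pos)
        r <- right_context_impact(scans[[as.character(k)]],
                                  scans[[as.character(k - 1)]], pos)
        if (p >= k && p <= len) {
          expect_equal(l, bf_left(nm, pairs, toy_profile, track, p, k),
                       tolerance = 1e-9, label = sprintf("left %s k=%d", pos, k))
        } else {
          expect_true(is.na(l))
        }
        if (p + k - 1 <= len) {
          expect_equal(r, bf_right(nm, pairs, toy_profile, track, p, k),
                       tolerance = 1e-9, label = sprintf("right %s k=%d", pos, k))
        } else {
          expect_true(is.na(r))
        }
      }
    }
  }
})

test_that("combined context modes follow their formulas", {
  pairs <- toy_pairs()
  nm <- nonlinear_model(toy_profile)
  scans <- multi_scan(nm, pairs, ks = 1:3, profile = toy_profile)
  s3 <- scans[["3"]]; s2 <- scans[["2"]]
  l <- left_context_impact(s3, s2, "L7")
  r <- right_context_impact(s3, s2, "L7")
  expect_equal(context_impact(s3, s2, "L7", "mean"), (l + r) / 2)
  expect_equal(context_impact(s3, s2, "L7", "paper"), (l - r) / 2)
  # off-edge side undefined -> combined undefined
  expect_true(is.na(context_impact(s3, s2, "L2", "mean"))) # left needs p >= 3
  expect_error(check <- left_context_impact(s3, scans[["1"]], "L7"),
               "adjacent")
})

test_that("constant models give identically zero impact profiles", {
  pairs <- toy_pairs()
  cm <- constant_model(0.4, toy_profile)
  scans <- multi_scan(cm, pairs, ks = 1:4, profile = toy_profile)
  prof <- build_impact_profile(scans)
  expect_true(all(prof$e_avg == 0))
  expect_true(all(prof$e_single == 0))
})

test_that("additive weights are recovered exactly (identifiability)", {
  w <- numeric(40)
  w[c(3, 7, 14, 25, 33)] <- c(0.01, 0.03, 0.02, 0.025, 0.015)
  am <- additive_model(w, base = 0.9, profile = toy_profile)
  pairs <- toy_pairs()
  scans <- multi_scan(am, pairs, ks = 1:6, profile = toy_profile)
  prof_mean <- build_impact_profile(scans, "mean")
  rows <- position_to_row(prof_mean$position, toy_profile)
  expect_equal(prof_mean$e_avg, -w[rows], tolerance = 1e-9)

  # the printed formula (l - r)/2 cancels an additive model everywhere the
  # context is defined; with e_single included, e_avg = -w/n_components
  prof_paper <- build_impact_profile(scans, "paper")
  ctx_cols <- grep("^e_ctx_", names(prof_paper), value = TRUE)
  ctx <- as.matrix(prof_paper[, ctx_cols])
  expect_true(all(abs(ctx[!is.na(ctx)]) < 1e-9))

  # only k = 1 supplied: e_avg is the single-nucleotide profile
  p1 <- build_impact_profile(scans["1"])
  expect_equal(p1$e_avg, p1$e_single)
  expect_error(build_impact_profile(scans[c("2", "3")]), "k = 1")
})

test_that("undefined positions never contribute to the average", {
  pairs <- toy_pairs()
  nm <- nonlinear_model(toy_profile)
  scans <- multi_scan(nm, pairs, ks = 1:4, profile = toy_profile)
  prof <- build_impact_profile(scans)
  # at the track edge only e_single is defined
  edge <- prof[prof$position == "L1", ]
  expect_equal(edge$n_components, 1L)
  expect_equal(edge$e_avg, edge$e_single)
  mid <- prof[prof$position == "L10", ]
  expect_equal(mid$n_components, 4L) # e_single + k=2,3,4
  ctx_cols <- grep("^e_ctx_", names(prof), value = TRUE)
  manual <- rowMeans(cbind(prof$e_single, as.matrix(prof[, ctx_cols])),
                     na.rm = TRUE)
  expect_equal(prof$e_avg, manual)
})

test_that("greedy feature regions find the planted peaks with tie rules", {
  prof <- data.frame(position = c(position_label("L", 1:20),
                                  position_label("LT", 1:20)),
                     track = rep(c("L", "LT"), each = 20),
                     index = c(1:20, 1:20),
                     e_avg = 0, stringsAsFactors = FALSE)
  class(prof) <- c("impact_profile", class(prof))
  # single nonzero block L13-L16
  prof$e_avg[prof$track == "L" & prof$index %in% 13:16] <- -0.3
  fr <- find_feature_regions(prof, window_len = 4, n_regions = 1)
  expect_equal(fr$label, "L13-4")
  expect_equal(fr$summit, "L13")

  # two equal disjoint peaks, one per track: L track reported first
  prof$e_avg[] <- 0
  prof$e_avg[prof$track == "L" & prof$index %in% 5:8] <- 0.2
  prof$e_avg[prof$track == "LT" & prof$index %in% 5:8] <- -0.2
  fr2 <- find_feature_regions(prof, window_len = 4, n_regions = 2)
  expect_equal(fr2$label, c("L5-4", "LT5-4"))

  # ties inside one track: smaller start wins; chosen windows never overlap
  prof$e_avg[] <- 0.1
  fr3 <- find_feature_regions(prof, window_len = 4, n_regions = 3)
  expect_equal(fr3$start, c(1, 5, 9))
  expect_true(all(fr3$track == "L"))

  # more regions than fit -> fewer, with a warning
  expect_warning(fr4 <- find_feature_regions(prof, window_len = 15, n_regions = 3),
                 "only")
  expect_lte(nrow(fr4), 2L)
})
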