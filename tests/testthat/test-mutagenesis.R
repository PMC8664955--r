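test_that("mutations replace exactly the requested rows", {
  prof <- dataset_profile("deepmirtar")
  pairs <- tiny_pairs(2, prof)
  enc <- encode_pair(pairs$mirna_seq[[1]], pairs$target_seq[[1]], prof)

  mut <- apply_mutation(enc, region_positions("L", 2, 6), "N", prof)
  changed <- which(rowSums(mut != enc) > 0)
  expect_equal(changed, 2:7)
  expect_true(all(mut[2:7, "N"] == 1))

  # empty spec is the identity; re-mutating to N is idempotent
  expect_identical(apply_mutation(enc, character(), "N", prof), enc)
  expect_identical(apply_mutation(mut, region_positions("L", 2, 6), "N", prof),
                   mut)

  # G replacement and zero rows
  mg <- apply_mutation(enc, "L1", "G", prof)
  expect_equal(unname(mg[1, ]), c(0, 0, 1, 0, 0))
  mz <- apply_mutation(enc, "L1", "zero", prof)
  expect_true(all(mz[1, ] == 0))

  # padding rows stay untouched (22-nt miRNA: L23-L26 are pads)
  short <- encode_pair(strrep("A", 22), strrep("U", 40), prof)
  mp <- apply_mutation(short, "L24", "N", prof)
  expect_identical(mp, short)

  expect_error(apply_mutation(enc, "L99", "N", prof), "out of bounds")
  expect_error(apply_mutation(enc, c("L2", "L2"), "N", prof), "distinct")
})

test_that("region effects behave on constant and planted models", {
  prof <- dataset_profile("deepmirtar")
  pairs <- tiny_pairs(10, prof)
  cm <- constant_model(0.7, prof)
  eff <- region_effect(cm, pairs, region_positions("L", 2, 6), "N",
                       family_size = 4, profile = prof)
  expect_true(all(eff$deltas == 0))
  expect_equal(eff$mean_mut_prob, eff$mean_ref_prob)
  expect_equal(eff$p_bonferroni, 1)
  expect_equal(eff$family_size, 4L)
  expect_error(region_effect(cm, pairs[0, ], "L1", profile = prof), "non-empty")
  expect_error(region_effect(cm, pairs, "L1", family_size = 0, profile = prof),
               ">= 1")
})

test_that("bonferroni adjustment is monotone and capped", {
  prof <- dataset_profile("deepmirtar")
  w <- numeric(79); w[2:7] <- 0.05
  am <- additive_model(w, base = 0.9, profile = prof)
  pairs <- tiny_pairs(8, prof)
  e1 <- region_effect(am, pairs, region_positions("L", 2, 6), family_size = 1,
                      profile = prof)
  e9 <- region_effect(am, pairs, region_positions("L", 2, 6), family_size = 9,
                      profile = prof)
  expect_gte(e9$p_bonferroni, e9$p_raw)
  expect_equal(e9$p_bonferroni, min(1, e1$p_raw * 9))
  expect_lte(e9$p_bonferroni, 1)
})

test_that("sliding windows respect stop positions, edges, and tracks", {
  prof <- dataset_profile("t", 6, 8)
  # windows are the k positions ending at the stop, on one track
  expect_equal(mirtarprobe:::scan_window("L", 5, 3), c("L3", "L4", "L5"))
  # edge overflow: positions before the track start fall away (zero padding)
  expect_equal(mirtarprobe:::scan_window("L", 1, 3), "L1")
  expect_equal(mirtarprobe:::scan_window("LT", 1, 3), "LT1")

  w <- numeric(14); w[3] <- 0.2
  am <- additive_model(w, base = 0.9, profile = prof)
  rule <- planted_rule(regions = list(list(start = 2, len = 2, complement_prob = 1)),
                       mirna_len_range = c(6, 6), site_len = 6, flank = 1)
  pairs <- generate_dataset(3, 3, rule, prof, seed = 5)$pairs
  sp <- sliding_scan(am, pairs, k = 3, profile = prof)
  expect_s3_class(sp, "scan_profile")
  expect_equal(nrow(sp), 14L)
  expect_equal(sp$position, c(position_label("L", 1:6), position_label("LT", 1:8)))
  # stop LT1 with k=3 touches no L row: delta there is target-only
  expect_equal(sp$mean_delta[sp$position == "LT1"], 0) # w zero on LT track
  # L3 weight shows up from stop L3 through L5
  expect_equal(sp$mean_delta[sp$position == "L3"], -0.2)
  expect_equal(sp$mean_delta[sp$position == "L5"], -0.2)
  expect_equal(sp$mean_delta[sp$position == "L6"], 0)
  expect_error(sliding_scan(am, pairs, k = 0, profile = prof), "out of range")
  expect_error(sliding_scan(am, pairs, k = 7, profile = prof), "out of range")
})

test_that("scan deltas are bounded and flat under a constant model", {
  prof <- dataset_profile("t", 6, 8)
  pairs <- generate_dataset(3, 3,
    planted_rule(regions = list(), mirna_len_range = c(6, 6),
                 site_len = 6, flank = 1), prof, seed = 6)$pairs
  cm <- constant_model(0.5, prof)
  sp <- sliding_scan(cm, pairs, 2, prof)
  expect_true(all(sp$mean_delta == 0))
  nm <- nonlinear_model(prof)
  sp2 <- sliding_scan(nm, pairs, 2, prof, keep_deltas = TRUE)
  d <- attr(sp2, "deltas")
  expect_true(all(d >= -1 & d <= 1))
  expect_true(all(abs(sp2$mean_delta) <= apply(abs(d), 2, max) + 1e-12))
})

test_that("multi_scan shares one reference and matches sliding_scan", {
  prof <- dataset_profile("t", 6, 8)
  pairs <- generate_dataset(4, 0,
    planted_rule(regions = list(list(start = 2, len = 2, complement_prob = 1)),
                 mirna_len_range = c(6, 6), site_len = 6, flank = 1),
    prof, seed = 7)$pairs
  nm <- nonlinear_model(prof)
  ms <- multi_scan(nm, pairs, ks = 1:3, profile = prof)
  expect_named(ms, c("1", "2", "3"))
  single <- sliding_scan(nm, pairs, 1, prof)
  expect_equal(ms[["1"]]$mean_delta, single$mean_delta)
  expect_equal(attr(ms[["1"]], "ref_mean"), attr(ms[["3"]], "ref_mean"))
})

test_that("k=1 scans equal single-position region effects", {
  prof <- dataset_profile("t", 6, 8)
  pairs <- generate_dataset(4, 0,
    planted_rule(regions = list(list(start = 2, len = 2, complement_prob = 1)),
                 mirna_len_range = c(6, 6), site_len = 6, flank = 1),
    prof, seed = 8)$pairs
  nm <- nonlinear_model(prof)
  sp <- sliding_scan(nm, pairs, 1, prof, keep_deltas = TRUE)
  for (pos in c("L1", "L4", "LT3")) {
    eff <- region_effect(nm, pairs, pos, profile = prof)
    expect_equal(attr(sp, "deltas")[, which(sp$position == pos)], eff$deltas)
    expect_equal(sp$mean_delta[sp$position == pos], mean(eff$deltas))
  }
})

test_that("joint effects report reductions and superadditivity", {
  prof <- dataset_profile("t", 6, 8)
  pairs <- generate_dataset(4, 0,
    planted_rule(regions = list(), mirna_len_range = c(6, 6),
                 site_len = 6, flank = 1), prof, seed = 9)$pairs
  w <- numeric(14); w[1:6] <- 0.1 # additive: -0.1 per mutated position
  am <- additive_model(w, base = 0.95, profile = prof)
  regions <- list(A = c("L1", "L2"), B = c("L4", "L5"))
  je <- joint_effect(am, pairs, regions, list(c("A", "B")), prof)
  expect_equal(je$label, c("reference", "A", "B", "A+B"))
  expect_equal(je$reduction[je$label == "A"], 0.2)
  # disjoint additive regions: superadditivity exactly 0
  expect_equal(je$superadditivity[je$label == "A+B"], 0, tolerance = 1e-12)

  # A = B: joint reduction equals the single reduction (union idempotent)
  je2 <- joint_effect(am, pairs, regions["A"], list(c("A", "A")), prof)
  expect_equal(je2$reduction[je2$label == "A+A"],
               je2$reduction[je2$label == "A"])

  # redundant-regions model (either region suffices): single mutations cost
  # nothing, the joint mutation is what hurts -> strictly superadditive
  or_model <- fn_model(function(enc) {
    a_ok <- all(rowSums(enc[1:2, c("A", "C", "G", "U"), drop = FALSE]) > 0)
    b_ok <- all(rowSums(enc[4:5, c("A", "C", "G", "U"), drop = FALSE]) > 0)
    if (a_ok || b_ok) 0.9 else 0.2
  }, prof)
  je3 <- joint_effect(or_model, pairs, regions, list(c("A", "B")), prof)
  expect_gt(je3$superadditivity[je3$label == "A+B"], 0)
  expect_error(joint_effect(am, pairs, regions, list(c("A", "ZZZ")), prof),
               "unknown region")
})
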