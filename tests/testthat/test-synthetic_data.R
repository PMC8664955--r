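test_that("miRNA generation is deterministic, bounded, and uniform", {
  rule <- planted_rule(mirna_len_range = c(22, 22))
  a <- with_seed(5, generate_mirna(rule))
  b <- with_seed(5, generate_mirna(rule))
  expect_identical(a, b)
  expect_equal(nchar(a), 22L)

  rule2 <- planted_rule()
  lens <- with_seed(1, vapply(1:200, function(i) nchar(generate_mirna(rule2)), 1))
  expect_true(all(lens >= 19 & lens <= 26))

  letters <- with_seed(2, {
    s <- paste(vapply(1:500, function(i) generate_mirna(rule), ""), collapse = "")
    table(strsplit(s, "")[[1]])
  })
  freqs <- letters / sum(letters)
  expect_true(all(abs(freqs - 0.25) < 0.02)) # law of large numbers
})

test_that("positive pairs plant complementarity where the rule says", {
  prof <- dataset_profile("deepmirtar")
  # fully complementary seed, no wobble -> 100% pairing over L2-L7
  rule <- planted_rule(regions = list(list(start = 2, len = 6, complement_prob = 1)),
                       background_match_prob = 0, wobble_prob = 0)
  p <- with_seed(3, generate_positive_pair(rule, prof))
  expect_true(all(2:7 %in% p$truth))
  expect_true(all(p$truth %in% 2:7))
  aln <- align_duplex(p$mirna, p$target)
  expect_equal(region_basepairing(aln, region_positions("L", 2, 6)), 1.0)

  # degenerate rule -> empty ground truth
  rule0 <- planted_rule(regions = list(list(start = 2, len = 6, complement_prob = 0)),
                        background_match_prob = 0)
  p0 <- with_seed(4, generate_positive_pair(rule0, prof))
  expect_length(p0$truth, 0L)

  # binomial sampling of a 0.8 region over many pairs
  rule8 <- planted_rule(regions = list(list(start = 13, len = 4, complement_prob = 0.8)),
                        background_match_prob = 0, wobble_prob = 0)
  fracs <- with_seed(6, vapply(1:1000, function(i) {
    pp <- generate_positive_pair(rule8, prof)
    mean(13:16 %in% pp$truth)
  }, 1))
  expect_lt(abs(mean(fracs) - 0.8), 0.04)

  # site too wide for the profile
  expect_error(generate_positive_pair(planted_rule(site_len = 50),
                                      dataset_profile("miraw")), "exceeds")
})

test_that("ground truth equals the positions that actually complement", {
  prof <- dataset_profile("deepmirtar")
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  pairs_with_wobble <- with_seed(11, lapply(1:20, function(i)
    generate_positive_pair(planted_rule(), prof)))
  for (p in pairs_with_wobble) {
    mi <- strsplit(p$mirna, "")[[1]]
    tg <- strsplit(p$target, "")[[1]]
    flank <- 5L
    pairing <- vapply(seq_along(mi), function(i) {
      t <- tg[[i + flank]]
      t == wc[[mi[[i]]]] ||
        (mi[[i]] == "G" && t == "U") || (mi[[i]] == "U" && t == "G")
    }, TRUE)
    expect_equal(sort(p$truth), which(pairing))
  }
})

test_that("negative seeds escape the real seed set", {
  rule <- planted_rule()
  n <- with_seed(8, generate_negative_pair(rule, real_seed_set = "ACGUAC"))
  expect_false(substr(n$mirna, 2, 7) == "ACGUAC")

  # unescapable: every 6-mer counted as a real seed
  all6 <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "U")), 6)))
  expect_error(with_seed(9, generate_negative_pair(rule, real_seed_set = all6)),
               "permutations")

  seeds <- with_seed(10, {
    real <- vapply(1:50, function(i)
      substr(generate_positive_pair(rule)$mirna, 2, 7), "")
    negs <- vapply(1:200, function(i)
      substr(generate_negative_pair(rule, real)$mirna, 2, 7), "")
    list(real = real, negs = negs)
  })
  expect_length(intersect(seeds$negs, seeds$real), 0L)
})

test_that("datasets are reproducible and correctly sized", {
  prof <- dataset_profile("deepmirtar")
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  a <- generate_dataset(20, 20, planted_rule(), prof, seed = 3, dir = d1)
  b <- generate_dataset(20, 20, planted_rule(), prof, seed = 3, dir = d2)
  expect_identical(readLines(file.path(d1, "pairs.tsv")),
                   readLines(file.path(d2, "pairs.tsv")))
  expect_identical(readLines(file.path(d1, "ground_truth.tsv")),
                   readLines(file.path(d2, "ground_truth.tsv")))
  expect_equal(mean(a$pairs$label == "positive"), 0.5)

  empty <- generate_dataset(0, 0, planted_rule(), prof, seed = 1)
  expect_equal(nrow(empty$pairs), 0L)
  expect_length(empty$ground_truth, 0L)
})

test_that("planted pairs bind more strongly than negatives", {
  # sanity link between the generator and the energetics module: planted
  # complementarity must be energetically visible. Chance pairings under
  # the affine-gap optimum give negatives substantial scores too, so the
  # link is a clear distributional shift, not a clean threshold split.
  prof <- dataset_profile("deepmirtar")
  rule <- planted_rule(
    regions = list(list(start = 2, len = 6, complement_prob = 1),
                   list(start = 13, len = 4, complement_prob = 1)),
    background_match_prob = 0.05, wobble_prob = 0)
  ds <- generate_dataset(250, 250, rule, prof, seed = 13)
  en <- binding_energies(ds$pairs)
  y <- ds$pairs$label == "positive"
  expect_lt(mean(en[y]), mean(en[!y]) - 2) # clearly stronger binding
  auc <- mean(outer(en[y], en[!y], "<"))
  expect_gt(auc, 0.7)
  expect_lt(mann_whitney_u(en[y], en[!y])$p, 1e-6)
})
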