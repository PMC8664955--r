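WC_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")
WOBBLE_PARTNER <- c(G = "U", U = "G") # G:U is the only wobble class

# letters that do NOT pair (WC or wobble) with the given miRNA letter
NONPAIRING <- list(A = c("A", "C", "G"), C = c("A", "C", "U"),
                   G = c("A", "G"), U = c("C", "U"))

#' Planted complementarity rule for the synthetic generator
#'
#' Describes where and how strongly a positive target site complements its
#' miRNA. The defaults mirror the positional structure recurrently reported
#' for real positive pairs: a seed at L2-L7 (complement probability 0.95)
#' and a 3'-supplementary region at L13-L16 (0.85), background
#' complementarity 0.25, wobble substitution 0.1, miRNA lengths 19-26 nt,
#' a 30-nt site extended by 5-nt flanks on both sides.
#'
#' @param regions List of `list(start, len, complement_prob)` on the L track.
#' @param background_match_prob Complement probability outside planted
#'   regions (opposite the miRNA).
#' @param wobble_prob Probability that a complementing position uses the G:U
#'   wobble partner instead of the Watson-Crick letter (only G/U have one).
#' @param mirna_len_range Integer (min, max) miRNA length in nt.
#' @param site_len Core site length in nt.
#' @param flank Flank length added on both sides of the site.
#' @return An object of class `planted_rule`.
#' @export
planted_rule <- function(regions = list(list(start = 2L, len = 6L, complement_prob = 0.95),
                                        list(start = 13L, len = 4L, complement_prob = 0.85)),
                         background_match_prob = 0.25,
                         wobble_prob = 0.1,
                         mirna_len_range = c(19L, 26L),
                         site_len = 30L,
                         flank = 5L) {
  probs <- c(background_match_prob, wobble_prob,
             vapply(regions, `[[`, 0, "complement_prob"))
  stopifnot(all(probs >= 0 & probs <= 1),
            mirna_len_range[1] >= 1,
            mirna_len_range[2] >= mirna_len_range[1],
            site_len >= 1, flank >= 0)
  for (r in regions)
    if (r$start + r$len - 1L > mirna_len_range[1])
      stop("planted region exceeds the minimum miRNA length")
  structure(list(regions = regions,
                 background_match_prob = background_match_prob,
                 wobble_prob = wobble_prob,
                 mirna_len_range = as.integer(mirna_len_range),
                 site_len = as.integer(site_len), flank = as.integer(flank)),
            class = "planted_rule")
}

planted_positions <- function(rule) {
  unlist(lapply(rule$regions, function(r) seq.int(r$start, r$start + r$len - 1L)))
}

complement_prob_at <- function(rule, i) {
  for (r in rule$regions)
    if (i >= r$start && i <= r$start + r$len - 1L) return(r$complement_prob)
  rule$background_match_prob
}

#' Generate a random miRNA sequence
#'
#' Uniform letters over `A,C,G,U`, length uniform in the rule's
#' `mirna_len_range`. Uses the current RNG state; wrap in `set.seed()` (or
#' let [generate_dataset()] drive the seed) for reproducibility.
#'
#' @param rule A [planted_rule()].
#' @return Sequence string (5'->3').
#' @export
generate_mirna <- function(rule = planted_rule()) {
  len <- sample.int(rule$mirna_len_range[2] - rule$mirna_len_range[1] + 1L, 1L) +
    rule$mirna_len_range[1] - 1L
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

draw_partner <- function(letter, complement, wobble_prob) {
  if (complement) {
    if (letter %in% names(WOBBLE_PARTNER) && runif(1) < wobble_prob)
      WOBBLE_PARTNER[[letter]]
    else WC_COMPLEMENT[[letter]]
  } else {
    sample(NONPAIRING[[letter]], 1L)
  }
}

build_target <- function(mirna, rule, prob_fn) {
  n_t <- rule$site_len + 2L * rule$flank
  mi <- strsplit(mirna, "")[[1]]
  letters <- character(n_t)
  truth <- integer(0)
  for (j in seq_len(n_t)) {
    i <- j - rule$flank # opposite miRNA position (L,i <-> LT,i+flank)
    if (i >= 1L && i <= length(mi)) {
      comp <- runif(1) < prob_fn(i)
      letters[j] <- draw_partner(mi[i], comp, rule$wobble_prob)
      if (comp) truth <- c(truth, i)
    } else {
      letters[j] <- sample(c("A", "C", "G", "U"), 1L)
    }
  }
  list(target = paste(letters, collapse = ""), truth = truth)
}

#' Generate one positive pair with ground truth
#'
#' The target is built position-by-position opposite the miRNA
#' (`L,i <-> LT,i+flank` under the 5'->3' vs 3'->5' writing convention):
#' within planted regions the complement is drawn with the region's
#' `complement_prob` (using the wobble partner with `wobble_prob`),
#' elsewhere with `background_match_prob`; non-complementing positions draw
#' a letter that does not pair, so the ground truth is exactly the set of
#' complemented L positions and is verifiable by inspection.
#'
#' @param rule A [planted_rule()].
#' @param profile A [dataset_profile()].
#' @return List with `mirna`, `target`, and integer `truth` (complemented L
#'   positions).
#' @export
generate_positive_pair <- function(rule = planted_rule(),
                                   profile = dataset_profile()) {
  if (rule$site_len + 2L * rule$flank > profile$target_pad_len)
    stop("site_len + 2*flank exceeds the profile's target pad length")
  mirna <- generate_mirna(rule)
  bt <- build_target(mirna, rule, function(i) complement_prob_at(rule, i))
  list(mirna = mirna, target = bt$target, truth = bt$truth)
}

#' Generate one negative pair by seed shuffling
#'
#' The miRNA's seed region (L2-L7) is repeatedly permuted until its 6-mer
#' matches no member of `real_seed_set` (nor the original seed); the target
#' carries background complementarity only. Errors once all distinct
#' permutations are exhausted.
#'
#' @param rule A [planted_rule()].
#' @param real_seed_set Character vector of 6-mers regarded as real seeds.
#' @param profile A [dataset_profile()].
#' @return List with `mirna` and `target`.
#' @export
generate_negative_pair <- function(rule = planted_rule(),
                                   real_seed_set = character(),
                                   profile = dataset_profile()) {
  if (rule$site_len + 2L * rule$flank > profile$target_pad_len)
    stop("site_len + 2*flank exceeds the profile's target pad length")
  mirna <- generate_mirna(rule)
  seed <- substr(mirna, 2L, 7L)
  forbidden <- union(real_seed_set, seed)
  letters <- strsplit(seed, "")[[1]]
  shuffled <- NULL
  for (try in seq_len(200L)) {
    cand <- paste(sample(letters), collapse = "")
    if (!cand %in% forbidden) { shuffled <- cand; break }
  }
  if (is.null(shuffled)) {
    perms <- unique(vapply(all_permutations(letters), paste, "", collapse = ""))
    escape <- setdiff(perms, forbidden)
    if (!length(escape))
      stop("all distinct permutations of the seed are in real_seed_set")
    shuffled <- escape[[1]]
  }
  mirna <- paste0(substr(mirna, 1L, 1L), shuffled,
                  substr(mirna, 8L, nchar(mirna)))
  bt <- build_target(mirna, rule, function(i) rule$background_match_prob)
  list(mirna = mirna, target = bt$target)
}

all_permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(all_permutations(x[-i]), function(p) c(x[[i]], p)))
  out
}

#' Generate a labelled synthetic dataset
#'
#' Draws `n_pos` positives and `n_neg` negatives under one rule,
#' reproducibly from `seed`. The seed 6-mers of the positives' miRNAs play
#' the role of the real seed set when shuffling negative seeds. Optionally
#' writes `pairs.tsv` and a `ground_truth.tsv` sidecar (`pair_id`,
#' comma-separated complemented L indices).
#'
#' @param n_pos,n_neg Pair counts.
#' @param rule A [planted_rule()].
#' @param profile A [dataset_profile()].
#' @param seed Integer seed driving all draws.
#' @param dir Output directory; `NULL` skips writing.
#' @return List with `pairs` (pair table) and `ground_truth` (named list of
#'   integer vectors, positives only).
#' @export
generate_dataset <- function(n_pos, n_neg, rule = planted_rule(),
                             profile = dataset_profile(), seed = 1L,
                             dir = NULL) {
  stopifnot(n_pos >= 0, n_neg >= 0)
  res <- with_seed(seed, {
    pos <- lapply(seq_len(n_pos), function(i) generate_positive_pair(rule, profile))
    seeds <- vapply(pos, function(p) substr(p$mirna, 2L, 7L), "")
    neg <- lapply(seq_len(n_neg), function(i) {
      # a drawn miRNA can have an unescapable seed (e.g. a homopolymer);
      # redraw the miRNA in that case
      for (try in seq_len(100L)) {
        out <- tryCatch(generate_negative_pair(rule, seeds, profile),
                        error = function(e) NULL)
        if (!is.null(out)) return(out)
      }
      stop("could not generate an escapable negative seed in 100 draws")
    })
    list(pos = pos, neg = neg)
  })
  ids <- c(sprintf("pos%04d", seq_len(n_pos)), sprintf("neg%04d", seq_len(n_neg)))
  pairs <- data.frame(
    pair_id = ids,
    mirna_seq = c(vapply(res$pos, `[[`, "", "mirna"),
                  vapply(res$neg, `[[`, "", "mirna")),
    target_seq = c(vapply(res$pos, `[[`, "", "target"),
                   vapply(res$neg, `[[`, "", "target")),
    label = rep(c("positive", "negative"), c(n_pos, n_neg)),
    stringsAsFactors = FALSE)
  truth <- lapply(res$pos, `[[`, "truth")
  names(truth) <- ids[seq_len(n_pos)]
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_pair_table(pairs, file.path(dir, "pairs.tsv"))
    gt <- data.frame(pair_id = names(truth),
                     l_positions = vapply(truth, paste, "", collapse = ","),
                     stringsAsFactors = FALSE)
    write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(pairs = pairs, ground_truth = truth)
}
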