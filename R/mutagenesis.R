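#' Apply an in silico mutation to an encoded input
#'
#' Replaces the listed positions by the `N` one-hot row, the `G` one-hot
#' row, or the all-zero row. Padding rows (already all-zero) are left
#' unchanged: mutating a position beyond a pair's true length is a no-op by
#' definition. The input is not modified in place.
#'
#' @param encoded Matrix from [encode_pair()], or a 3-D array from
#'   [encode_table()] (mutation applied to every slice).
#' @param positions Character vector of position labels (`"L2"`, `"LT7"`,
#'   ...); may be empty.
#' @param replacement `"N"`, `"G"`, or `"zero"`.
#' @param profile A [dataset_profile()].
#' @return Object of the same shape with the mutation applied.
#' @export
apply_mutation <- function(encoded, positions,
                           replacement = c("N", "G", "zero"),
                           profile = attr(encoded, "profile")) {
  replacement <- match.arg(replacement)
  if (!length(positions)) return(encoded)
  if (anyDuplicated(positions)) stop("mutation positions must be distinct")
  rows <- position_to_row(positions, profile)
  onehot <- switch(replacement,
                   N = letter_onehot("N"),
                   G = letter_onehot("G"),
                   zero = numeric(5L))
  if (is.matrix(encoded)) {
    for (r in rows)
      if (any(encoded[r, ] > 0) || replacement == "zero")
        encoded[r, ] <- onehot
    encoded
  } else {
    for (r in rows) {
      nonpad <- colSums(encoded[r, , , drop = FALSE][1, , ]) > 0
      if (replacement == "zero") nonpad[] <- TRUE
      encoded[r, , ] <- outer(onehot, as.numeric(nonpad))
    }
    encoded
  }
}

#' Effect of occluding one region
#'
#' Computes reference and mutated prediction probabilities for every pair,
#' then compares the two probability samples with a two-sided (unpaired)
#' Mann-Whitney U test, Bonferroni-corrected over `family_size` tests.
#'
#' @param model A model with a [predict_proba()] method.
#' @param pairs Pair table (non-empty).
#' @param region Character vector of position labels, e.g.
#'   `region_positions("L", 2, 6)` for the seed.
#' @param replacement `"N"`, `"G"`, or `"zero"`.
#' @param family_size Number of region tests in the invoking report
#'   (Bonferroni family); recorded in the output.
#' @param profile A [dataset_profile()].
#' @param region_label Label recorded in the output.
#' @return An object of class `region_effect`: list with `region_label`,
#'   `mean_ref_prob`, `mean_mut_prob`, `se_ref`, `se_mut`, `deltas`
#'   (mut - ref, one per pair), `U`, `p_raw`, `p_bonferroni`, `family_size`.
#' @export
region_effect <- function(model, pairs, region, replacement = "N",
                          family_size = 1L, profile = dataset_profile(),
                          region_label = NULL) {
  if (!nrow(pairs)) stop("pairs must be non-empty")
  if (family_size < 1L) stop("family_size must be >= 1")
  arr <- encode_table(pairs, profile)
  ref <- predict_proba(model, arr)
  mut <- predict_proba(model, apply_mutation(arr, region, replacement, profile))
  mw <- mann_whitney_u(ref, mut)
  structure(list(
    region_label = region_label %||% region_span_label(region),
    replacement = replacement,
    mean_ref_prob = mean(ref), mean_mut_prob = mean(mut),
    se_ref = se_of(ref), se_mut = se_of(mut),
    deltas = mut - ref,
    U = mw$U, p_raw = mw$p,
    p_bonferroni = bonferroni(mw$p, family_size),
    family_size = as.integer(family_size)), class = "region_effect")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

region_span_label <- function(region) {
  p <- parse_positions(region)
  sprintf("%s%d-%d", p$track[[1]], min(p$index), length(region))
}

#' @export
print.region_effect <- function(x, ...) {
  cat(sprintf(
    "<region_effect %s (%s): ref %.3f+/-%.3f -> mut %.3f+/-%.3f, U=%.1f, p_bonf=%.3g (family %d)>\n",
    x$region_label, x$replacement, x$mean_ref_prob, x$se_ref,
    x$mean_mut_prob, x$se_mut, x$U, x$p_bonferroni, x$family_size))
  invisible(x)
}

track_lengths <- function(profile) {
  c(L = profile$mirna_pad_len, LT = profile$target_pad_len)
}

scan_window <- function(track, stop, k) {
  idx <- seq.int(stop - k + 1L, stop)
  position_label(track, idx[idx >= 1L]) # overflow realised as zero padding
}

#' Sliding k-nucleotide mutation scan
#'
#' For each stop position on each track the k positions ending there (on
#' that track only; windows never span the miRNA/target boundary) are
#' mutated and the mean prediction-probability change recorded at the stop.
#' Window slots before a track's start are realised as zero padding, i.e.
#' only the existing positions are occluded. The unmutated mean probability
#' is kept as the `L0` reference.
#'
#' @param model A model with a [predict_proba()] method.
#' @param pairs Pair table.
#' @param k Mutation width in nt, `1 <= k <= min(track lengths)`.
#' @param profile A [dataset_profile()].
#' @param replacement Passed to [apply_mutation()].
#' @param ref Optional precomputed reference probabilities (one per pair).
#' @param keep_deltas Keep the per-pair delta matrix (needed by brute-force
#'   cross-checks and effect filters).
#' @return Data.frame of class `scan_profile` with columns `position`,
#'   `track`, `index`, `mean_delta`, `se`, `n`; attributes `k`, `ref_mean`,
#'   and optionally `deltas` (pairs x stops).
#' @export
sliding_scan <- function(model, pairs, k, profile = dataset_profile(),
                         replacement = "N", ref = NULL, keep_deltas = FALSE) {
  lens <- track_lengths(profile)
  if (k < 1L || k > min(lens)) stop("k out of range for this profile")
  arr <- encode_table(pairs, profile)
  if (is.null(ref)) ref <- predict_proba(model, arr)
  stops <- data.frame(
    track = rep(names(lens), lens),
    index = c(seq_len(lens[[1]]), seq_len(lens[[2]])),
    stringsAsFactors = FALSE)
  deltas <- matrix(NA_real_, nrow(pairs), nrow(stops))
  for (s in seq_len(nrow(stops))) {
    win <- scan_window(stops$track[[s]], stops$index[[s]], k)
    mut <- apply_mutation(arr, win, replacement, profile)
    deltas[, s] <- predict_proba(model, mut) - ref
  }
  out <- data.frame(position = position_label(stops$track, stops$index),
                    track = stops$track, index = stops$index,
                    mean_delta = colMeans(deltas),
                    se = apply(deltas, 2L, se_of),
                    n = nrow(pairs), stringsAsFactors = FALSE)
  attr(out, "k") <- as.integer(k)
  attr(out, "ref_mean") <- mean(ref)
  attr(out, "ref") <- ref
  if (keep_deltas) attr(out, "deltas") <- deltas
  class(out) <- c("scan_profile", class(out))
  out
}

#' Run sliding scans for several mutation widths
#'
#' All scans share one set of reference probabilities, computed once.
#'
#' @param model,pairs,profile,replacement,keep_deltas As [sliding_scan()].
#' @param ks Integer vector of mutation widths, e.g. `1:6`.
#' @return Named list (`"1"`, `"2"`, ...) of `scan_profile`s, class
#'   `scan_set`.
#' @export
multi_scan <- function(model, pairs, ks = 1:6, profile = dataset_profile(),
                       replacement = "N", keep_deltas = FALSE) {
  stopifnot(length(ks) >= 1L)
  arr <- encode_table(pairs, profile)
  ref <- predict_proba(model, arr)
  out <- lapply(ks, function(k)
    sliding_scan(model, pairs, k, profile, replacement, ref = ref,
                 keep_deltas = keep_deltas))
  names(out) <- as.character(ks)
  class(out) <- "scan_set"
  out
}

#' Independent and joint effects of named regions
#'
#' Mutates each region separately and each listed pair of regions jointly
#' (union of positions), reporting mean probability, its standard error,
#' the reduction versus the unmutated reference, and for joint rows the
#' superadditivity `reduction(A U B) - [reduction(A) + reduction(B)]`.
#'
#' @param model A model with a [predict_proba()] method.
#' @param pairs Pair table.
#' @param regions Named list of position-label vectors (may overlap).
#' @param region_pairs List of length-2 character vectors naming regions to
#'   mutate jointly.
#' @param profile A [dataset_profile()].
#' @param replacement Passed to [apply_mutation()].
#' @return Data.frame with one row for the reference, each region, and each
#'   pair: `label`, `mean_prob`, `se`, `reduction`, `superadditivity`.
#' @export
joint_effect <- function(model, pairs, regions = builtin_regions()[c("seed2-6", "L4-4", "L13-4")],
                         region_pairs = list(), profile = dataset_profile(),
                         replacement = "N") {
  for (rp in region_pairs) {
    bad <- setdiff(rp, names(regions))
    if (length(bad)) stop(sprintf("unknown region label '%s'", bad[[1]]))
  }
  arr <- encode_table(pairs, profile)
  ref <- predict_proba(model, arr)
  eff_of <- function(pos) {
    p <- predict_proba(model, apply_mutation(arr, pos, replacement, profile))
    c(mean = mean(p), se = se_of(p))
  }
  rows <- list(data.frame(label = "reference", mean_prob = mean(ref),
                          se = se_of(ref), reduction = 0,
                          superadditivity = NA_real_))
  red <- numeric(0)
  for (nm in names(regions)) {
    e <- eff_of(regions[[nm]])
    red[nm] <- mean(ref) - e[["mean"]]
    rows[[length(rows) + 1L]] <- data.frame(
      label = nm, mean_prob = e[["mean"]], se = e[["se"]],
      reduction = red[nm], superadditivity = NA_real_)
  }
  for (rp in region_pairs) {
    u <- union(regions[[rp[[1]]]], regions[[rp[[2]]]])
    e <- eff_of(u)
    r <- mean(ref) - e[["mean"]]
    rows[[length(rows) + 1L]] <- data.frame(
      label = paste(rp, collapse = "+"), mean_prob = e[["mean"]],
      se = e[["se"]], reduction = r,
      superadditivity = r - (red[[rp[[1]]]] + red[[rp[[2]]]]))
  }
  do.call(rbind, rows)
}
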