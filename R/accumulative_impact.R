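scan_delta <- function(scan, track, index) {
  i <- which(scan$track == track & scan$index == index)
  if (!length(i)) return(NA_real_)
  scan$mean_delta[[i]]
}

scan_k <- function(scan) attr(scan, "k")

#' Contextual per-nucleotide impacts from adjacent mutation widths
#'
#' The impact of position p with its `k-1` left neighbours mutated is the
#' difference between the width-k scan stopped at p and the width-(k-1)
#' scan stopped at p-1 (e.g. at width 4: `delta4(L7) - delta3(L6)`
#' isolates L7). Symmetrically, the right-context impact differences the
#' two widths stopped at `p+k-1` (`delta4(L10) - delta3(L10)` for L7).
#' Positions whose windows do not fit the track return `NA` (the undefined
#' marker), not an error.
#'
#' @param scan_k Width-k [sliding_scan()] profile.
#' @param scan_km1 Width-(k-1) profile from the same pairs.
#' @param position Position label, e.g. `"L7"`.
#' @return Numeric impact (mut - ref scale), or `NA` where undefined.
#' @export
left_context_impact <- function(scan_k, scan_km1, position) {
  k <- check_adjacent(scan_k, scan_km1)
  p <- parse_positions(position)
  lens <- c(L = max(scan_k$index[scan_k$track == "L"]),
            LT = max(scan_k$index[scan_k$track == "LT"]))
  if (p$index < k || p$index > lens[[p$track]]) return(NA_real_)
  scan_delta(scan_k, p$track, p$index) -
    scan_delta(scan_km1, p$track, p$index - 1L)
}

#' @rdname left_context_impact
#' @export
right_context_impact <- function(scan_k, scan_km1, position) {
  k <- check_adjacent(scan_k, scan_km1)
  p <- parse_positions(position)
  lens <- c(L = max(scan_k$index[scan_k$track == "L"]),
            LT = max(scan_k$index[scan_k$track == "LT"]))
  if (p$index < 1L || p$index + k - 1L > lens[[p$track]]) return(NA_real_)
  scan_delta(scan_k, p$track, p$index + k - 1L) -
    scan_delta(scan_km1, p$track, p$index + k - 1L)
}

check_adjacent <- function(scan_k, scan_km1) {
  k <- scan_k(scan_k)
  if (scan_k(scan_km1) != k - 1L)
    stop("scans must have adjacent widths k and k-1")
  k
}

#' Combined contextual impact at one width
#'
#' `mode = "mean"` averages the left and right contextual impacts
#' (`(l + r)/2`), the default used everywhere downstream. `mode = "paper"`
#' reproduces the printed combination `(l - r)/2` verbatim for fidelity
#' runs; on any model with symmetric left/right effects it cancels to zero,
#' which is why it is not the default (see the methods vignette).
#'
#' @inheritParams left_context_impact
#' @param mode `"mean"` or `"paper"`.
#' @return Numeric impact or `NA` if either side is undefined.
#' @export
context_impact <- function(scan_k, scan_km1, position,
                           mode = c("mean", "paper")) {
  mode <- match.arg(mode)
  l <- left_context_impact(scan_k, scan_km1, position)
  r <- right_context_impact(scan_k, scan_km1, position)
  if (is.na(l) || is.na(r)) return(NA_real_)
  if (mode == "mean") (l + r) / 2 else (l - r) / 2
}

#' Averaged per-nucleotide impact profile
#'
#' For every position p, collects the width-1 scan delta `e_single(p)` and
#' the contextual impacts `e_ctx(p, k)` for every contiguous width
#' `k = 2..K` present in `scans`, and averages all defined components into
#' `e_avg(p)`. Component counts are recorded so undefined (edge) positions
#' are auditable.
#'
#' @param scans A `scan_set` from [multi_scan()] containing `k = 1` and a
#'   contiguous range above it.
#' @param mode Passed to [context_impact()].
#' @return Data.frame of class `impact_profile`: `position`, `track`,
#'   `index`, `e_single`, `e_ctx_k2..`, `e_avg`, `n_components`.
#' @export
build_impact_profile <- function(scans, mode = c("mean", "paper")) {
  mode <- match.arg(mode)
  ks <- sort(as.integer(names(scans)))
  if (ks[[1]] != 1L) stop("scans must contain k = 1")
  K <- max(which(seq_along(ks) == ks)) # contiguous prefix 1..K
  s1 <- scans[["1"]]
  out <- data.frame(position = s1$position, track = s1$track,
                    index = s1$index, e_single = s1$mean_delta,
                    stringsAsFactors = FALSE)
  comp <- matrix(out$e_single, ncol = 1L)
  if (K >= 2L) for (k in 2L:K) {
    ek <- vapply(out$position, function(p)
      context_impact(scans[[as.character(k)]], scans[[as.character(k - 1L)]],
                     p, mode), numeric(1))
    out[[sprintf("e_ctx_k%d", k)]] <- unname(ek)
    comp <- cbind(comp, ek)
  }
  out$e_avg <- rowMeans(comp, na.rm = TRUE)
  out$n_components <- rowSums(!is.na(comp))
  attr(out, "mode") <- mode
  attr(out, "K") <- K
  class(out) <- c("impact_profile", class(out))
  out
}

#' Greedy selection of high-impact feature regions
#'
#' Repeatedly takes the contiguous single-track window of length
#' `window_len` maximising the summed `|e_avg|` among windows not
#' overlapping an already selected region; ties prefer the smaller start
#' index and the L track over LT. The summit is the maximum-`|e_avg|`
#' position within each window. Returns fewer regions (with a warning) when
#' the request cannot be met.
#'
#' @param profile An [build_impact_profile()] result.
#' @param window_len Window length in nt (default 4).
#' @param n_regions Number of regions to select (default 2).
#' @return Data.frame with `label` (`"L<start>-<len>"` form), `track`,
#'   `start`, `len`, `score`, `summit`.
#' @export
find_feature_regions <- function(profile, window_len = 4L, n_regions = 2L) {
  stopifnot(window_len >= 1L)
  cand <- list()
  for (tr in c("L", "LT")) { # L first: tie preference
    sub <- profile[profile$track == tr, ]
    sub <- sub[order(sub$index), ]
    if (nrow(sub) < window_len) next
    for (st in seq_len(nrow(sub) - window_len + 1L)) {
      w <- sub[st:(st + window_len - 1L), ]
      cand[[length(cand) + 1L]] <- list(
        track = tr, start = w$index[[1]],
        score = sum(abs(w$e_avg)),
        summit = w$position[[which.max(abs(w$e_avg))]])
    }
  }
  chosen <- list()
  taken <- list(L = integer(0), LT = integer(0))
  while (length(chosen) < n_regions && length(cand)) {
    scores <- vapply(cand, `[[`, 0, "score")
    best <- which(scores == max(scores))[[1]] # cand is in tie-preference order
    b <- cand[[best]]
    span <- seq.int(b$start, b$start + window_len - 1L)
    chosen[[length(chosen) + 1L]] <- data.frame(
      label = sprintf("%s%d-%d", b$track, b$start, window_len),
      track = b$track, start = b$start, len = as.integer(window_len),
      score = b$score, summit = b$summit, stringsAsFactors = FALSE)
    taken[[b$track]] <- c(taken[[b$track]], span)
    cand <- Filter(function(cc) {
      cc$track != b$track ||
        !any(seq.int(cc$start, cc$start + window_len - 1L) %in% taken[[cc$track]])
    }, cand)
  }
  if (length(chosen) < n_regions)
    warning(sprintf("only %d of %d requested regions available",
                    length(chosen), n_regions))
  do.call(rbind, chosen)
}
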