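#' Scoring parameters for duplex alignment
#'
#' A transparent linear scoring model: Watson-Crick G:C and A:U pairs and
#' the G:U wobble earn positive scores, mismatches and affine gaps cost
#' (a gap of length g costs `gap_open + g * gap_extend`). The free energy
#' is the alignment score times `energy_per_score` (negative), so more
#' pairing means more negative (stronger) binding. Downstream analyses use
#' the energy only ordinally, so rank fidelity is what matters.
#'
#' @param gc,au,gu Pair scores (positive).
#' @param mismatch,gap_open,gap_extend Penalties (non-positive).
#' @param energy_per_score kcal/mol-like units per score unit (negative).
#' @return An object of class `energy_params`.
#' @export
energy_params <- function(gc = 3, au = 2, gu = 1, mismatch = -1,
                          gap_open = -4, gap_extend = -1,
                          energy_per_score = -1.0) {
  stopifnot(gc > 0, au > 0, gu > 0, mismatch <= 0, gap_open <= 0,
            gap_extend <= 0, energy_per_score < 0)
  structure(list(gc = gc, au = au, gu = gu, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 energy_per_score = energy_per_score),
            class = "energy_params")
}

seq_to_int <- function(s) {
  ch <- strsplit(gsub("-", "", toupper(seq_letters(s))), "")[[1]]
  ch[ch == "T"] <- "U"
  if (any(ch == "N")) stop("sequences must be N-free for alignment")
  out <- match(ch, c("A", "C", "G", "U")) - 1L
  if (anyNA(out)) stop("illegal letter in sequence")
  out
}

#' Align a miRNA against a target site
#'
#' Global dynamic-programming alignment of the miRNA (written 5'->3')
#' against the target (written 3'->5') maximising the total score under
#' affine gaps, with free end-gaps on the target flanks (the site window is
#' wider than the binding register). Among equal-score optima, pairings are
#' preferred over gaps. Pads are stripped before alignment; `T` and `U` are
#' one pairing class.
#'
#' @param mirna,target Sequence strings (written orders as stored).
#' @param params An [energy_params()].
#' @return Object of class `duplex_alignment`: list with `paired`
#'   (data.frame `l_index`, `lt_index`, `type` in WC/wobble), `score`, and
#'   `free_energy = score * energy_per_score`.
#' @examples
#' align_duplex("GGGG", "CCCC")$free_energy # -12
#' @export
align_duplex <- function(mirna, target, params = energy_params()) {
  mi <- seq_to_int(mirna); tg <- seq_to_int(target)
  if (!length(mi) || !length(tg)) stop("sequences must be non-empty")
  res <- cpp_align_duplex(mi, tg, params$gc, params$au, params$gu,
                          params$mismatch, params$gap_open, params$gap_extend)
  paired <- data.frame(l_index = res$paired[, 1],
                       lt_index = res$paired[, 2],
                       type = c("WC", "wobble")[res$paired[, 3]],
                       stringsAsFactors = FALSE)
  structure(list(paired = paired, score = res$score,
                 free_energy = res$score * params$energy_per_score),
            class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(sprintf("<duplex_alignment: %d paired (%d wobble), score %.1f, energy %.1f>\n",
              nrow(x$paired), sum(x$paired$type == "wobble"), x$score,
              x$free_energy))
  invisible(x)
}

#' Binding energy of a pair
#'
#' Free energy of the best duplex alignment of the unpadded sequences; more
#' negative means stronger binding.
#'
#' @param mirna,target Sequences, or a `mirtar_pair` as `mirna`.
#' @param params An [energy_params()].
#' @return Numeric free energy.
#' @export
binding_energy <- function(mirna, target = NULL, params = energy_params()) {
  if (inherits(mirna, "mirtar_pair")) {
    target <- mirna$target$letters; mirna <- mirna$mirna$letters
  }
  align_duplex(mirna, target, params)$free_energy
}

#' @rdname binding_energy
#' @param pairs Pair table.
#' @return `binding_energies()`: numeric vector, one energy per row.
#' @export
binding_energies <- function(pairs, params = energy_params()) {
  vapply(seq_len(nrow(pairs)), function(i)
    binding_energy(pairs$mirna_seq[[i]], pairs$target_seq[[i]], params),
    numeric(1))
}

#' Fraction of a region's positions that base-pair
#'
#' Watson-Crick and wobble pairs both count as pairing.
#'
#' @param alignment A [align_duplex()] result.
#' @param region Position labels on a single track.
#' @return Fraction in `[0, 1]`.
#' @export
region_basepairing <- function(alignment, region) {
  if (!length(region)) stop("region must be non-empty")
  p <- parse_positions(region)
  if (length(unique(p$track)) != 1L) stop("region must lie on a single track")
  paired_idx <- if (p$track[[1]] == "L") alignment$paired$l_index
                else alignment$paired$lt_index
  mean(p$index %in% paired_idx)
}

#' Region base-pairing percentages across a dataset
#'
#' Aligns every pair and reports the mean base-pairing percentage per named
#' region, for all pairs and optionally for "extracted" subsets: pairs whose
#' absolute mutation effect for a named region exceeds a threshold
#' (defaulting to the mean absolute effect, the convention used for the
#' published extraction). An empty subset yields a flagged `NA` row, not an
#' error.
#'
#' @param pairs Pair table.
#' @param regions Named list of position-label vectors.
#' @param effect_filters Optional named list: for each entry named after a
#'   region label, the per-pair `|delta|` values (aligned to `pairs` rows)
#'   used to extract the high-effect subset.
#' @param thresholds Optional named numeric overriding the mean-|delta|
#'   threshold per filter.
#' @param params An [energy_params()].
#' @return Data.frame: rows `all` and `extracted_<label>`, columns `subset`,
#'   `n`, then one mean percentage per region.
#' @export
basepairing_table <- function(pairs, regions = builtin_regions(),
                              effect_filters = NULL, thresholds = NULL,
                              params = energy_params()) {
  aligns <- lapply(seq_len(nrow(pairs)), function(i)
    align_duplex(pairs$mirna_seq[[i]], pairs$target_seq[[i]], params))
  frac <- sapply(regions, function(reg)
    vapply(aligns, region_basepairing, numeric(1), region = reg))
  frac <- matrix(frac, nrow = nrow(pairs),
                 dimnames = list(NULL, names(regions)))
  row_of <- function(subset_name, keep) {
    vals <- if (any(keep)) 100 * colMeans(frac[keep, , drop = FALSE])
            else setNames(rep(NA_real_, ncol(frac)), colnames(frac))
    cbind(data.frame(subset = subset_name, n = sum(keep)),
          as.data.frame(as.list(vals), check.names = FALSE))
  }
  out <- row_of("all", rep(TRUE, nrow(pairs)))
  for (nm in names(effect_filters)) {
    d <- abs(effect_filters[[nm]])
    if (length(d) != nrow(pairs))
      stop("effect filter deltas must align to pairs")
    thr <- if (!is.null(thresholds) && nm %in% names(thresholds))
      thresholds[[nm]] else mean(d)
    out <- rbind(out, row_of(paste0("extracted_", nm), d > thr))
  }
  out
}
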