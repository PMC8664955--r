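#' Aggregate an activation tensor to a correlation level
#'
#' `raw_unit` keeps units as they are; `per_feature_map` sums convolutional
#' unit outputs over positions within each feature map (requires the
#' `(feature_map, position)` factorisation carried by cnn/pool tensors);
#' `all_units` sums over all units into a single column.
#'
#' @param tensor An `activation_tensor` from [layer_outputs()].
#' @param level `"raw_unit"`, `"per_feature_map"`, or `"all_units"`.
#' @return Matrix pairs x aggregated units.
#' @export
aggregate_activations <- function(tensor,
                                  level = c("raw_unit", "per_feature_map",
                                            "all_units")) {
  level <- match.arg(level)
  m <- unclass(tensor)
  attr(m, "layer") <- NULL; attr(m, "prob") <- NULL
  switch(level,
    raw_unit = m,
    per_feature_map = {
      fd <- attr(tensor, "fmap_dims")
      if (is.null(fd))
        stop("per_feature_map requires a layer with a (feature_map, position) factorization")
      maps <- fd[[1]]; pos <- fd[[2]]
      out <- vapply(seq_len(maps), function(f)
        rowSums(m[, (f - 1L) * pos + seq_len(pos), drop = FALSE]),
        numeric(nrow(m)))
      out <- matrix(out, nrow = nrow(m))
      colnames(out) <- sprintf("map%d", seq_len(maps))
      attr(out, "fmap_dims") <- NULL
      out
    },
    all_units = matrix(rowSums(m), ncol = 1L,
                       dimnames = list(NULL, "all_units")))
}

#' Correlate layer activations with binding energy
#'
#' For each requested aggregation level, computes the Spearman correlation
#' of every aggregated unit with the per-pair binding energies, Bonferroni-
#' adjusts over the level's unit count after excluding constant
#' (dead) units, and summarises the minimum and maximum correlations with
#' their adjusted p-values.
#'
#' @param model A trained `mitar_surrogate`.
#' @param pairs Pair table.
#' @param layer Registry layer name (`"cnn"`, `"birnn"`, `"dense1"`, ...).
#' @param energies Per-pair binding energies (see [binding_energies()]).
#' @param levels Aggregation levels to report.
#' @param adjust Multiple-testing method; Bonferroni over the level's
#'   post-exclusion unit count (recorded in the report).
#' @param profile A [dataset_profile()].
#' @return List of `correlation_report` objects, one per level: `layer`,
#'   `level`, `unit_count`, `n_constant_excluded`, `units` (data.frame
#'   `unit`, `rho`, `p_raw`, `p_adj`), `summary` (`MinCor`, `MinCor_p_adj`,
#'   `MaxCor`, `MaxCor_p_adj`).
#' @export
correlate_with_energy <- function(model, pairs, layer, energies,
                                  levels = c("raw_unit", "per_feature_map",
                                             "all_units"),
                                  adjust = "bonferroni",
                                  profile = dataset_profile()) {
  stopifnot(adjust == "bonferroni")
  if (length(energies) != nrow(pairs))
    stop("energies must align to pairs")
  arr <- encode_table(pairs, profile)
  tensor <- layer_outputs(model, arr, layer)
  out <- lapply(levels, function(lv) {
    agg <- aggregate_activations(tensor, lv)
    const <- apply(agg, 2L, function(u) sd(u) == 0)
    fam <- sum(!const)
    rows <- lapply(seq_len(ncol(agg)), function(j) {
      if (const[[j]]) return(data.frame(unit = j, rho = NA_real_,
                                        p_raw = NA_real_, p_adj = NA_real_))
      sc <- spearman_cor(agg[, j], energies)
      data.frame(unit = j, rho = sc$rho, p_raw = sc$p,
                 p_adj = bonferroni(sc$p, fam))
    })
    units <- do.call(rbind, rows)
    if (!is.null(colnames(agg))) units$unit <- colnames(agg)
    ok <- !is.na(units$rho)
    summary <- if (any(ok)) {
      imin <- which.min(units$rho); imax <- which.max(units$rho)
      data.frame(MinCor = units$rho[[imin]],
                 MinCor_p_adj = units$p_adj[[imin]],
                 MaxCor = units$rho[[imax]],
                 MaxCor_p_adj = units$p_adj[[imax]])
    } else data.frame(MinCor = NA_real_, MinCor_p_adj = NA_real_,
                      MaxCor = NA_real_, MaxCor_p_adj = NA_real_)
    structure(list(layer = layer, level = lv, unit_count = fam,
                   n_constant_excluded = sum(const),
                   adjust = adjust, units = units, summary = summary),
              class = "correlation_report")
  })
  names(out) <- levels
  out
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf(
    "<correlation_report %s/%s: %d units (%d constant excluded), MinCor %.3f (p_adj %.3g), MaxCor %.3f (p_adj %.3g)>\n",
    x$layer, x$level, x$unit_count, x$n_constant_excluded,
    x$summary$MinCor, x$summary$MinCor_p_adj,
    x$summary$MaxCor, x$summary$MaxCor_p_adj))
  invisible(x)
}

#' Flatten correlation reports into a summary table
#'
#' One row per layer/level combination with unit counts and min/max
#' correlations, mirroring the conventional layout of such reports.
#'
#' @param reports List of `correlation_report` objects (possibly nested per
#'   layer).
#' @return Data.frame.
#' @export
correlation_summary <- function(reports) {
  if (inherits(reports, "correlation_report")) reports <- list(reports)
  flat <- list()
  collect <- function(x) {
    if (inherits(x, "correlation_report")) flat[[length(flat) + 1L]] <<- x
    else lapply(x, collect)
  }
  collect(reports)
  do.call(rbind, lapply(flat, function(r)
    cbind(data.frame(layer = r$layer, level = r$level,
                     unit_count = r$unit_count,
                     n_constant_excluded = r$n_constant_excluded),
          r$summary)))
}
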