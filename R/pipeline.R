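#' Full-analysis pipeline configuration
#'
#' One document configuring every stage: simulate -> train -> scan ->
#' impact -> duplex -> correlate -> joint -> report. Serialisable to YAML
#' ([read_pipeline_config()] reads it back).
#'
#' @param seed Global integer seed; per-stage seeds are derived from it via
#'   a fixed splitting scheme.
#' @param profile_name `"deepmirtar"` or `"miraw"`.
#' @param n_pos,n_neg Dataset sizes.
#' @param rule A [planted_rule()].
#' @param model A [model_config()].
#' @param ks Mutation widths for the scan stage.
#' @param impact_mode,impact_window,impact_top Impact-profile options.
#' @param energy An [energy_params()].
#' @param regions Named region list for duplex/joint stages.
#' @param region_pairs Region pairs for the joint stage.
#' @param layers,levels Correlation stage settings.
#' @param scan_n_pairs Cap on the number of positive pairs scanned (scans
#'   dominate runtime; `Inf` scans all positives).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 7L, profile_name = "deepmirtar",
                            n_pos = 1000L, n_neg = 1000L,
                            rule = planted_rule(), model = model_config(),
                            ks = 1:6, impact_mode = "mean",
                            impact_window = 4L, impact_top = 2L,
                            energy = energy_params(),
                            regions = builtin_regions()[c("seed2-6", "L4-4", "L13-4")],
                            region_pairs = list(c("seed2-6", "L13-4"),
                                                c("L4-4", "L13-4")),
                            layers = c("cnn", "birnn", "dense1"),
                            levels = c("raw_unit", "per_feature_map", "all_units"),
                            scan_n_pairs = 300L) {
  structure(list(seed = as.integer(seed), profile_name = profile_name,
                 n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 rule = rule, model = model, ks = as.integer(ks),
                 impact_mode = impact_mode,
                 impact_window = as.integer(impact_window),
                 impact_top = as.integer(impact_top),
                 energy = energy, regions = regions,
                 region_pairs = region_pairs, layers = layers,
                 levels = levels, scan_n_pairs = scan_n_pairs),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with (a subset of) the fields above.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  plain <- intersect(names(y), c("seed", "profile_name", "n_pos", "n_neg",
                                 "ks", "impact_mode", "impact_window",
                                 "impact_top", "layers", "levels",
                                 "scan_n_pairs"))
  args[plain] <- y[plain]
  if (!is.null(y$rule)) args$rule <- do.call(planted_rule, y$rule)
  if (!is.null(y$model)) args$model <- do.call(model_config, y$model)
  if (!is.null(y$energy)) args$energy <- do.call(energy_params, y$energy)
  if (!is.null(y$regions))
    args$regions <- lapply(y$regions, function(r)
      region_positions(r$track, r$start, r$len))
  if (!is.null(y$region_pairs))
    args$region_pairs <- lapply(y$region_pairs, unlist)
  do.call(pipeline_config, args)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes all stages in dependency order under one output directory and
#' writes a JSON run manifest last. Each stage's outputs are plain TSV (the
#' trained model additionally as an RDS); warnings (dead units, empty
#' extracted subsets, short feature-region lists) are first-class manifest
#' entries.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Writable output directory.
#' @param quiet Suppress stage messages.
#' @return The run manifest (list of class `run_manifest`), invisibly
#'   written to `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  profile <- dataset_profile(config$profile_name)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(config_hash = config_hash(config),
                   seed = config$seed, stages = list(), warnings = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    manifest$stages[[name]] <<- c(manifest$stages[[name]],
                                  list(elapsed_s = round(proc.time()[["elapsed"]] - t0, 2)))
    res
  }

  # simulate
  say("stage simulate: %d pos + %d neg pairs", config$n_pos, config$n_neg)
  ds <- t_stage("simulate", generate_dataset(
    config$n_pos, config$n_neg, config$rule, profile,
    seed = stage_seed(config$seed, "simulate"), dir = out_dir))
  manifest$stages$simulate$outputs <- c("pairs.tsv", "ground_truth.tsv")
  manifest$stages$simulate$rows <- nrow(ds$pairs)

  # train
  say("stage train: %d epochs", config$model$epochs)
  mc <- config$model
  mc$train_seed <- stage_seed(config$seed, "train")
  model <- t_stage("train", train_surrogate(ds$pairs, profile, mc))
  save_surrogate(model, file.path(out_dir, "model"))
  manifest$stages$train$outputs <- c("model/model.rds", "model/model.json")
  manifest$stages$train$heldout_accuracy <- model$heldout_accuracy

  pos <- ds$pairs[ds$pairs$label == "positive", , drop = FALSE]
  scan_pos <- head(pos, min(nrow(pos), config$scan_n_pairs))

  # scan
  say("stage scan: k = %s on %d positives",
      paste(config$ks, collapse = ","), nrow(scan_pos))
  scans <- t_stage("scan", multi_scan(model, scan_pos, config$ks, profile))
  scan_files <- vapply(names(scans), function(k)
    write_tsv(as.data.frame(scans[[k]])[, c("position", "mean_delta", "se", "n")],
              file.path(out_dir, sprintf("scan_k%s.tsv", k))), "")
  manifest$stages$scan$outputs <- basename(scan_files)

  # impact
  imp <- t_stage("impact", build_impact_profile(scans, config$impact_mode))
  feats <- find_feature_regions(imp, config$impact_window, config$impact_top)
  write_tsv(as.data.frame(imp), file.path(out_dir, "impact.tsv"))
  write_tsv(feats, file.path(out_dir, "regions_found.tsv"))
  manifest$stages$impact$outputs <- c("impact.tsv", "regions_found.tsv")
  if (nrow(feats) < config$impact_top)
    manifest$warnings <- c(manifest$warnings, "fewer feature regions than requested")
  say("stage impact: regions %s", paste(feats$label, collapse = ", "))

  # duplex
  say("stage duplex: energies + base-pairing on %d positives", nrow(pos))
  energies <- t_stage("duplex", binding_energies(pos, config$energy))
  write_tsv(data.frame(pair_id = pos$pair_id, free_energy = energies),
            file.path(out_dir, "energies.tsv"))
  top_label <- if (nrow(feats)) feats$label[[1]] else names(config$regions)[[1]]
  eff_region <- config$regions[[top_label]] %||%
    region_positions(feats$track[[1]], feats$start[[1]], feats$len[[1]])
  eff <- region_effect(model, pos, eff_region, family_size = 1L,
                       profile = profile, region_label = top_label)
  bp <- basepairing_table(pos, config$regions,
                          effect_filters = setNames(list(eff$deltas), top_label),
                          params = config$energy)
  write_tsv(bp, file.path(out_dir, "pairing_table.tsv"))
  manifest$stages$duplex$outputs <- c("energies.tsv", "pairing_table.tsv")
  if (any(bp$n == 0))
    manifest$warnings <- c(manifest$warnings, "empty extracted subset in pairing table")

  # correlate
  say("stage correlate: layers %s", paste(config$layers, collapse = ","))
  reports <- t_stage("correlate", lapply(config$layers, function(ly) {
    lv <- if (ly %in% c("cnn", "pool")) config$levels
          else setdiff(config$levels, "per_feature_map")
    correlate_with_energy(model, pos, ly, energies, levels = lv,
                          profile = profile)
  }))
  corr <- correlation_summary(reports)
  write_tsv(corr, file.path(out_dir, "correlation_summary.tsv"))
  manifest$stages$correlate$outputs <- "correlation_summary.tsv"
  ndead <- sum(corr$n_constant_excluded[corr$level == "raw_unit"])
  if (ndead > 0)
    manifest$warnings <- c(manifest$warnings,
                           sprintf("%d constant units excluded", ndead))

  # joint
  say("stage joint: %d regions, %d pairs of regions",
      length(config$regions), length(config$region_pairs))
  je <- t_stage("joint", joint_effect(model, scan_pos, config$regions,
                                      config$region_pairs, profile))
  write_tsv(je, file.path(out_dir, "effects.tsv"))
  manifest$stages$joint$outputs <- "effects.tsv"

  manifest$finished <- TRUE
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  attr(manifest, "out_dir") <- out_dir
  invisible(manifest)
}

config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  # small rolling hash; stable across sessions, no extra dependency
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

#' Render figures and a summary from a pipeline run
#'
#' Produces static figures (scan profiles with the `L0` reference leftmost,
#' impact bars, independent/joint effect bars) plus a plain-text summary;
#' every figure's underlying numbers are already on disk as TSV.
#'
#' @param out_dir Directory of a completed [run_pipeline()] run (or a
#'   `run_manifest` with that attribute).
#' @return Character vector of files written.
#' @export
render_report <- function(out_dir) {
  if (inherits(out_dir, "run_manifest")) out_dir <- attr(out_dir, "out_dir")
  need <- c("impact.tsv", "effects.tsv", "correlation_summary.tsv")
  for (f in need)
    if (!file.exists(file.path(out_dir, f)))
      stop(sprintf("missing upstream output %s; run its stage first", f))
  files <- character(0)
  scan_files <- list.files(out_dir, pattern = "^scan_k[0-9]+\\.tsv$",
                           full.names = TRUE)
  if (length(scan_files)) {
    scans <- do.call(rbind, lapply(scan_files, function(f) {
      df <- read.delim(f)
      df$k <- sub("^scan_k([0-9]+)\\.tsv$", "\\1", basename(f))
      df
    }))
    scans$position <- factor(scans$position, levels = unique(scans$position))
    g <- ggplot2::ggplot(scans, ggplot2::aes(x = position, y = mean_delta,
                                             group = k, colour = k)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "stop position (L track then LT track; L0 = reference)",
                    y = "mean probability change") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 5))
    f <- file.path(out_dir, "fig_scans.png")
    ggplot2::ggsave(f, g, width = 10, height = 4, dpi = 150)
    files <- c(files, f)
  }
  imp <- read.delim(file.path(out_dir, "impact.tsv"))
  imp$position <- factor(imp$position, levels = unique(imp$position))
  g2 <- ggplot2::ggplot(imp, ggplot2::aes(x = position, y = e_avg)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "position", y = "average per-nucleotide impact") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 5))
  f2 <- file.path(out_dir, "fig_impact.png")
  ggplot2::ggsave(f2, g2, width = 10, height = 4, dpi = 150)
  files <- c(files, f2)
  je <- read.delim(file.path(out_dir, "effects.tsv"))
  je$label <- factor(je$label, levels = je$label)
  g3 <- ggplot2::ggplot(je, ggplot2::aes(x = label, y = mean_prob)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_prob - se,
                                        ymax = mean_prob + se), width = 0.3) +
    ggplot2::labs(x = NULL, y = "mean prediction probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  f3 <- file.path(out_dir, "fig_effects.png")
  ggplot2::ggsave(f3, g3, width = 7, height = 4, dpi = 150)
  files <- c(files, f3)
  corr <- read.delim(file.path(out_dir, "correlation_summary.tsv"))
  summary_lines <- c(
    "# Pipeline report", "",
    sprintf("Feature regions: %s",
            paste(read.delim(file.path(out_dir, "regions_found.tsv"))$label,
                  collapse = ", ")),
    "", "Correlation summary:",
    utils::capture.output(print(corr)))
  f4 <- file.path(out_dir, "report.md")
  writeLines(summary_lines, f4)
  c(files, f4)
}
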