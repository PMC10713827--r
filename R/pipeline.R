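#' Segment and featurize one field
#'
#' Convenience wrapper: [segment_field()] then [featurize_field()].
#'
#' @param channels named list of channel matrices (dna/th/asyn/map2).
#' @param config pipeline config.
#' @return a [featurize_field()] result.
#' @export
process_field <- function(channels, config = default_config()) {
  featurize_field(segment_field(channels, config), config)
}

#' Generate, segment and featurize a whole plate, streaming per field
#'
#' Walks the plate layout field by field: each field is rendered with its
#' deterministic seed, segmented, featurized, and discarded before the next
#' field is generated, so memory stays flat regardless of plate size. When
#' `out_dir` is given, channel TIFFs and the layout/ground-truth tables are
#' written as a side effect.
#'
#' @param layout plate layout from [build_plate_layout()].
#' @param effects effect model.
#' @param config pipeline config.
#' @param seed integer plate seed.
#' @param out_dir optional directory for TIFFs + tables.
#' @return list: `wells` (well feature table, one row per well with 126
#'   features), `ground_truth`, `layout`, `seed`.
#' @export
process_plate <- function(layout, effects, config = default_config(),
                          seed = 1L, out_dir = NULL) {
  validate_layout(layout)
  ps <- plate_seeds(layout, config, seed)
  if (!is.null(out_dir))
    dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  well_rows <- gt_all <- list()
  for (i in seq_len(nrow(layout))) {
    cfg_i <- config
    cfg_i$replicate_offsets <- ps$replicate_offsets
    cfg_i$well_offset <- ps$well_offsets[i]
    field_feats <- vector("list", layout$fields[i])
    for (f in seq_len(layout$fields[i])) {
      fld <- generate_field(layout[i, ], effects, cfg_i,
                            seed = ps$field_seeds[i, f])
      if (nrow(fld$ground_truth)) {
        fld$ground_truth$well <- layout$well[i]
        fld$ground_truth$field <- f
        gt_all[[length(gt_all) + 1L]] <- fld$ground_truth
      }
      if (!is.null(out_dir)) {
        for (ch in names(fld$channels))
          tiff::writeTIFF(fld$channels[[ch]] / 65535,
                          file.path(out_dir, "images",
                                    sprintf("%s_f%02d_%s.tif",
                                            layout$well[i], f, ch)),
                          bits.per.sample = 16L)
      }
      field_feats[[f]] <- process_field(fld$channels, config)
    }
    well_rows[[i]] <- featurize_well(
      field_feats,
      list(plate = "plate1", well = layout$well[i],
           compound = layout$compound[i], dose_uM = layout$dose_uM[i],
           replicate = layout$replicate[i]),
      config)
  }
  wells <- do.call(rbind, well_rows)
  gt <- if (length(gt_all)) do.call(rbind, gt_all) else NULL
  if (!is.null(out_dir)) {
    utils::write.csv(layout, file.path(out_dir, "layout.csv"), row.names = FALSE)
    if (!is.null(gt))
      utils::write.csv(gt, file.path(out_dir, "ground_truth.csv"),
                       row.names = FALSE)
  }
  list(wells = wells, ground_truth = gt, layout = layout, seed = seed)
}

#' Run the full analysis pipeline on one synthetic plate
#'
#' End to end: plate generation + segmentation + feature extraction
#' ([process_plate()]), robust scaling and condition profiling with cosine
#' clustering, a 2-D embedding of the control and top-dose wells, the
#' three-classifier treated-vs-control study, and dose-response statistics
#' for the headline features. Optionally writes all result tables (CSV, and
#' Parquet when the arrow package is available) plus a manifest of file
#' checksums.
#'
#' @param config pipeline config (default [small_config()]).
#' @param effects effect model (default [default_effect_model()]).
#' @param seed integer seed; every random step derives from it.
#' @param out_dir optional results directory.
#' @param embed_method `"umap"` or `"pca"`.
#' @return list: `wells`, `scaled`, `profiles`, `clustering`, `embedding`,
#'   `classification`, `dose_response`, `layout`, `seed`, `manifest`.
#' @export
run_pipeline <- function(config = small_config(),
                         effects = default_effect_model(config$doses_uM,
                                                        config$compounds),
                         seed = 1L, out_dir = NULL,
                         embed_method = c("umap", "pca")) {
  embed_method <- match.arg(embed_method)
  layout <- build_plate_layout(config)
  plate <- process_plate(layout, effects, config, seed,
                         out_dir = if (is.null(out_dir)) NULL else
                           file.path(out_dir, "plate"))
  wells <- plate$wells
  ok <- !is.na(wells$n_living_cells) & wells$n_living_cells > 0
  scaled <- robust_scale(wells[ok, , drop = FALSE])
  profiles <- aggregate_profiles(scaled)
  clustering <- cosine_distance_matrix(profiles)
  top_dose <- max(config$doses_uM)
  emb_rows <- scaled$compound == "vehicle" | scaled$dose_uM == top_dose
  embedding <- embed_wells(scaled[emb_rows, , drop = FALSE],
                           method = embed_method, seed = seed,
                           labels = label_wells(scaled[emb_rows, , drop = FALSE]))
  classification <- classify_wells(wells, config = config, seed = seed)
  dose_response <- dose_response_table(wells[ok, , drop = FALSE],
                                       config = config)
  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(wells, file.path(out_dir, "well_features.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(profiles),
                     file.path(out_dir, "condition_profiles.csv"))
    utils::write.csv(dose_response, file.path(out_dir, "dose_response.csv"),
                     row.names = FALSE)
    writeLines(clustering$newick, file.path(out_dir, "condition_tree.nwk"))
    if (requireNamespace("arrow", quietly = TRUE))
      arrow::write_parquet(wells, file.path(out_dir, "well_features.parquet"))
    files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                           md5 = unname(tools::md5sum(files)),
                           bytes = file.size(files), stringsAsFactors = FALSE)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(wells = wells, scaled = scaled, profiles = profiles,
       clustering = clustering, embedding = embedding,
       classification = classification, dose_response = dose_response,
       layout = layout, seed = seed, manifest = manifest)
}

#' Reproduction study: median best-classifier test accuracy over seeds
#'
#' Renders `n_seeds` independent synthetic plates (seeds `seed`,
#' `seed + 1`, ...), runs the full treated-vs-control classification study
#' on each, takes the best held-out test accuracy across the three
#' classifier kinds per seed, and reports the median over seeds.
#'
#' @param seed base integer seed.
#' @param config pipeline config (default [small_config()]).
#' @param n_seeds number of plate seeds (default 5).
#' @return list: `median_best_accuracy`, `best_per_seed` (named by seed),
#'   `per_seed` (per-kind accuracies), `n_wells` per plate.
#' @export
acceptance_study <- function(seed = 1L, config = small_config(), n_seeds = 5L) {
  seeds <- seed + seq_len(n_seeds) - 1L
  effects <- default_effect_model(config$doses_uM, config$compounds)
  layout <- build_plate_layout(config)
  best <- stats::setNames(numeric(n_seeds), seeds)
  per_seed <- list()
  n_wells <- NA_integer_
  for (i in seq_along(seeds)) {
    plate <- process_plate(layout, effects, config, seeds[i])
    n_wells <- nrow(plate$wells)
    cls <- classify_wells(plate$wells, config = config, seed = seeds[i])
    accs <- vapply(cls, `[[`, 0, "accuracy")
    per_seed[[as.character(seeds[i])]] <- accs
    best[i] <- max(accs)
  }
  list(median_best_accuracy = stats::median(best), best_per_seed = best,
       per_seed = per_seed, n_wells = n_wells)
}
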