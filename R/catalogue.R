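#' The fixed phenotypic feature catalogue
#'
#' Returns the ordered catalogue of the 126 phenotypic features computed per
#' well. Features fall into four classes — `shape`, `intensity`, `texture`
#' (gray-level co-occurrence) and `context` (counts, channel correlations and
#' spatial relationships) — and are attached to a compartment (`nucleus`,
#' `cell`, `cytoplasm`, `membrane` or `field`) and, where applicable, one or
#' two fluorescence channels (DNA/Hoechst, TH, aSyn, MAP2).
#'
#' The catalogue is data, not code: it is read from a registry file shipped
#' with the package, its order is stable across runs, and downstream tables
#' always carry exactly these columns in this order. [catalogue_hash()] gives
#' a schema fingerprint recorded in every output manifest.
#'
#' @return A data.frame with 126 rows and columns `name`, `class`,
#'   `compartment`, `channel`, `level` (`cell` for per-cell features averaged
#'   over living cells, `field` for field-level features averaged over
#'   fields), `units`.
#' @export
#' @examples
#' cat126 <- feature_catalogue()
#' nrow(cat126)     # 126
#' table(cat126$class)
feature_catalogue <- function() {
  path <- system.file("extdata", "feature_catalogue.csv", package = "edcprofiler")
  cat_df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(cat_df) == 126L, !anyDuplicated(cat_df$name))
  cat_df
}

#' Schema fingerprint of the feature catalogue
#'
#' MD5 hash of the ordered feature names; recorded alongside every feature
#' table so that consumers can detect catalogue drift.
#'
#' @return A length-one character MD5 string.
#' @export
catalogue_hash <- function() {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(feature_catalogue()$name, tf)
  unname(tools::md5sum(tf))
}

#' Names of the headline dose-response features
#'
#' The features reported individually in the dose-response analyses:
#' living-cell count, aSyn intensity in TH-positive cells, neurite length and
#' branch points per cell, overall and membrane TH intensity, and the
#' TH/aSyn double-positive surface intensity.
#'
#' @return Character vector of catalogue feature names.
#' @export
headline_features <- function() {
  c("ctx_n_living_cells",
    "ctx_asyn_mean_th_pos_cells",
    "ctx_neurite_length_per_cell_um",
    "ctx_branch_points_per_cell",
    "int_th_cell_mean",
    "int_th_membrane_mean",
    "ctx_th_asyn_dpos_integrated")
}

# metadata columns that accompany the 126 feature columns in a well table
.meta_cols <- c("plate", "well", "compound", "dose_uM", "replicate",
                "n_fields", "n_living_cells")
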