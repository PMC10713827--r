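#' Default pipeline configuration
#'
#' All tunable thresholds and parameters of the pipeline in one list. The
#' printed experimental constants keep their published values: viability
#' calls use nuclei larger than 2000 px with mean DNA intensity below 1500,
#' the membrane rim is a 5-pixel window inside the cell edge, the pixel pitch
#' is 0.1628 um/px (2000 px ~ 53 um2, 5 px ~ 0.81 um), the test split is 10%,
#' hyperparameter search uses 5-fold CV, model assessment 10-fold CV, and
#' significance tiers are 0.05/0.01/0.001.
#'
#' Intensities are on a 16-bit scale with background around 200 counts and
#' somatic signal in the 2500-8000 range, so that the 1500 nucleus-intensity
#' threshold discriminates normal from pyknotic (condensed, bright) nuclei.
#'
#' @param ... named overrides of any config entry.
#' @return A named list of class `edc_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    # geometry / optics
    pixel_pitch_um = 0.1628,
    image_size = 256L,
    # plate design
    compounds = c("BPA", "BPS", "PFOS", "PFOA"),
    doses_uM = c(0.01, 0.1, 1, 2),
    wells_per_condition = 3L,
    vehicle_wells = 12L,
    fields_per_well = 16L,
    replicates = 2L,
    # rendering
    cells_per_field = 5,
    background_level = 200,
    illumination_gradient = 0.15,
    read_noise_sd = 25,
    apoptotic_fraction = 0.06,
    replicate_sd = 0.03,
    well_sd = 0.02,
    cell_sd = 0.12,
    th_pos_prob = 0.85,
    # segmentation
    viability_min_area_px = 2000,
    viability_max_mean_intensity = 1500,
    membrane_width_px = 5L,
    soma_opening_radius_px = 8L,
    nucleus_threshold = 350,   # fixed, calibrated to the synthetic scale;
    cell_threshold = 1000,     # "otsu" selects automatic per-image thresholds

    nucleus_min_area_px = 80,
    cell_max_seed_dist_px = 120,
    spur_prune_px = 3L,
    # features
    th_pos_threshold = 1000,
    glcm_levels = 16L,
    glcm_quantiles = c(0.01, 0.99),
    # classification
    test_fraction = 0.10,
    grid_cv_folds = 5L,
    cv_folds = 10L,
    scale_before_split = FALSE,   # TRUE = scale whole table before splitting
    group_by_replicate = FALSE,
    # statistics
    alpha_tiers = c(0.05, 0.01, 0.001)
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  structure(cfg, class = "edc_config")
}

#' Small configuration for desk-scale runs
#'
#' The default small synthetic experiment used by the analysis scripts and
#' the reproduction study: 4 compounds x 4 doses with 3 wells each plus 12
#' vehicle wells (60 wells, 12+ per classification class), 4 fields per well,
#' 256x256 px fields. This keeps a full pipeline run to a couple of minutes
#' on one CPU while preserving the statistical structure of the full design.
#'
#' @param ... named overrides, as in [default_config()].
#' @return An `edc_config` list.
#' @export
small_config <- function(...) {
  default_config(fields_per_well = 4L, ...)
}

#' Default dose-effect model
#'
#' Per-compound, per-dose multipliers applied by the image generator to the
#' phenotype axes the chemicals act on: aSyn cytoplasmic intensity, TH
#' cytoplasmic and membrane intensity, neurite length and branching. Effects
#' follow a saturating dose-response over the tested doses (0.01, 0.1, 1,
#' 2 uM) and are class-coupled: the two bisphenols share a signature
#' (stronger aSyn increase and neurite loss), the two perfluoroalkyls share
#' another (stronger TH increase). The vehicle condition has all multipliers
#' equal to 1, and the apoptotic fraction is not modulated by treatment
#' (viability is unaffected by design).
#'
#' @param doses_uM dose grid (default the tested doses).
#' @param compounds compound names.
#' @return data.frame of class `edc_effects` with one row per
#'   (compound, dose) plus a vehicle row; columns `asyn_mult`,
#'   `th_cyto_mult`, `th_mem_mult`, `neurite_mult`, `branch_mult`,
#'   `apoptotic_delta`.
#' @export
default_effect_model <- function(doses_uM = c(0.01, 0.1, 1, 2),
                                 compounds = c("BPA", "BPS", "PFOS", "PFOA")) {
  # saturating fractional response at each tested dose
  sat <- c(0.25, 0.5, 0.8, 1)[seq_along(doses_uM)]
  class_of <- function(cmp) if (cmp %in% c("BPA", "BPS")) "BP" else "PF"
  max_eff <- list(
    BP = c(asyn = 1.60, th_cyto = 1.25, th_mem = 1.30, neurite = 0.65, branch = 0.65),
    PF = c(asyn = 1.35, th_cyto = 1.45, th_mem = 1.50, neurite = 0.75, branch = 0.70))
  rows <- list(data.frame(compound = "vehicle", dose_uM = 0, asyn_mult = 1,
                          th_cyto_mult = 1, th_mem_mult = 1, neurite_mult = 1,
                          branch_mult = 1, apoptotic_delta = 0))
  for (cmp in compounds) {
    m <- max_eff[[class_of(cmp)]]
    for (i in seq_along(doses_uM)) {
      s <- sat[i]
      rows[[length(rows) + 1L]] <- data.frame(
        compound = cmp, dose_uM = doses_uM[i],
        asyn_mult = 1 + (m[["asyn"]] - 1) * s,
        th_cyto_mult = 1 + (m[["th_cyto"]] - 1) * s,
        th_mem_mult = 1 + (m[["th_mem"]] - 1) * s,
        neurite_mult = 1 - (1 - m[["neurite"]]) * s,
        branch_mult = 1 - (1 - m[["branch"]]) * s,
        apoptotic_delta = 0)
    }
  }
  structure(do.call(rbind, rows), class = c("edc_effects", "data.frame"))
}

#' Null (zero-effect) model
#'
#' All multipliers equal to 1 for every compound and dose; treated and
#' vehicle wells are then statistically exchangeable by construction.
#'
#' @inheritParams default_effect_model
#' @return An `edc_effects` data.frame.
#' @export
zero_effect_model <- function(doses_uM = c(0.01, 0.1, 1, 2),
                              compounds = c("BPA", "BPS", "PFOS", "PFOA")) {
  em <- default_effect_model(doses_uM, compounds)
  em$asyn_mult <- em$th_cyto_mult <- em$th_mem_mult <- 1
  em$neurite_mult <- em$branch_mult <- 1
  em$apoptotic_delta <- 0
  em
}

# look up the effect row for one condition; vehicle rows are all-ones
effect_for <- function(effects, compound, dose_uM) {
  if (identical(compound, "vehicle") || dose_uM == 0) {
    hit <- effects[effects$compound == "vehicle", , drop = FALSE]
    if (nrow(hit) == 0)
      hit <- data.frame(compound = "vehicle", dose_uM = 0, asyn_mult = 1,
                        th_cyto_mult = 1, th_mem_mult = 1, neurite_mult = 1,
                        branch_mult = 1, apoptotic_delta = 0)
    return(hit[1, ])
  }
  hit <- effects[effects$compound == compound & effects$dose_uM == dose_uM, , drop = FALSE]
  if (nrow(hit) == 0)
    stop("unknown compound/dose combination: ", compound, " @ ", dose_uM, " uM")
  hit[1, ]
}
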