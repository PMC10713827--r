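test_that("GLCM is a normalized symmetric probability matrix", {
  set.seed(3)
  img <- matrix(runif(64 * 64, 0, 65535), 64, 64)
  region <- matrix(TRUE, 64, 64)
  P <- glcm_matrix(img, region)
  expect_equal(sum(P), 1)
  expect_equal(P, t(P))
  expect_true(all(P >= 0))
})

test_that("constant regions give ASM = 1 and zero contrast", {
  img <- matrix(777, 32, 32)
  P <- glcm_matrix(img, matrix(TRUE, 32, 32))
  st <- glcm_stats(P)
  expect_equal(unname(st["asm"]), 1)
  expect_equal(unname(st["contrast"]), 0)
  expect_equal(unname(st["entropy"]), 0)
})

test_that("GLCM stats match a hand-computed 2x2 oracle", {
  # P = [[0.5, 0.25], [0.25, 0]]
  P <- matrix(c(0.5, 0.25, 0.25, 0), 2, 2)
  st <- glcm_stats(P)
  expect_equal(unname(st["asm"]), 0.5^2 + 2 * 0.25^2)
  expect_equal(unname(st["contrast"]), 2 * 0.25 * 1)
  expect_equal(unname(st["homogeneity"]), 0.5 + 2 * 0.25 / 2)
  expect_equal(unname(st["entropy"]), -(0.5 * log2(0.5) + 2 * 0.25 * log2(0.25)))
})

test_that("degenerate and tiny regions are handled", {
  img <- matrix(1:16, 4, 4)
  one_px <- matrix(FALSE, 4, 4); one_px[2, 2] <- TRUE
  expect_null(glcm_matrix(img, one_px))
  expect_equal(unname(glcm_stats(NULL)["asm"]), 0)
})

test_that("solidity is 1 for convex shapes and < 1 for concave ones", {
  sq <- which(matrix(TRUE, 10, 10), arr.ind = TRUE)
  expect_equal(edcprofiler:::region_solidity(sq[, 1], sq[, 2]), 1)
  # an L-shape is concave
  m <- matrix(FALSE, 12, 12); m[1:12, 1:4] <- TRUE; m[9:12, 1:12] <- TRUE
  px <- which(m, arr.ind = TRUE)
  expect_lt(edcprofiler:::region_solidity(px[, 1], px[, 2]), 0.85)
})

test_that("unit conversions match the printed constants", {
  pitch <- default_config()$pixel_pitch_um
  expect_equal(2000 * pitch^2, 53.0, tolerance = 0.01)
  expect_equal(5 * pitch, 0.81, tolerance = 0.01)
  # and area features use exactly this conversion
  lab <- matrix(0L, 40, 40); lab[10:19, 10:19] <- 1L
  sh <- shape_features(lab, pixel_pitch_um = pitch)
  expect_equal(sh$area_um2, 100 * pitch^2)
})

test_that("intensity statistics agree with direct computation (dual route)", {
  seg <- fix_seg()
  ids <- sort(setdiff(unique(as.vector(seg$cytoplasm)), 0L))
  st <- edcprofiler:::intensity_stats(seg$cytoplasm, seg$corrected$asyn, ids)
  L <- ids[1]
  v <- seg$corrected$asyn[seg$cytoplasm == L]
  expect_equal(unname(st[1, "mean"]), mean(v))
  expect_equal(unname(st[1, "median"]), stats::median(v))
  expect_equal(unname(st[1, "sd"]), stats::sd(v))
  expect_equal(unname(st[1, "integrated"]), sum(v))
})

test_that("featurize_field emits the exact per-cell and field catalogues", {
  feat <- fix_feat()
  cat126 <- feature_catalogue()
  expect_setequal(setdiff(names(feat$cell_table), "label"),
                  cat126$name[cat126$level == "cell"])
  expect_setequal(names(feat$field_row), cat126$name[cat126$level == "field"])
  expect_equal(nrow(feat$cell_table), feat$n_living)
})

test_that("field counts agree with the ground truth", {
  gt <- fix_field()$ground_truth
  feat <- fix_feat()
  expect_equal(feat$n_living, sum(gt$viable))
  expect_equal(feat$n_nuclei, nrow(gt))
  expect_equal(unname(feat$field_row["ctx_n_living_cells"]), sum(gt$viable))
  expect_equal(unname(feat$field_row["ctx_apoptotic_fraction"]),
               mean(!gt$viable))
})

test_that("channel correlation features are true Pearson correlations", {
  seg <- fix_seg()
  feat <- fix_feat()
  mask <- seg$cell > 0
  oracle <- stats::cor(seg$corrected$th[mask], seg$corrected$asyn[mask])
  expect_equal(unname(feat$field_row["ctx_corr_th_asyn_cell"]), oracle,
               tolerance = 1e-12)
})

test_that("a well row carries exactly 126 features in catalogue order", {
  feat <- fix_feat()
  w <- featurize_well(list(feat), list(plate = "p", well = "B02",
                                       compound = "vehicle", dose_uM = 0,
                                       replicate = 1L))
  expect_equal(ncol(w), 7 + 126)
  expect_identical(names(w)[-(1:7)], feature_catalogue()$name)
  expect_false(anyNA(w[, feature_cols(w)][
    , setdiff(feature_cols(w), "ctx_asyn_mean_th_pos_cells")]))
})

test_that("a well with zero living cells yields NA features and a warning", {
  empty <- list(cell_table = NULL, field_row = NULL, n_living = 0L,
                n_nuclei = 0L)
  expect_warning(
    w <- featurize_well(list(empty), list(plate = "p", well = "B03",
                                          compound = "vehicle", dose_uM = 0,
                                          replicate = 1L)),
    "zero living cells")
  expect_true(all(is.na(w[, feature_cols(w)])))
})
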