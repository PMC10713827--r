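# Shared fixtures, computed once per test run and memoized. All heavier
# image work lives here so individual test files stay fast.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, make) {
  if (!exists(name, envir = .fixtures)) assign(name, make(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# one default-density vehicle field (channels + ground truth)
fix_field <- function() memo("field", function() {
  cfg <- default_config()
  cond <- data.frame(compound = "vehicle", dose_uM = 0, replicate = 1L)
  generate_field(cond, default_effect_model(), cfg, seed = 101L)
})

# the same field segmented
fix_seg <- function() memo("seg", function() {
  segment_field(fix_field()$channels, default_config())
})

# the same field featurized
fix_feat <- function() memo("feat", function() {
  featurize_field(fix_seg(), default_config())
})

# a sparse field (2 cells) where neurites are unoccluded, for skeleton
# recovery against ground truth
fix_sparse_field <- function() memo("sparse_field", function() {
  cfg <- default_config(cells_per_field = 2)
  cond <- data.frame(compound = "vehicle", dose_uM = 0, replicate = 1L)
  generate_field(cond, default_effect_model(), cfg, seed = 7L)
})

# a zero-effect (null) plate: 60 wells x 1 field, treated and vehicle wells
# statistically exchangeable by construction
fix_null_wells <- function() memo("null_wells", function() {
  cfg <- small_config(fields_per_well = 1L)
  # single-field wells can draw zero living cells (warned, features NA);
  # those rows are dropped like in the pipeline
  w <- suppressWarnings(
    process_plate(build_plate_layout(cfg), zero_effect_model(), cfg,
                  seed = 77L)$wells)
  w[!is.na(w$n_living_cells) & w$n_living_cells > 0, , drop = FALSE]
})

# a default-effect plate: 60 wells x 2 fields, used for profiling,
# classification and dose-response tests
fix_wells <- function() memo("wells", function() {
  cfg <- small_config(fields_per_well = 2L)
  process_plate(build_plate_layout(cfg), default_effect_model(), cfg,
                seed = 55L)$wells
})
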