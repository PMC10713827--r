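#!/usr/bin/env Rscript
# Segment every field written by 01_simulate.R and extract the 126-feature
# well profiles. Wells are re-rendered deterministically in a streaming
# pass (identical to the TIFFs on disk, see the round-trip test), so this
# script does not need to hold the plate in memory.

library(edcprofiler)

seed <- 1L
cfg <- small_config()
layout <- build_plate_layout(cfg)
effects <- default_effect_model(cfg$doses_uM, cfg$compounds)

plate <- process_plate(layout, effects, cfg, seed = seed)
wells <- plate$wells

dir.create("results", showWarnings = FALSE)
write.csv(wells, "results/well_features.csv", row.names = FALSE)
if (requireNamespace("arrow", quietly = TRUE))
  arrow::write_parquet(wells, "results/well_features.parquet")

cat("well table:", nrow(wells), "wells x", length(feature_cols(wells)),
    "features\n")
cat("living cells/well: median",
    median(wells$n_living_cells), "range",
    paste(range(wells$n_living_cells), collapse = "-"), "\n")
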