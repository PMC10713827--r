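#!/usr/bin/env Rscript
# Render the synthetic plate: 4 compounds x 4 doses x 3 wells + 12 vehicle
# wells, 4 fields per well, and write the channel TIFFs plus layout and
# per-cell ground truth under results/plate/.

library(edcprofiler)

seed <- 1L
cfg <- small_config()
layout <- build_plate_layout(cfg)
effects <- default_effect_model(cfg$doses_uM, cfg$compounds)

plate <- generate_plate(layout, effects, cfg, seed = seed,
                        out_dir = "results/plate")

cat("wells:", nrow(layout), " fields/well:", cfg$fields_per_well, "\n")
cat("cells drawn:", nrow(plate$ground_truth),
    " viable:", sum(plate$ground_truth$viable), "\n")
cat("images:", length(list.files("results/plate/images")), "TIFFs\n")
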