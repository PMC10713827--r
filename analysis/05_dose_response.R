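#!/usr/bin/env Rscript
# Dose-response statistics on the headline features: control-normalized
# means with 95% CIs, one-way ANOVA per feature x compound, Tukey post-hoc
# dose-vs-vehicle contrasts and significance stars.

library(edcprofiler)

wells <- read.csv("results/well_features.csv")
ok <- !is.na(wells$n_living_cells) & wells$n_living_cells > 0
dr <- dose_response_table(wells[ok, ], config = small_config())
write.csv(dr, "results/dose_response.csv", row.names = FALSE)

cat("rows:", nrow(dr), " significant contrasts:",
    sum(dr$stars != "ns"), "\n\n")
show <- dr[dr$feature == "ctx_neurite_length_per_cell_um", ]
print(show[order(show$compound, show$dose_uM),
           c("compound", "dose_uM", "mean_norm", "ci_lo", "ci_hi",
             "anova_p", "p_adj", "stars")],
      row.names = FALSE, digits = 3)
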