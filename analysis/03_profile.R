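#!/usr/bin/env Rscript
# Phenotypic profiling: robust-scale the well features, aggregate them into
# per-condition profiles, cluster conditions by cosine distance and embed
# the control + top-dose wells in 2-D.

library(edcprofiler)

wells <- read.csv("results/well_features.csv")
ok <- !is.na(wells$n_living_cells) & wells$n_living_cells > 0
scaled <- robust_scale(wells[ok, ])

profiles <- aggregate_profiles(scaled)
clust <- cosine_distance_matrix(profiles)
write.csv(as.data.frame(profiles), "results/condition_profiles.csv")
write.csv(as.data.frame(clust$dist), "results/cosine_distances.csv")
writeLines(clust$newick, "results/condition_tree.nwk")

top <- max(wells$dose_uM)
rows <- scaled$compound == "vehicle" | scaled$dose_uM == top
emb <- embed_wells(scaled[rows, ], method = "umap", seed = 1L,
                   labels = label_wells(scaled[rows, ]))
write.csv(cbind(scaled[rows, c("well", "compound", "dose_uM")], emb$coords),
          "results/embedding.csv", row.names = FALSE)

cat("conditions profiled:", nrow(profiles), "\n")
cat("dendrogram leaf order:", paste(clust$leaf_order, collapse = " "), "\n")
cat(sprintf("UMAP silhouette (treated vs control): %.3f\n", emb$silhouette))
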