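# builds the fixed 126-feature catalogue CSV
chans <- c("th", "asyn", "map2")
comps <- c("nucleus", "cell", "cytoplasm", "membrane")

rows <- list()
add <- function(name, class, compartment, channel, level, units) {
  rows[[length(rows) + 1]] <<- data.frame(name = name, class = class,
    compartment = compartment, channel = channel, level = level, units = units)
}

# intensity: 4 compartments x 3 channels x 4 stats = 48
for (cp in comps) for (ch in chans) for (st in c("mean", "median", "sd", "integrated"))
  add(sprintf("int_%s_%s_%s", ch, cp, st), "intensity", cp, ch, "cell",
      if (st == "integrated") "au" else "au")

# shape: 4 compartments x 5 metrics = 20
for (cp in comps) {
  add(sprintf("shp_%s_area_um2", cp), "shape", cp, "none", "cell", "um2")
  add(sprintf("shp_%s_perimeter_um", cp), "shape", cp, "none", "cell", "um")
  add(sprintf("shp_%s_eccentricity", cp), "shape", cp, "none", "cell", "ratio")
  add(sprintf("shp_%s_solidity", cp), "shape", cp, "none", "cell", "ratio")
  add(sprintf("shp_%s_form_factor", cp), "shape", cp, "none", "cell", "ratio")
}

# texture: 3 channels x 2 compartments x 4 GLCM metrics = 24
for (ch in c("asyn", "th", "map2")) for (cp in c("cell", "cytoplasm"))
  for (m in c("asm", "contrast", "correlation", "homogeneity"))
    add(sprintf("tex_%s_%s_%s", ch, cp, m), "texture", cp, ch, "cell", "ratio")

# context: 34
pairs <- c("dna_th", "dna_asyn", "dna_map2", "th_asyn", "th_map2", "asyn_map2")
for (cp in c("cell", "cytoplasm")) for (pr in pairs)
  add(sprintf("ctx_corr_%s_%s", pr, cp), "context", cp, pr, "field", "r")
for (nm in c("ctx_n_living_cells", "ctx_n_nuclei_total", "ctx_apoptotic_fraction",
             "ctx_living_density_per_mm2", "ctx_n_th_pos_cells", "ctx_fraction_th_pos_cells"))
  add(nm, "context", "field", "none", "field",
      if (grepl("density", nm)) "per_mm2" else if (grepl("fraction", nm)) "ratio" else "count")
for (nm in c("ctx_nn_soma_dist_mean_um", "ctx_nn_soma_dist_sd_um", "ctx_nn_soma_dist_min_um"))
  add(nm, "context", "field", "none", "field", "um")
add("ctx_neurite_length_per_cell_um", "context", "field", "map2", "field", "um")
add("ctx_branch_points_per_cell", "context", "field", "map2", "field", "count")
add("ctx_neurite_length_total_um", "context", "field", "map2", "field", "um")
add("ctx_branch_points_total", "context", "field", "map2", "field", "count")
add("ctx_branches_per_100um", "context", "field", "map2", "field", "per_100um")
add("ctx_asyn_mean_th_pos_cells", "context", "cell", "asyn", "field", "au")
add("ctx_th_asyn_dpos_integrated", "context", "field", "th_asyn", "field", "au")
add("ctx_th_asyn_dpos_area_fraction", "context", "field", "th_asyn", "field", "ratio")
add("ctx_map2_area_per_nucleus_um2", "context", "field", "map2", "field", "um2")
add("ctx_map2_area_fraction", "context", "field", "map2", "field", "ratio")
add("ctx_th_area_fraction", "context", "field", "th", "field", "ratio")
add("ctx_nucleus_area_mean_living_um2", "context", "nucleus", "dna", "field", "um2")
add("ctx_nucleus_dna_mean_living", "context", "nucleus", "dna", "field", "au")

cat_df <- do.call(rbind, rows)
stopifnot(nrow(cat_df) == 126, !anyDuplicated(cat_df$name))
write.csv(cat_df, "inst/extdata/feature_catalogue.csv", row.names = FALSE, quote = FALSE)
cat("wrote", nrow(cat_df), "features\n")
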