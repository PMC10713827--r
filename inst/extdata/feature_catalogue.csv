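name,class,compartment,channel,level,units
int_th_nucleus_mean,intensity,nucleus,th,cell,au
int_th_nucleus_median,intensity,nucleus,th,cell,au
int_th_nucleus_sd,intensity,nucleus,th,cell,au
int_th_nucleus_integrated,intensity,nucleus,th,cell,au
int_asyn_nucleus_mean,intensity,nucleus,asyn,cell,au
int_asyn_nucleus_median,intensity,nucleus,asyn,cell,au
int_asyn_nucleus_sd,intensity,nucleus,asyn,cell,au
int_asyn_nucleus_integrated,intensity,nucleus,asyn,cell,au
int_map2_nucleus_mean,intensity,nucleus,map2,cell,au
int_map2_nucleus_median,intensity,nucleus,map2,cell,au
int_map2_nucleus_sd,intensity,nucleus,map2,cell,au
int_map2_nucleus_integrated,intensity,nucleus,map2,cell,au
int_th_cell_mean,intensity,cell,th,cell,au
int_th_cell_median,intensity,cell,th,cell,au
int_th_cell_sd,intensity,cell,th,cell,au
int_th_cell_integrated,intensity,cell,th,cell,au
int_asyn_cell_mean,intensity,cell,asyn,cell,au
int_asyn_cell_median,intensity,cell,asyn,cell,au
int_asyn_cell_sd,intensity,cell,asyn,cell,au
int_asyn_cell_integrated,intensity,cell,asyn,cell,au
int_map2_cell_mean,intensity,cell,map2,cell,au
int_map2_cell_median,intensity,cell,map2,cell,au
int_map2_cell_sd,intensity,cell,map2,cell,au
int_map2_cell_integrated,intensity,cell,map2,cell,au
int_th_cytoplasm_mean,intensity,cytoplasm,th,cell,au
int_th_cytoplasm_median,intensity,cytoplasm,th,cell,au
int_th_cytoplasm_sd,intensity,cytoplasm,th,cell,au
int_th_cytoplasm_integrated,intensity,cytoplasm,th,cell,au
int_asyn_cytoplasm_mean,intensity,cytoplasm,asyn,cell,au
int_asyn_cytoplasm_median,intensity,cytoplasm,asyn,cell,au
int_asyn_cytoplasm_sd,intensity,cytoplasm,asyn,cell,au
int_asyn_cytoplasm_integrated,intensity,cytoplasm,asyn,cell,au
int_map2_cytoplasm_mean,intensity,cytoplasm,map2,cell,au
int_map2_cytoplasm_median,intensity,cytoplasm,map2,cell,au
int_map2_cytoplasm_sd,intensity,cytoplasm,map2,cell,au
int_map2_cytoplasm_integrated,intensity,cytoplasm,map2,cell,au
int_th_membrane_mean,intensity,membrane,th,cell,au
int_th_membrane_median,intensity,membrane,th,cell,au
int_th_membrane_sd,intensity,membrane,th,cell,au
int_th_membrane_integrated,intensity,membrane,th,cell,au
int_asyn_membrane_mean,intensity,membrane,asyn,cell,au
int_asyn_membrane_median,intensity,membrane,asyn,cell,au
int_asyn_membrane_sd,intensity,membrane,asyn,cell,au
int_asyn_membrane_integrated,intensity,membrane,asyn,cell,au
int_map2_membrane_mean,intensity,membrane,map2,cell,au
int_map2_membrane_median,intensity,membrane,map2,cell,au
int_map2_membrane_sd,intensity,membrane,map2,cell,au
int_map2_membrane_integrated,intensity,membrane,map2,cell,au
shp_nucleus_area_um2,shape,nucleus,none,cell,um2
shp_nucleus_perimeter_um,shape,nucleus,none,cell,um
shp_nucleus_eccentricity,shape,nucleus,none,cell,ratio
shp_nucleus_solidity,shape,nucleus,none,cell,ratio
shp_nucleus_form_factor,shape,nucleus,none,cell,ratio
shp_cell_area_um2,shape,cell,none,cell,um2
shp_cell_perimeter_um,shape,cell,none,cell,um
shp_cell_eccentricity,shape,cell,none,cell,ratio
shp_cell_solidity,shape,cell,none,cell,ratio
shp_cell_form_factor,shape,cell,none,cell,ratio
shp_cytoplasm_area_um2,shape,cytoplasm,none,cell,um2
shp_cytoplasm_perimeter_um,shape,cytoplasm,none,cell,um
shp_cytoplasm_eccentricity,shape,cytoplasm,none,cell,ratio
shp_cytoplasm_solidity,shape,cytoplasm,none,cell,ratio
shp_cytoplasm_form_factor,shape,cytoplasm,none,cell,ratio
shp_membrane_area_um2,shape,membrane,none,cell,um2
shp_membrane_perimeter_um,shape,membrane,none,cell,um
shp_membrane_eccentricity,shape,membrane,none,cell,ratio
shp_membrane_solidity,shape,membrane,none,cell,ratio
shp_membrane_form_factor,shape,membrane,none,cell,ratio
tex_asyn_cell_asm,texture,cell,asyn,cell,ratio
tex_asyn_cell_contrast,texture,cell,asyn,cell,ratio
tex_asyn_cell_correlation,texture,cell,asyn,cell,ratio
tex_asyn_cell_homogeneity,texture,cell,asyn,cell,ratio
tex_asyn_cytoplasm_asm,texture,cytoplasm,asyn,cell,ratio
tex_asyn_cytoplasm_contrast,texture,cytoplasm,asyn,cell,ratio
tex_asyn_cytoplasm_correlation,texture,cytoplasm,asyn,cell,ratio
tex_asyn_cytoplasm_homogeneity,texture,cytoplasm,asyn,cell,ratio
tex_th_cell_asm,texture,cell,th,cell,ratio
tex_th_cell_contrast,texture,cell,th,cell,ratio
tex_th_cell_correlation,texture,cell,th,cell,ratio
tex_th_cell_homogeneity,texture,cell,th,cell,ratio
tex_th_cytoplasm_asm,texture,cytoplasm,th,cell,ratio
tex_th_cytoplasm_contrast,texture,cytoplasm,th,cell,ratio
tex_th_cytoplasm_correlation,texture,cytoplasm,th,cell,ratio
tex_th_cytoplasm_homogeneity,texture,cytoplasm,th,cell,ratio
tex_map2_cell_asm,texture,cell,map2,cell,ratio
tex_map2_cell_contrast,texture,cell,map2,cell,ratio
tex_map2_cell_correlation,texture,cell,map2,cell,ratio
tex_map2_cell_homogeneity,texture,cell,map2,cell,ratio
tex_map2_cytoplasm_asm,texture,cytoplasm,map2,cell,ratio
tex_map2_cytoplasm_contrast,texture,cytoplasm,map2,cell,ratio
tex_map2_cytoplasm_correlation,texture,cytoplasm,map2,cell,ratio
tex_map2_cytoplasm_homogeneity,texture,cytoplasm,map2,cell,ratio
ctx_corr_dna_th_cell,context,cell,dna_th,field,r
ctx_corr_dna_asyn_cell,context,cell,dna_asyn,field,r
ctx_corr_dna_map2_cell,context,cell,dna_map2,field,r
ctx_corr_th_asyn_cell,context,cell,th_asyn,field,r
ctx_corr_th_map2_cell,context,cell,th_map2,field,r
ctx_corr_asyn_map2_cell,context,cell,asyn_map2,field,r
ctx_corr_dna_th_cytoplasm,context,cytoplasm,dna_th,field,r
ctx_corr_dna_asyn_cytoplasm,context,cytoplasm,dna_asyn,field,r
ctx_corr_dna_map2_cytoplasm,context,cytoplasm,dna_map2,field,r
ctx_corr_th_asyn_cytoplasm,context,cytoplasm,th_asyn,field,r
ctx_corr_th_map2_cytoplasm,context,cytoplasm,th_map2,field,r
ctx_corr_asyn_map2_cytoplasm,context,cytoplasm,asyn_map2,field,r
ctx_n_living_cells,context,field,none,field,count
ctx_n_nuclei_total,context,field,none,field,count
ctx_apoptotic_fraction,context,field,none,field,ratio
ctx_living_density_per_mm2,context,field,none,field,per_mm2
ctx_n_th_pos_cells,context,field,none,field,count
ctx_fraction_th_pos_cells,context,field,none,field,ratio
ctx_nn_soma_dist_mean_um,context,field,none,field,um
ctx_nn_soma_dist_sd_um,context,field,none,field,um
ctx_nn_soma_dist_min_um,context,field,none,field,um
ctx_neurite_length_per_cell_um,context,field,map2,field,um
ctx_branch_points_per_cell,context,field,map2,field,count
ctx_neurite_length_total_um,context,field,map2,field,um
ctx_branch_points_total,context,field,map2,field,count
ctx_branches_per_100um,context,field,map2,field,per_100um
ctx_asyn_mean_th_pos_cells,context,cell,asyn,field,au
ctx_th_asyn_dpos_integrated,context,field,th_asyn,field,au
ctx_th_asyn_dpos_area_fraction,context,field,th_asyn,field,ratio
ctx_map2_area_per_nucleus_um2,context,field,map2,field,um2
ctx_map2_area_fraction,context,field,map2,field,ratio
ctx_th_area_fraction,context,field,th,field,ratio
ctx_nucleus_area_mean_living_um2,context,nucleus,dna,field,um2
ctx_nucleus_dna_mean_living,context,nucleus,dna,field,au
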