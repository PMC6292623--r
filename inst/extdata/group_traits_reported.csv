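trait,entire,hh,rest
n_species,172,61,167
n_individuals,2158,168,1990
n_quadrats,575,18,557
area_m2,2300,72,2228
pct_trees,50.56,34.52,52.35
pct_shrubs,38.14,42.26,37.27
pct_palms,5.00,10.72,4.60
pct_vines_cacti,6.3,12.50,5.78
density_trees,0.474,0.806,0.464
density_se_trees,0.018,0.138,0.018
density_shrubs,0.358,0.986,0.338
density_se_shrubs,0.019,0.180,0.018
density_palms,0.047,0.250,0.040
density_se_palms,0.007,0.114,0.006
density_vines_cacti,0.020,0.097,0.017
density_se_vines_cacti,0.002,0.029,0.002
density_all,0.156,0.389,0.149
density_se_all,0.006,0.056,0.006
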