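# example pipeline configuration (flat key = value; see ?read_chamber_config)
otsu_scale = 0.2
filter_window = 15
cv_mu = 0.15
shrink_orient = 0.85
shrink_follicle = 0.80
oocyte_frac_threshold = 0.10
n_sectors = 12
pixel_size = 0.31
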