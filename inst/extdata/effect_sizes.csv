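factor,category,sample_size,effect_percent,applies_to_map
crop_type,Cereal grains,106,31.41,TRUE
crop_type,Grasses,154,24.33,FALSE
crop_type,Legumes,42,9.19,TRUE
soil_ph,Low,93,33.43,TRUE
soil_ph,Medium,76,33.64,TRUE
soil_ph,High,81,13.63,TRUE
soil_texture,Sandy,16,9.64,TRUE
soil_texture,Loamy,110,20.74,TRUE
soil_texture,Clayey,52,46.79,TRUE
n_rate,Low,183,19.00,TRUE
n_rate,High,25,8.51,TRUE
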