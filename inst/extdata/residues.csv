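item,concentration_ng_g,compound
crop_seed,555600,CTD
crop_seedlings,3425,CTD
exposed_birds,56,IMI
eggs_exposed_bird,28,IMI
wild_plants_field_margin,0.51,CTD
invertebrates,11.1,IMI
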