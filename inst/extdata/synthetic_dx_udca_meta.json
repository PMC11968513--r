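{"sample_mass_mg":5,"medium_volume_ml":2,"loadings":{"DX":{"loading_per_mg":95.79,"unit":"ug/mg","entrapment_fraction":0.8612},"UDCA":{"loading_per_mg":49.52,"unit":"ug/mg","entrapment_fraction":0.6515}}}
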