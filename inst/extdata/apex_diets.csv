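label,protein_pct,carb_pct,fat_pct,energy_density_mj_kg
HP,60,20,20,14.5
HC,5,75,20,14.5
HF,5,20,75,14.5
AIN93G,20,64,16,14.5
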