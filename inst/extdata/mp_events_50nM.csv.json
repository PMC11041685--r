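{"true_particle_fractions":[9.09208704074886e-08,2.98188423698468e-09,0.344984479765431,0.654982288723877,3.31376079372055e-05],"true_subunit_fractions":[6.55929540405921e-09,4.30243561977146e-10,0.149329088192106,0.850541810086229,0.00012909473212666],"monomer_mass":44.3,"error_model":{"sd_floor_kda":4,"sd_frac":0.02},"n_events":300,"seed":42}
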