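# 10 um diameter polystyrene microsphere with surface conductance.
model: surface_conducting_sphere
radius: 5.0e-6
rel_permittivity: 2.5
k_surf: 1.0e-9
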