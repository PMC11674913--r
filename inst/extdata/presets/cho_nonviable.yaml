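# Non-viable CHO cell, double-shell dielectric parameters (SI units).
model: double_shell
r_cell: 5.5e-6
r_n_fraction: 0.55
d_n: 4.0e-8
d_mem: 5.0e-9
sigma_mem: 1.0e-6
sigma_ne: 1.0e-3
sigma_cyt: 0.07
sigma_n: 0.56
eps_mem: 5.0
eps_ne: 11.5
eps_cyt: 54.5
eps_n: 69
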