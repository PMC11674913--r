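# Default end-to-end run: CHO viable/non-viable mixture at 8 Vpp, 6 MHz.
# Device-level units: um, um/s; converted to SI on load.
drive:
  electrode_width_um: 35
  gap_um: 25
  vpp: 8
  frequency_hz: 6.0e+6
channel:
  height_um: 50
  width_um: 8000
  vbar_um_s: 1000
medium:
  rel_permittivity: 78
  conductivity: 0.17
  density: 1017.5
  viscosity: 1.0e-3
optics:
  um_per_pixel: 0.62
  frame_rate: 226
  frame_px: [1080, 1442]
population:
  arrival_rate: 10
  components:
    - name: viable
      fraction: 0.45
      diam_mean_um: 12.5
      diam_sd_um: 1.25
      diam_bounds_um: [10, 15]
      preset: cho_viable
      rho_p: 1050
    - name: nonviable
      fraction: 0.55
      diam_mean_um: 11
      diam_sd_um: 1.25
      diam_bounds_um: [9, 14]
      preset: cho_nonviable
      rho_p: 1050
mapping:
  r_axis_um: [4.5, 5.5, 6.5, 7.5]
  kcm_axis: [-0.3, -0.1, 0.1, 0.3, 0.5]
  vi_axis_um_s: [780, 960, 1140, 1320, 1480]
tracking:
  sigma_px: 1
  mad_k: 4
  d_min_um: 5
  d_max_um: 30
  ecc_max: 0.9
  max_disp_px: 15
  memory_frames: 2
seeds:
  master: 1
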