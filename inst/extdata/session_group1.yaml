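# Reference session: group 1 of the BPD mouse study.
# 50 mW/cm2 from the 10-mm disc for 600 s, 0.53 uM BPD, default murine
# optics (mu_a = 0.69 /cm, mu_s' = 11 /cm, g = 0.9, n = 1.4) and BPD
# photokinetics with 40 uM initial oxygen.
group: 1
source:
  fluence_rate: 50      # mW/cm2 in air
  diameter_mm: 10
grid:
  n: 100
  voxel_mm: 0.5
pk:
  S0_init_uM: 0.53
  time_s: 600
mc:
  n_photons: 2.0e6
  seed: 1
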