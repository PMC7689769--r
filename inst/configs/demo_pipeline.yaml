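# end-to-end smoke configuration: small tube-grid phantom, identity encoding
seed: 1
stages: [simulate, recon, report]
phantom:
  kind: tube_grid
  voxel_mm: 2
sim:
  noise_sd: 0
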