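# End-to-end demo: small brain phantom, fixed 7/70 ramp (no design grid
# search), spiral acquisition, subspace reconstruction, dictionary maps
# and angiographic projection.
seed: 1
stages: [simulate, recon, infer, angio]
design:
  alpha_a: 7
  alpha_b: 70
  N: 260
simulate:
  shape: 64
  phantom: brain2d
  n_coils: 4
  snr_db: 30
  vessel_v: 50
recon:
  rank: 10
  lambda: 0.005
  iters: 10
  cg_iters: 6
infer:
  method: dict
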