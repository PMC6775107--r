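# Demo run configuration: a small two-layer phantom (coenosarc-like tissue
# over skeleton) that simulates and processes in about a minute on one CPU.
acquisition:
  lambda_min: 520
  lambda_max: 720
  n_k: 1024
  pixel_pitch_um: 5
  rolloff_db_per_mm: -10
  noise_rel: 0.0316        # 30 dB SNR
  medium_index: 1.35
  rng_seed: 1
phantom:
  nx: 24
  ny: 24
  dz_um: 2
  depth_um: 420
  surface_um: 60
  solid_angle: 0.01
  regions:
    - name: tissue_over_skeleton
      layers:
        - {name: tissue, thickness_um: 150, D: 2.5, Ln: 600,
           mu_s_600: 100, chl_mg_cm3: 0.3, backscatter_scale: 1}
        - {name: skeleton, thickness_um: 200, D: 3.5, Ln: 800,
           mu_s_600: 200, chl_mg_cm3: 0, backscatter_scale: 1}
fit:
  depth_window_um: 90
  lateral_kernel: 3
  block: 8
  seed: 1
lookup:
  lambda_ref: 620
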