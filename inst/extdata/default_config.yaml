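# Default simulation: a 254-image cohort with population lordosis
# N(20, 10) degrees, mild degenerative wedging and listhesis, and human
# annotation noise calibrated to give test-retest ARA error SD near 2 deg.
generator:
  n_images: 254
  seed: 1234
  ara_mean: 20
  ara_sd: 10
  base_tilt_mean: 0
  base_tilt_sd: 5
  listhesis_sd: 0.5
  wedge_sd: 1
  global_rotation_sd: 2
  global_translation_sd: 5
noise:
  sigma: 0.15
  cv_sigma: 0.15
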