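# Example pipeline configuration: a small simulated image study.
# Exactly one of `simulation` or `inputs` may be present.
#
# inputs:                      # measured data instead of simulation
#   - path: mouse1_img1.tif
#     group: control
#     mouse_id: m01
#     image_id: m01_i01
# pixel_size_um: 0.5676        # calibration override for inputs

simulation:
  tabular: false               # true: draw tables directly from the GLMMs
  mice_per_group: 2
  images_per_mouse: 2
  image_shape: [256, 256]
  arterioles_per_image: 3
  capillaries_per_image: 6
  intramural_per_image: 5
  extramural_per_image: 10
  noise:
    gaussian_sd: 0.02
    poisson_scale: 0

segmentation:
  threshold_method: otsu
  min_arteriole_area_px: 150
  min_capillary_area_px: 29
  dilation_radius_px: 4

detection:
  top_hat_radius_px: 10
  mexican_hat_sigma_px: 2
  threshold_method: otsu

statistics:
  n_restarts: 3
  outlier_factor: 20

outdir: caaquant_out
seed: 1
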