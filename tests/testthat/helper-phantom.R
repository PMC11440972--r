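# Small phantom configurations used across the suite: 40^3 at 3 mm keeps
# unit tests fast while leaving room for a brain, a lesion and a background
# ROI with > 50 voxels.

small_spec <- function(grid_shape = c(40, 40, 40), spacing = c(3, 3, 3),
                       brain_semi_axes = c(50, 55, 45), noise_sigma = 0,
                       psf_fwhm = 0,
                       lesions = list(lesion_spec(center = c(12, 8, 4),
                                                  semi_axes = 9)),
                       ...) {
  phantom_spec(grid_shape = grid_shape, spacing = spacing,
               brain_semi_axes = brain_semi_axes, noise_sigma = noise_sigma,
               psf_fwhm = psf_fwhm, lesions = lesions, ...)
}

# background ROI in the hemisphere contralateral to the small_spec lesion
roi_left <- function() background_roi(center = c(-30, 0, 0), radius = 12)

# grid used by the degraded-recovery checks: 2 mm voxels, ~4.2 ml lesion
recovery_spec <- function(noise_sigma = 0, psf_fwhm = 0, seed = NULL) {
  phantom_spec(grid_shape = c(64, 64, 64), spacing = c(2, 2, 2),
               brain_semi_axes = c(55, 60, 50),
               noise_sigma = noise_sigma, psf_fwhm = psf_fwhm,
               lesions = list(lesion_spec(center = c(15, 10, 5),
                                          semi_axes = 10, tbr_true = 2.0)),
               seed = seed)
}

recovery_roi <- function() background_roi(center = c(-28, 0, 0), radius = 11)

mk_mask <- function(arr, spacing = c(1, 1, 1)) {
  binary_mask(array(as.logical(arr), dim = dim(arr)), spacing = spacing)
}

mk_vol <- function(arr, spacing = c(1, 1, 1)) {
  image_volume(arr, spacing = spacing)
}
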