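# Compact phantom used throughout the tests: default mm geometry on a grid
# just large enough (~168 mm extent) for the structures, few frames.
small_phantom <- function(true_ratio = 1.0, spacing = 1.46, noise_sigma = 0,
                          n_frames = 6L, end_systolic_frame = 3L, seed = 1L,
                          ...) {
  shape <- ceiling(168 / spacing) + 1L
  phantom_spec(image_shape = c(shape, shape),
               pixel_spacing = c(spacing, spacing),
               n_frames = n_frames,
               end_systolic_frame = end_systolic_frame,
               true_ratio = true_ratio,
               noise_sigma = noise_sigma,
               seed = seed,
               ...)
}
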