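# Shared fixtures, all generated in code.

# A small network configuration that exercises every layer kind quickly.
tiny_model_config <- function(n_branches = 2L) {
  model_config(input_shape = c(12L, 12L, 4L, 3L),
               branch_conv_filters = c(4L, 8L),
               conv_kernels = list(c(3L, 3L), c(3L, 3L)),
               conv_strides = list(c(2L, 2L), c(1L, 1L)),
               pool_windows = list(c(2L, 2L), c(2L, 2L)),
               pool_strides = list(c(1L, 1L), c(1L, 1L)),
               fc_widths = c(8L, 4L),
               n_branches = n_branches)
}

tiny_sample <- function(seed = 1, side = 12L, n_images = 4L) {
  set.seed(seed)
  array(runif(side * side * 3 * n_images), c(side, side, 3L, n_images))
}

# Fast scene: small native frames, short clips.
tiny_scene <- function(n_clips_per_class = 1L, frames = c(21L, 21L),
                       noise = 0.02, seed = 1L) {
  scene_config(image_size = c(60L, 80L),
               n_clips_per_class = n_clips_per_class,
               frame_count_range = frames,
               actor = c(half_width = 5, half_height = 18),
               noise_sigma = noise, seed = seed)
}

# A 16-frame window holding a single bright pixel that moves one pixel per
# frame along a row, on black background.
moving_dot_window <- function(side = 32L, row = 10L, col0 = 5L) {
  lapply(0:15, function(i) {
    f <- matrix(0, side, side)
    f[row, col0 + i] <- 1
    f
  })
}
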