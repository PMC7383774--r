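# Small, fast phantom fixtures shared across tests (built in code at test
# time; nothing stored on disk).

tiny_phantom_config <- function(seed = 1L, ...) {
  args <- list(image_size = 64L, pixel_spacing = 0.2, n_frames = 10L,
               lateral_amplitude = 0.8, septal_amplitude = 0.5,
               label_radius = 2L, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_config, args)
}

tiny_net_config <- function() {
  network_config(n_classes = 3L, depth = 2L, base_channels = 4L,
                 input_size = 16L)
}

random_trajectory <- function(n = 8L, spacing = 0.1, seed = 1L) {
  set.seed(seed)
  tb <- tibble::tibble(frame = seq_len(n), annulus = "lateral",
                       row = runif(n, 0, 50), col = runif(n, 0, 50))
  rvtrack:::new_trajectory(tb, spacing)
}

make_trajectory <- function(pos, spacing = NA_real_, annulus = "lateral") {
  tb <- tibble::tibble(frame = seq_len(nrow(pos)), annulus = annulus,
                       row = pos[, 1L], col = pos[, 2L])
  rvtrack:::new_trajectory(tb, spacing)
}
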