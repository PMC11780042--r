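# Small shared fixtures, built once per test run.

# A tiny configuration + phantom geometry for fast plumbing tests
# (32x64 projection grid, 48-pixel slice grid, short trainings).
tiny_config <- function() {
  cfg <- phantom_scale_config()
  cfg$loc_grid <- c(32L, 64L)
  cfg$sigma <- 4
  cfg$seg_grid <- 48L
  cfg$model$loc_base <- 2L
  cfg$model$seg_base <- 4L
  cfg$training$epochs_loc <- 2L
  cfg$training$epochs_seg <- 2L
  cfg$training$batch <- 2L
  cfg$training$validation_frac <- 0
  cfg
}

tiny_phantom_spec <- function(seed = 1, subject = "tiny", column_top = 74L) {
  phantom_spec(shape = c(48L, 48L, 80L), spacing = c(2, 2, 2),
               body_radii = c(19, 17), sat_thickness = 3,
               muscle_thickness = 2.5, spine_offset_frac = 0.45,
               vert_core_radius = 3, vert_shell_thickness = 1,
               vert_height = 10L, gap = 3L, column_top = column_top,
               n_vat_blobs = 4L, vat_radius_range = c(1.5, 3),
               seed = seed, subject = subject)
}

tiny_dataset <- function(n, seed = 1) {
  lapply(seq_len(n), function(i)
    generate_phantom(tiny_phantom_spec(seed = seed + 37L * i,
                                       subject = sprintf("tiny_%02d", i),
                                       column_top = 68L + ((seed + 5L * i) %% 10L))))
}

# A projection record with identity geometry (1 mm pixels, no resize), for
# heatmap tests that need the pixel <-> mm mapping to be trivial.
identity_record <- function(shape = c(128L, 256L)) {
  structure(list(channels = array(0, c(shape, 3L)),
                 transform = list(scale = c(1, 1), spacing = c(1, 1),
                                  input_dim = shape, shape = shape),
                 subject = "synthetic"),
            class = "projection_record")
}

# A featureless volume matching an identity record's SI extent.
flat_volume <- function(n_slices = 256L) {
  ct_volume(array(0, c(4, 4, n_slices)), c(1, 1, 1), subject = "synthetic")
}
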