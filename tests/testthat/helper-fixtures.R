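# Small fixtures shared across test files; everything is generated in code.

tiny_geometry <- function(n_conditions, d = 3, seed = 99) {
  oscirsa:::with_seed(seed, matrix(stats::rnorm(n_conditions * d), n_conditions))
}

# One planted component in a small noiseless recording plus a matching grid
# whose third frequency is exactly the component frequency (10, 14.14, 20,
# 28.28, 40 Hz).
tiny_planted <- function(coding, n_conditions = 8, n_sensors = 6,
                         n_trials = 1, noise_scale = 0, seed = 7,
                         gain = 6, phase_gain = 1.2) {
  cmp <- planted_component(20, c(-0.4, 0.9), coding,
                           geometry = tiny_geometry(n_conditions),
                           amplitude_gain = gain, phase_gain = phase_gain)
  spec <- generator_spec(n_conditions = n_conditions, n_sensors = n_sensors,
                         n_trials = n_trials, sfreq = 250,
                         epoch_window = c(-0.5, 1), components = list(cmp),
                         noise_scale = noise_scale, seed = seed)
  list(epochs = simulate_meg_epochs(spec),
       grid = build_tf_grid(10, 40, 5, 0, 0.4, 0.1),
       f_index = 3L, t_index = 3L)
}

# Build a complex_tfr object directly from a coefficient array, bypassing
# the transform, to exercise the pattern extractors in isolation.
fake_tfr <- function(coef, freqs = seq_len(dim(coef)[4]),
                     times = seq_len(dim(coef)[5])) {
  grid <- structure(list(freqs = as.numeric(freqs), times = as.numeric(times),
                         window_cycles = 2, smoothing = 0.4),
                    class = "tf_grid")
  structure(list(coefficients = coef,
                 valid = matrix(TRUE, dim(coef)[4], dim(coef)[5]),
                 grid = grid,
                 conditions = sprintf("cond%03d", seq_len(dim(coef)[1])),
                 sfreq = 1000),
            class = "complex_tfr")
}

expect_valid_rdm <- function(r) {
  expect_s3_class(r, "rdm")
  expect_silent(validate_rdm(r))
}
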