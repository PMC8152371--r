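test_that("simulation is bit-identical given the same spec and seed", {
  spec <- generator_spec(n_conditions = 5, n_sensors = 4, n_trials = 2,
                         sfreq = 100, epoch_window = c(-0.2, 0.4),
                         components = list(planted_component(
                           10, c(0, 0.3), "power",
                           geometry = tiny_geometry(5))),
                         seed = 3)
  a <- simulate_meg_epochs(spec)
  b <- simulate_meg_epochs(spec)
  expect_identical(a$data, b$data)
  expect_identical(a$truth[[1]]$pattern, b$truth[[1]]$pattern)
})

test_that("default spec matches the emulated recording layout", {
  spec <- generator_spec()
  expect_equal(spec$n_conditions, 92L)
  expect_equal(spec$n_sensors, 306L)
  expect_equal(spec$n_trials, 20L)
  expect_equal(spec$sfreq, 500)
  expect_equal(spec$epoch_window, c(-0.6, 1.2))
  # instantiate with a single trial to keep memory modest; the per-epoch
  # sample count is what the layout fixes: 1.8 s at 500 Hz = 900 samples
  spec1 <- generator_spec(n_trials = 1, seed = 1)
  ep <- simulate_meg_epochs(spec1)
  expect_equal(dim(ep$data), c(92L, 1L, 306L, 900L))
  expect_equal(length(ep$conditions), 92L)
})

test_that("invalid specs are rejected with explicit messages", {
  g <- tiny_geometry(5)
  expect_error(generator_spec(n_conditions = 2), ">= 3")
  expect_error(generator_spec(n_trials = 0), ">= 1")
  expect_error(generator_spec(epoch_window = c(1, 0)), "t0 < t1")
  expect_error(
    generator_spec(n_conditions = 5, n_sensors = 6, sfreq = 100,
                   components = list(planted_component(60, c(0, 0.5), "power",
                                                       geometry = g))),
    "Nyquist")
  expect_error(
    generator_spec(n_conditions = 5, n_sensors = 6,
                   components = list(planted_component(10, c(-2, 0.5), "power",
                                                       geometry = g))),
    "outside the epoch")
  expect_error(planted_component(10, c(0, 0.5), "phase", geometry = g,
                                 phase_gain = 4), "pi")
})

test_that("noise-only epochs give power RDMs with off-diagonal mean near 1", {
  spec <- generator_spec(n_conditions = 10, n_sensors = 8, n_trials = 4,
                         sfreq = 250, epoch_window = c(-0.5, 1),
                         components = list(), seed = 11)
  ep <- simulate_meg_epochs(spec)
  tfr <- multitaper_tfr(ep, build_tf_grid(10, 40, 3, 0, 0.4, 0.2))
  pw <- condition_power_patterns(tfr)
  offdiag <- unlist(lapply(1:3, function(fi)
    vectorize_rdm(compute_rdm(pw$values[, , fi, 2]))))
  expect_gt(mean(offdiag), 0.8)
  expect_lt(mean(offdiag), 1.2)
})

test_that("a noiseless power-coded component is recovered exactly from dB power patterns", {
  fx <- tiny_planted("power")
  tfr <- multitaper_tfr(fx$epochs, fx$grid)
  pw <- condition_power_patterns(tfr)
  meas <- compute_rdm(pw$values[, , fx$f_index, fx$t_index],
                      labels = fx$epochs$conditions)
  truth <- fx$epochs$truth[[1]]$rdm
  expect_lt(max(abs(meas$matrix - truth$matrix)), 1e-6)
  # and the planted RDM equals the RDM of the latent geometry: the sensor
  # embedding preserves pairwise Pearson structure
  geom_rdm <- compute_rdm(tiny_geometry(8), labels = fx$epochs$conditions)
  expect_lt(max(abs(truth$matrix - geom_rdm$matrix)), 1e-9)
})

test_that("a noiseless phase-coded component is recovered from phase patterns up to spectral leakage", {
  fx <- tiny_planted("phase")
  tfr <- multitaper_tfr(fx$epochs, fx$grid)
  ph <- condition_phase_patterns(tfr)
  meas <- compute_rdm(ph$values[, , fx$f_index, fx$t_index],
                      labels = fx$epochs$conditions)
  truth <- fx$epochs$truth[[1]]$rdm
  # agreement is bounded by negative-frequency leakage of the real-valued
  # carrier (~1e-2 in phase), not by numerical precision
  expect_lt(max(abs(meas$matrix - truth$matrix)), 0.05)
  expect_gt(rdm_correlation(meas, truth), 0.999)
})

test_that("power coding leaks nothing into phase patterns and vice versa", {
  fx_pow <- tiny_planted("power", n_trials = 12, noise_scale = 0.3, seed = 21)
  tfr <- multitaper_tfr(fx_pow$epochs, fx_pow$grid)
  truth <- fx_pow$epochs$truth[[1]]$rdm
  r_pow <- rdm_correlation(compute_rdm(
    condition_power_patterns(tfr)$values[, , 3, 3]), truth)
  r_pha <- rdm_correlation(compute_rdm(
    condition_phase_patterns(tfr)$values[, , 3, 3]), truth)
  expect_gt(r_pow, 0.8)
  expect_lt(abs(r_pha), 0.35)

  fx_ph <- tiny_planted("phase", n_trials = 12, noise_scale = 0.3, seed = 22)
  tfr2 <- multitaper_tfr(fx_ph$epochs, fx_ph$grid)
  truth2 <- fx_ph$epochs$truth[[1]]$rdm
  r_pha2 <- rdm_correlation(compute_rdm(
    condition_phase_patterns(tfr2)$values[, , 3, 3]), truth2)
  r_pow2 <- rdm_correlation(compute_rdm(
    condition_power_patterns(tfr2)$values[, , 3, 3]), truth2)
  expect_gt(r_pha2, 0.8)
  expect_lt(abs(r_pow2), 0.35)
})

test_that("reference RDM pairs are valid and hit the target coupling", {
  pair <- simulate_reference_rdms(20, 0.3, seed = 5)
  expect_silent(validate_rdm(pair$rdm_low))
  expect_silent(validate_rdm(pair$rdm_high))
  expect_equal(pair$achieved_correlation,
               rdm_correlation(pair$rdm_low, pair$rdm_high))
  # identical latents: perfect coupling
  one <- simulate_reference_rdms(12, 1 - 1e-12, seed = 2)
  expect_gt(one$achieved_correlation, 0.999999)
  # Monte Carlo over seeds at the emulated scale
  r <- vapply(1:50, function(s)
    simulate_reference_rdms(92, 0.3, seed = s)$achieved_correlation, 0)
  expect_lt(abs(mean(r) - 0.3), 0.05)
})

test_that("layered feature sets morph monotonically from low to high geometry", {
  gl <- tiny_geometry(20, d = 6, seed = 1)
  gh <- tiny_geometry(20, d = 6, seed = 2)
  fs <- center_features(simulate_layered_features(gl, gh, n_layers = 6,
                                                  seed = 3))
  rdm_l <- compute_rdm(gl); rdm_h <- compute_rdm(gh)
  r_low <- vapply(fs$layers, function(f)
    rdm_correlation(vectorize_rdm(compute_rdm(f)), vectorize_rdm(rdm_l)), 0)
  r_high <- vapply(fs$layers, function(f)
    rdm_correlation(vectorize_rdm(compute_rdm(f)), vectorize_rdm(rdm_h)), 0)
  expect_gt(r_low[1], r_high[1])          # first layer is low-like
  expect_gt(r_high[6], r_low[6])          # last layer is high-like
  expect_true(all(diff(r_high) > -0.02))  # monotone morph (small noise slack)
  expect_true(all(diff(r_low) < 0.02))
})

test_that("zero mean offset makes centering a no-op for layer RDMs", {
  gl <- tiny_geometry(16, d = 5, seed = 4)
  gh <- tiny_geometry(16, d = 5, seed = 5)
  fs <- simulate_layered_features(gl, gh, n_layers = 4, mean_offset_scale = 0,
                                  seed = 6)
  cen <- center_features(fs)
  for (l in 1:4) {
    r_raw <- vectorize_rdm(compute_rdm(fs$layers[[l]]))
    r_cen <- vectorize_rdm(compute_rdm(cen$layers[[l]]))
    expect_lt(1 - stats::cor(r_raw, r_cen), 0.02)
  }
  expect_error(simulate_layered_features(gl, gh, n_layers = 1), ">= 2")
})
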