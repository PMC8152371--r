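test_that("the default grid reproduces the stated layout", {
  g <- build_tf_grid()
  expect_length(g$freqs, 50)
  expect_equal(g$freqs[1], 3)
  expect_equal(g$freqs[50], 100)
  expect_true(all(diff(g$freqs) > 0))
  expect_length(g$times, 66)
  expect_equal(g$times[1], -0.6)
  expect_equal(g$times[66], 0.7)
})

test_that("grid construction handles degenerate and non-commensurate inputs", {
  g1 <- build_tf_grid(n_freqs = 1, fmin = 7, fmax = 50)
  expect_equal(g1$freqs, 7)
  # non-commensurate tmax: last point at or before tmax, never beyond
  g2 <- build_tf_grid(tmin = 0, tmax = 0.55, tstep = 0.2)
  expect_equal(g2$times, c(0, 0.2, 0.4))
  expect_error(build_tf_grid(fmin = -1), "fmin")
})

test_that("the stated window parameters imply a single taper", {
  # 2 * (2 / f) * (0.4 f) - 1 = 0.6 < 1 at every frequency
  expect_equal(taper_count(2, 0.4), 1L)
  expect_equal(taper_count(8, 0.4), 5L)   # longer windows admit more tapers
  h <- dpss_tapers(101, 0.8, 1)
  expect_equal(sum(h^2), 1, tolerance = 1e-12)
  expect_gt(sum(h), 0)
})

test_that("a pure sinusoid at a grid frequency yields its phase and a power peak", {
  phi <- 0.9
  sfreq <- 250
  times <- -0.5 + (0:374) / sfreq
  data <- array(0, c(3, 1, 1, 375))
  for (cc in 1:3) data[cc, 1, 1, ] <- cos(2 * pi * 20 * times + phi)
  ep <- structure(list(data = data, times = times, sfreq = sfreq,
                       epoch_window = c(-0.5, 1),
                       conditions = sprintf("cond%03d", 1:3),
                       truth = list(), spec = NULL), class = "epoch_set")
  grid <- build_tf_grid(10, 40, 5, 0, 0.4, 0.1)
  tfr <- multitaper_tfr(ep, grid)
  co <- tfr$coefficients[1, 1, 1, , 3]
  expect_lt(abs(Arg(co[3]) - phi), 0.05)
  expect_equal(which.max(Mod(co)), 3L)
  expect_equal(Mod(co[3]), 1, tolerance = 0.05)  # amplitude-calibrated scale
})

test_that("all-zero epochs give zero-magnitude coefficients and out-of-epoch windows are masked", {
  times <- -0.2 + (0:99) / 250
  ep <- structure(list(data = array(0, c(3, 1, 2, 100)), times = times,
                       sfreq = 250, epoch_window = c(-0.2, 0.2),
                       conditions = sprintf("cond%03d", 1:3),
                       truth = list(), spec = NULL), class = "epoch_set")
  grid <- build_tf_grid(20, 60, 3, -0.2, 0.18, 0.06)
  tfr <- multitaper_tfr(ep, grid)
  vi <- which(tfr$valid, arr.ind = TRUE)
  mx <- max(vapply(seq_len(nrow(vi)), function(r)
    max(Mod(tfr$coefficients[, , , vi[r, 1], vi[r, 2]])), 0))
  expect_equal(mx, 0)
  # 20 Hz needs a 100 ms half-window: the earliest/latest centers are masked
  expect_false(tfr$valid[1, 1])
  expect_true(any(tfr$valid[1, ]))
  expect_true(all(is.na(tfr$coefficients[, , , 1, 1])))
  expect_error(multitaper_tfr(ep, build_tf_grid(20, 200, 3, 0, 0.1, 0.05)),
               "Nyquist")
})

test_that("power patterns convert to decibels before averaging across trials", {
  p1 <- 4; p2 <- 9
  coef <- array(complex(modulus = sqrt(c(p1, p2)), argument = 0), c(1, 2, 1, 1, 1))
  coef <- array(rep(coef, 3), c(3, 2, 1, 1, 1))  # 3 conditions, 2 trials
  pw <- condition_power_patterns(fake_tfr(coef))
  expect_equal(pw$values[1, 1, 1, 1], (10 * log10(p1) + 10 * log10(p2)) / 2,
               tolerance = 1e-12)
  # NOT the dB of the mean power
  expect_false(isTRUE(all.equal(pw$values[1, 1, 1, 1],
                                10 * log10((p1 + p2) / 2))))
  # unit power everywhere -> 0 dB patterns
  unit <- fake_tfr(array(1 + 0i, c(3, 1, 2, 1, 1)))
  expect_equal(max(abs(condition_power_patterns(unit)$values)), 0,
               tolerance = 1e-9)
})

test_that("phase patterns are unit resultants with 2S features", {
  # 306 sensors -> 612-dimensional phase vectors
  coef <- array(exp(1i * stats::runif(4 * 306, -pi, pi)), c(4, 1, 306, 1, 1))
  ph <- condition_phase_patterns(fake_tfr(coef))
  expect_equal(dim(ph$values)[2], 612L)
  # each (cos, sin) sensor sub-pair has unit norm
  norms <- sqrt(ph$values[, 1:306, 1, 1]^2 + ph$values[, 307:612, 1, 1]^2)
  expect_equal(max(abs(norms - 1)), 0, tolerance = 1e-9)

  # trials at +theta and -theta: resultant direction is (1, 0)
  theta <- 1.1
  two <- array(c(exp(1i * theta), exp(-1i * theta)), c(1, 2, 1, 1, 1))
  two <- array(rep(two, each = 3), c(3, 2, 1, 1, 1))
  v <- condition_phase_patterns(fake_tfr(two))$values
  expect_equal(v[1, 1, 1, 1], 1, tolerance = 1e-12)
  expect_equal(v[1, 2, 1, 1], 0, tolerance = 1e-12)

  # a single trial: the trial's own unit vector
  one <- fake_tfr(array(3 * exp(1i * 0.4), c(3, 1, 1, 1, 1)))
  v1 <- condition_phase_patterns(one)$values
  expect_equal(v1[1, 1, 1, 1], cos(0.4), tolerance = 1e-12)
  expect_equal(v1[1, 2, 1, 1], sin(0.4), tolerance = 1e-12)
})

test_that("zero-coefficient trials are excluded and all-zero coordinates masked", {
  coef <- array(exp(1i * 0.7), c(3, 2, 1, 1, 1))
  coef[, 2, , , ] <- 0          # second trial silent: excluded, not NaN
  v <- condition_phase_patterns(fake_tfr(coef))$values
  expect_equal(v[1, 1, 1, 1], cos(0.7), tolerance = 1e-12)
  allzero <- fake_tfr(array(0i, c(3, 2, 1, 1, 1)))
  expect_warning(ph <- condition_phase_patterns(allzero), "degenerate")
  expect_false(any(ph$valid))
})

test_that("phase patterns ignore per-trial amplitude scaling", {
  oscirsa:::with_seed(8, {
    base <- array(complex(modulus = stats::runif(3 * 4 * 2, 0.5, 2),
                          argument = stats::runif(3 * 4 * 2, -pi, pi)),
                  c(3, 4, 2, 1, 1))
    gains <- stats::runif(4, 0.1, 10)
  })
  scaled <- base
  for (r in 1:4) scaled[, r, , , ] <- base[, r, , , ] * gains[r]
  v0 <- condition_phase_patterns(fake_tfr(base))$values
  v1 <- condition_phase_patterns(fake_tfr(scaled))$values
  expect_lt(max(abs(v0 - v1)), 1e-12)
})

test_that("global gain shifts dB patterns additively and leaves RDMs unchanged", {
  fx <- tiny_planted("power", n_trials = 3, noise_scale = 0.5, seed = 31)
  tfr <- multitaper_tfr(fx$epochs, fx$grid)
  scaled <- fx$epochs
  scaled$data <- scaled$data * 7
  tfr2 <- multitaper_tfr(scaled, fx$grid)
  p1 <- condition_power_patterns(tfr)$values[, , 3, 3]
  p2 <- condition_power_patterns(tfr2)$values[, , 3, 3]
  expect_equal(max(abs((p2 - p1) - 20 * log10(7))), 0, tolerance = 1e-9)
  expect_lt(max(abs(compute_rdm(p1)$matrix - compute_rdm(p2)$matrix)), 1e-9)
})
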