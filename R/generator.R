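#' Specify a planted oscillatory component
#'
#' A planted component is a condition-coded sinusoid added to every trial of
#' a synthetic recording.  Its condition structure is taken from a latent
#' `geometry` matrix (conditions x d): the latent rows are embedded into
#' sensor space through a correlation-preserving projection, so the pairwise
#' Pearson structure of the geometry is exactly the pairwise structure of
#' the planted sensor pattern.
#'
#' Two coding schemes are available:
#' \describe{
#'   \item{`"power"`}{the per-sensor oscillation amplitude is condition
#'     dependent (log-linear in the projected geometry, so decibel power
#'     patterns are affine in it), while the oscillation phase is drawn
#'     uniformly at random per trial (shared across sensors, as for a
#'     coherent source).  Phase patterns therefore carry no condition
#'     information.}
#'   \item{`"phase"`}{the per-sensor phase offset is condition dependent and
#'     the amplitude is fixed, so power patterns carry no condition
#'     information.  `phase_gain` is the largest absolute phase offset in
#'     radians and must not exceed pi.}
#' }
#'
#' @param freq Oscillation frequency in Hz.
#' @param time_window Length-2 numeric, on/off times in seconds.
#' @param coding `"power"`, `"phase"`, or `"none"` (a condition-blind
#'   oscillation).
#' @param geometry Conditions x d latent matrix (d >= 2); its row-wise
#'   Pearson structure defines the planted representational geometry.
#'   Ignored for `coding = "none"`.
#' @param topography Per-sensor positive gain vector (recycled); defaults to
#'   uniform gain.  Non-uniform gains multiply the oscillation amplitude
#'   sensor-wise.
#' @param amplitude_base Baseline oscillation amplitude (signal units).
#' @param amplitude_gain Power coding: standard deviation, in dB, of the
#'   planted decibel-amplitude pattern across sensors.
#' @param phase_gain Phase coding: maximum absolute condition phase offset in
#'   radians (must be <= pi).
#' @return An object of class `planted_component`.
#' @seealso [generator_spec()], [simulate_meg_epochs()]
#' @export
planted_component <- function(freq, time_window, coding = c("power", "phase", "none"),
                              geometry = NULL, topography = NULL,
                              amplitude_base = 1, amplitude_gain = 6,
                              phase_gain = 1.2) {
  coding <- match.arg(coding)
  if (!is.numeric(freq) || length(freq) != 1L || freq <= 0)
    stopf("`freq` must be a single positive number")
  if (length(time_window) != 2L || time_window[1] >= time_window[2])
    stopf("`time_window` must be [on, off] with on < off")
  if (coding != "none") {
    if (is.null(geometry)) stopf("`geometry` is required for coding '%s'", coding)
    geometry <- as.matrix(geometry)
    if (nrow(geometry) < 3L || ncol(geometry) < 2L)
      stopf("`geometry` must be at least 3 conditions x 2 latent dimensions")
  }
  if (coding == "phase" && (phase_gain <= 0 || phase_gain > pi))
    stopf("`phase_gain` must be in (0, pi] radians so planted phases stay in (-pi, pi]")
  if (amplitude_base <= 0) stopf("`amplitude_base` must be positive")
  structure(list(freq = freq, time_window = as.numeric(time_window),
                 coding = coding, geometry = geometry, topography = topography,
                 amplitude_base = amplitude_base, amplitude_gain = amplitude_gain,
                 phase_gain = phase_gain),
            class = "planted_component")
}

#' Specify a synthetic epoched recording
#'
#' Defaults emulate the study conditions the pipeline is designed for: 92
#' stimulus conditions, 306 sensors, epochs from 600 ms before to 1200 ms
#' after stimulus onset sampled at 500 Hz, and 20 trials per condition.
#' The background is 1/f noise generated in the spectral domain.
#'
#' @param n_conditions Number of stimulus conditions (>= 3).
#' @param n_sensors Number of sensors.
#' @param n_trials Trials per condition (>= 1).
#' @param sfreq Sampling rate in Hz.
#' @param epoch_window Length-2 numeric `[t0, t1]` in seconds; samples cover
#'   `[t0, t1)` on a `1/sfreq` grid.
#' @param components List of [planted_component()] objects (may be empty for
#'   pure noise).
#' @param noise_exponent Spectral slope of the background: power ~ 1/f^a.
#' @param noise_scale Noise standard deviation in signal units (0 disables
#'   noise).
#' @param seed Integer seed; identical specs give bit-identical data.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_conditions = 92, n_sensors = 306, n_trials = 20,
                           sfreq = 500, epoch_window = c(-0.6, 1.2),
                           components = list(), noise_exponent = 1,
                           noise_scale = 1, seed = 1) {
  if (n_conditions < 3) stopf("`n_conditions` must be >= 3")
  if (n_trials < 1) stopf("`n_trials` must be >= 1")
  if (length(epoch_window) != 2L || epoch_window[1] >= epoch_window[2])
    stopf("`epoch_window` must be [t0, t1] with t0 < t1")
  if (inherits(components, "planted_component")) components <- list(components)
  for (cmp in components) {
    if (!inherits(cmp, "planted_component"))
      stopf("`components` must be a list of planted_component objects")
    if (cmp$freq >= sfreq / 2)
      stopf("component frequency %.3g Hz is at or above the Nyquist frequency %.3g Hz",
            cmp$freq, sfreq / 2)
    if (cmp$time_window[1] < epoch_window[1] || cmp$time_window[2] > epoch_window[2])
      stopf("component time window [%.3g, %.3g] falls outside the epoch window",
            cmp$time_window[1], cmp$time_window[2])
    if (cmp$coding != "none") {
      if (nrow(cmp$geometry) != n_conditions)
        stopf("component geometry has %d rows but the spec has %d conditions",
              nrow(cmp$geometry), n_conditions)
      if (ncol(cmp$geometry) > n_sensors - 1L)
        stopf("component geometry dimension %d needs at least %d sensors",
              ncol(cmp$geometry), ncol(cmp$geometry) + 1L)
    }
  }
  structure(list(n_conditions = as.integer(n_conditions),
                 n_sensors = as.integer(n_sensors),
                 n_trials = as.integer(n_trials), sfreq = sfreq,
                 epoch_window = as.numeric(epoch_window),
                 components = components, noise_exponent = noise_exponent,
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "generator_spec")
}

# 1/f^a background noise, synthesized in the spectral domain with random
# phases and unit time-domain standard deviation, as `n` columns of length
# `n_samples`.
pink_noise <- function(n_samples, n, exponent) {
  nf <- n_samples %/% 2L
  f <- seq_len(nf)
  amp <- f^(-exponent / 2)
  ph <- matrix(stats::runif(nf * n, 0, 2 * pi), nf, n)
  spec <- matrix(0i, n_samples, n)
  spec[2:(nf + 1L), ] <- amp * exp(1i * ph)
  if (n_samples %% 2L == 0L) spec[nf + 1L, ] <- Re(spec[nf + 1L, ])
  idx <- seq(n_samples, n_samples - nf + 1L + (n_samples %% 2L == 0L))
  spec[idx, ] <- Conj(spec[2:(nf + !(n_samples %% 2L == 0L)), , drop = FALSE])
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / n_samples
  x <- sweep(x, 2L, apply(x, 2L, stats::sd), "/")
  x
}

# Realize a component's condition/sensor structure under the current RNG
# state.  Returns the deterministic ground truth a recovery test needs.
realize_component <- function(cmp, n_conditions, n_sensors) {
  topo <- if (is.null(cmp$topography)) rep(1, n_sensors)
          else rep_len(cmp$topography, n_sensors)
  if (all(topo == 0)) stopf("component topography must not be all zero")
  out <- list(freq = cmp$freq, time_window = cmp$time_window, coding = cmp$coding,
              topography = topo, amplitude_base = cmp$amplitude_base)
  if (cmp$coding == "none") return(out)
  x <- geometry_to_pattern(cmp$geometry, n_sensors)  # rows: mean 0, sd 1
  if (cmp$coding == "power") {
    # log-linear amplitudes: the dB pattern is affine in the projected
    # geometry, so the measured dB-power RDM equals the planted RDM exactly
    db <- cmp$amplitude_gain * x
    amp <- cmp$amplitude_base * 10^(db / 20)
    amp <- sweep(amp, 2L, topo, "*")
    out$amplitude <- amp
    out$pattern <- 20 * log10(amp)                  # dB-scale planted pattern
    out$rdm <- compute_rdm(out$pattern,
                           labels = default_condition_labels(n_conditions))
  } else {
    ph <- cmp$phase_gain * x / max(abs(x))
    out$phase <- ph
    out$pattern <- cbind(cos(ph), sin(ph))          # [Re | Im] feature layout
    out$rdm <- compute_rdm(out$pattern,
                           labels = default_condition_labels(n_conditions))
  }
  out
}

default_condition_labels <- function(n) sprintf("cond%03d", seq_len(n))

#' Simulate an epoched multichannel recording
#'
#' Each trial is the sum of the planted components plus 1/f background
#' noise.  The realized per-component ground truth (sensor patterns and the
#' planted RDM) is stored in the returned object under `$truth` so that
#' downstream recovery can be tested against it.
#'
#' @param spec A [generator_spec()].
#' @return An object of class `epoch_set` with elements `data` (array
#'   conditions x trials x sensors x samples), `times`, `sfreq`,
#'   `epoch_window`, `conditions`, `truth`, and `spec`.
#' @export
simulate_meg_epochs <- function(spec) {
  if (!inherits(spec, "generator_spec")) stopf("`spec` must be a generator_spec")
  C <- spec$n_conditions; R <- spec$n_trials; S <- spec$n_sensors
  n_samp <- round((spec$epoch_window[2] - spec$epoch_window[1]) * spec$sfreq)
  times <- spec$epoch_window[1] + (seq_len(n_samp) - 1L) / spec$sfreq
  with_seed(spec$seed, {
    truth <- lapply(spec$components, realize_component, n_conditions = C,
                    n_sensors = S)
    data <- array(0, dim = c(C, R, S, n_samp))
    if (spec$noise_scale > 0) {
      nz <- pink_noise(n_samp, C * R * S, spec$noise_exponent) * spec$noise_scale
      data <- array(t(nz), dim = c(C, R, S, n_samp))
    }
    for (tr in truth) {
      on <- times >= tr$time_window[1] & times < tr$time_window[2]
      carrier <- 2 * pi * tr$freq * times
      if (tr$coding == "power") {
        phi <- matrix(stats::runif(C * R, -pi, pi), C, R)  # per condition x trial,
        for (r in seq_len(R)) {                            # shared across sensors
          osc <- cos(outer(phi[, r], carrier, "+")) * rep(on, each = C)
          for (s in seq_len(S))
            data[, r, s, ] <- data[, r, s, ] + tr$amplitude[, s] * osc
        }
      } else if (tr$coding == "phase") {
        for (s in seq_len(S)) {
          osc <- cos(outer(tr$phase[, s], carrier, "+")) * rep(on, each = C)
          contrib <- tr$amplitude_base * tr$topography[s] * osc  # C x n_samp
          for (r in seq_len(R)) data[, r, s, ] <- data[, r, s, ] + contrib
        }
      } else {
        osc <- cos(carrier) * on
        for (s in seq_len(S)) {
          contrib <- matrix(tr$amplitude_base * tr$topography[s] * osc,
                            C, n_samp, byrow = TRUE)
          for (r in seq_len(R)) data[, r, s, ] <- data[, r, s, ] + contrib
        }
      }
    }
    structure(list(data = data, times = times, sfreq = spec$sfreq,
                   epoch_window = spec$epoch_window,
                   conditions = default_condition_labels(C),
                   truth = truth, spec = spec),
              class = "epoch_set")
  })
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d conditions x %d trials x %d sensors x %d samples\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  sfreq %g Hz, epoch [%g, %g) s, %d planted component(s)\n",
              x$sfreq, x$epoch_window[1], x$epoch_window[2], length(x$truth)))
  invisible(x)
}

#' Simulate a multi-subject study
#'
#' Repeated draws from one [generator_spec()] with subject-specific seeds.
#' All subjects share the planted component geometries up to per-subject
#' Gaussian jitter of the latent entries (standard deviation
#' `geometry_jitter_sd` relative to the latent scale), which creates the
#' between-subject variability that paired group statistics require.
#'
#' @param spec A [generator_spec()]; its `seed` seeds the whole study.
#' @param n_subjects Number of subjects (>= 2 for group statistics).
#' @param geometry_jitter_sd Relative SD of the per-subject latent jitter.
#' @return List of `epoch_set` objects, one per subject.
#' @export
simulate_study <- function(spec, n_subjects, geometry_jitter_sd = 0.2) {
  if (n_subjects < 1) stopf("`n_subjects` must be >= 1")
  lapply(seq_len(n_subjects), function(s) {
    sspec <- spec
    sspec$seed <- derive_seed(spec$seed, s)
    if (geometry_jitter_sd > 0 && length(spec$components)) {
      sspec$components <- with_seed(derive_seed(spec$seed, 100000L + s), {
        lapply(spec$components, function(cmp) {
          if (cmp$coding == "none") return(cmp)
          sc <- stats::sd(cmp$geometry)
          cmp$geometry <- cmp$geometry +
            matrix(stats::rnorm(length(cmp$geometry), sd = geometry_jitter_sd * sc),
                   nrow(cmp$geometry))
          cmp
        })
      })
    }
    simulate_meg_epochs(sspec)
  })
}

#' Simulate a coupled pair of reference RDMs
#'
#' Draws two latent pattern matrices sharing a common component and forms
#' their 1 - Pearson RDMs.  With mixing weight `w` on the shared component,
#' the expected Pearson correlation between the two vectorized RDMs is
#' `w^2`, so the weight is set to `sqrt(target_correlation)`.  The achieved
#' correlation of each draw is recorded; its seed-to-seed spread is of order
#' `1/sqrt(n_latent)` and the mean over seeds matches the target.
#'
#' @param n_conditions Number of conditions (>= 3).
#' @param target_correlation Desired Pearson r between the vectorized RDMs,
#'   in (-1, 1).
#' @param n_latent Latent dimensionality of the underlying patterns.
#' @param seed Integer seed.
#' @return An object of class `ref_rdm_pair`: `rdm_low`, `rdm_high`,
#'   `achieved_correlation`, `target_correlation`, and the latent matrices
#'   `latent_low`, `latent_high` (useful for planting components with a
#'   matching geometry).
#' @export
simulate_reference_rdms <- function(n_conditions = 92, target_correlation = 0.3,
                                    n_latent = 20, seed = 1) {
  if (n_conditions < 3) stopf("`n_conditions` must be >= 3")
  if (abs(target_correlation) >= 1) stopf("`target_correlation` must be in (-1, 1)")
  with_seed(seed, {
    a <- matrix(stats::rnorm(n_conditions * n_latent), n_conditions)
    b <- matrix(stats::rnorm(n_conditions * n_latent), n_conditions)
    w <- sqrt(abs(target_correlation))
    hi <- sign(target_correlation) * w * a + sqrt(1 - w^2) * b
    labels <- default_condition_labels(n_conditions)
    rdm_low <- compute_rdm(a, labels = labels)
    rdm_high <- compute_rdm(hi, labels = labels)
    achieved <- rdm_correlation(rdm_low, rdm_high)
    if (identical(target_correlation, 1)) achieved <- 1
    if (abs(achieved - target_correlation) > 0.2)
      warnf("achieved reference-RDM correlation %.3f is far from target %.3f (small n_conditions?)",
            achieved, target_correlation)
    structure(list(rdm_low = rdm_low, rdm_high = rdm_high,
                   achieved_correlation = achieved,
                   target_correlation = target_correlation,
                   latent_low = a, latent_high = hi),
              class = "ref_rdm_pair")
  })
}

#' @export
print.ref_rdm_pair <- function(x, ...) {
  cat(sprintf("<ref_rdm_pair> %d conditions, target r = %.3f, achieved r = %.3f\n",
              nrow(unclass(x$rdm_low)$matrix), x$target_correlation,
              x$achieved_correlation))
  invisible(x)
}

#' Simulate a layered feature hierarchy
#'
#' Layer features are built so that, after centering, the layer RDM
#' interpolates linearly (and hence monotonically in RDM correlation) from
#' the RDM of `low_geometry` at layer 1 to the RDM of `high_geometry` at the
#' last layer.  Every layer carries a common additive mean offset of
#' per-feature magnitude `mean_offset_scale` times the feature SD, emulating
#' feature spaces in which the analysis images sit far from the origin, so
#' that centering on an independent image set matters.  The centering set is
#' drawn from the same per-layer distribution (same mean offset) over fresh
#' latent images.
#'
#' @param low_geometry,high_geometry Images x d latent matrices over the same
#'   images.
#' @param n_layers Number of layers (>= 2).
#' @param n_features Feature dimensionality per layer.
#' @param mean_offset_scale Offset magnitude in units of the feature SD.
#' @param noise_sd Per-entry feature noise, relative to the feature SD.
#' @param n_centering Number of centering images (defaults to 4 per analysis
#'   image, mirroring a 368-image centering set for 92 images).
#' @param seed Integer seed.
#' @return An object of class `layered_feature_set` with `layers` and
#'   `centering` (lists of images x features matrices), `n_layers`, `alpha`
#'   (the per-layer interpolation weights), and `centered = FALSE`.
#' @export
simulate_layered_features <- function(low_geometry, high_geometry, n_layers,
                                      n_features = 128, mean_offset_scale = 5,
                                      noise_sd = 0.05,
                                      n_centering = 4 * nrow(low_geometry),
                                      seed = 1) {
  low_geometry <- as.matrix(low_geometry); high_geometry <- as.matrix(high_geometry)
  if (n_layers < 2) stopf("`n_layers` must be >= 2")
  if (nrow(low_geometry) != nrow(high_geometry))
    stopf("low and high geometries must cover the same images")
  if (n_centering < 1) stopf("`n_centering` must be positive")
  n_img <- nrow(low_geometry)
  p_half <- n_features %/% 2L
  with_seed(seed, {
    zl <- row_standardize(low_geometry, "low geometry row")
    zh <- row_standardize(high_geometry, "high geometry row")
    ml <- orthonormal_contrast(ncol(zl), p_half)
    mh <- orthonormal_contrast(ncol(zh), n_features - p_half)
    zcl <- row_standardize(matrix(stats::rnorm(n_centering * ncol(zl)), n_centering))
    zch <- row_standardize(matrix(stats::rnorm(n_centering * ncol(zh)), n_centering))
    alpha <- (seq_len(n_layers) - 1) / (n_layers - 1)
    feat_sd <- 1 / sqrt(n_features)    # scale of the embedded unit-norm rows
    layers <- vector("list", n_layers); centering <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      a <- alpha[l]
      base <- cbind(sqrt(1 - a) * (zl %*% ml), sqrt(a) * (zh %*% mh))
      cent <- cbind(sqrt(1 - a) * (zcl %*% ml), sqrt(a) * (zch %*% mh))
      mu <- stats::rnorm(n_features, sd = mean_offset_scale * feat_sd)
      layers[[l]] <- base +
        matrix(stats::rnorm(length(base), sd = noise_sd * feat_sd), n_img) +
        matrix(mu, n_img, n_features, byrow = TRUE)
      centering[[l]] <- cent +
        matrix(stats::rnorm(length(cent), sd = noise_sd * feat_sd), n_centering) +
        matrix(mu, n_centering, n_features, byrow = TRUE)
    }
    structure(list(layers = layers, centering = centering, n_layers = n_layers,
                   alpha = alpha, centered = FALSE),
              class = "layered_feature_set")
  })
}

#' @export
print.layered_feature_set <- function(x, ...) {
  cat(sprintf("<layered_feature_set> %d layers, %d images x %d features, %d centering images%s\n",
              x$n_layers, nrow(x$layers[[1]]), ncol(x$layers[[1]]),
              nrow(x$centering[[1]]), if (x$centered) " (centered)" else ""))
  invisible(x)
}

#' Simulate a family of feature hierarchies of different depths
#'
#' Convenience wrapper around [simulate_layered_features()] mirroring a
#' seven-network setting with depths 5, 13, 12, 16, 17, 14, and 8 layers.
#'
#' @inheritParams simulate_layered_features
#' @param depths Integer vector of hierarchy depths.
#' @return List of `layered_feature_set` objects.
#' @export
simulate_hierarchies <- function(low_geometry, high_geometry,
                                 depths = c(5, 13, 12, 16, 17, 14, 8),
                                 n_features = 128, mean_offset_scale = 5,
                                 noise_sd = 0.05,
                                 n_centering = 4 * nrow(low_geometry),
                                 seed = 1) {
  lapply(seq_along(depths), function(i)
    simulate_layered_features(low_geometry, high_geometry, depths[i],
                              n_features = n_features,
                              mean_offset_scale = mean_offset_scale,
                              noise_sd = noise_sd, n_centering = n_centering,
                              seed = derive_seed(seed, i)))
}

#' Simulate a stack of RDM vectors with planted geometry families
#'
#' Draws `n_families` independent latent geometries and, for each, `per_family`
#' member RDMs whose latents are jittered copies of the family geometry.
#' Useful for testing clustering and model selection against a known family
#' structure.
#'
#' @param n_families Number of planted families.
#' @param per_family Members per family.
#' @param n_conditions Conditions per RDM.
#' @param n_latent Latent dimensionality.
#' @param noise_sd Relative SD of the member latent jitter (within-family
#'   spread; the expected member-to-family RDM correlation is
#'   `1 / (1 + noise_sd^2)`).
#' @param seed Integer seed.
#' @return List with `vectors` (members x pairs matrix of vectorized RDMs),
#'   `family` (integer labels), and `family_rdms`.
#' @export
simulate_rdm_family_stack <- function(n_families = 7, per_family = 20,
                                      n_conditions = 24, n_latent = 20,
                                      noise_sd = 0.3, seed = 1) {
  with_seed(seed, {
    labels <- default_condition_labels(n_conditions)
    fams <- lapply(seq_len(n_families), function(i)
      matrix(stats::rnorm(n_conditions * n_latent), n_conditions))
    family_rdms <- lapply(fams, compute_rdm, labels = labels)
    vecs <- NULL; fam_id <- integer(0)
    for (i in seq_len(n_families)) {
      for (m in seq_len(per_family)) {
        g <- fams[[i]] + matrix(stats::rnorm(n_conditions * n_latent, sd = noise_sd),
                                n_conditions)
        vecs <- rbind(vecs, vectorize_rdm(compute_rdm(g, labels = labels)))
        fam_id <- c(fam_id, i)
      }
    }
    list(vectors = vecs, family = fam_id, family_rdms = family_rdms)
  })
}
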