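test_that("the level score evaluates the sigmoid of the normalized contrast", {
  expect_equal(level_score(0.3, 0.3), 0.5, tolerance = 1e-12)
  # frozen direct evaluations of the scale
  expect_equal(level_score(0.2, 0.4), 0.5825702065, tolerance = 1e-9)
  expect_equal(level_score(0, 0.4), 0.7310585786, tolerance = 1e-9)
  # antisymmetry: swapping the references reflects the scale
  expect_equal(level_score(0.1, 0.45), 1 - level_score(0.45, 0.1),
               tolerance = 1e-12)
  expect_error(level_score(-0.2, 0.1), "not positive")
  expect_error(level_score(0, 0), "not positive")
})

test_that("the surrogate test is calibrated, reproducible, and monotone", {
  oscirsa:::with_seed(41, {
    target <- stats::runif(45)
    control <- stats::runif(45)
  })
  # perfect match: no entry permutation can beat the observed statistic
  st <- surrogate_test(target, target, control, n_iter = 1000, seed = 1)
  expect_equal(st$p, 1 / 1001, tolerance = 1e-12)
  expect_equal(st$observed, 1, tolerance = 1e-9)
  # reproducibility
  oscirsa:::with_seed(42, x <- stats::runif(45))
  s1 <- surrogate_test(x, target, control, n_iter = 500, seed = 9)
  s2 <- surrogate_test(x, target, control, n_iter = 500, seed = 9)
  expect_identical(s1$p, s2$p)
  # monotonicity: on shared surrogate draws a larger observed statistic
  # cannot receive a larger p
  ps <- vapply(list(x, target), function(v)
    surrogate_test(v, target, control, n_iter = 500, seed = 9)$p, 0)
  obs <- vapply(list(x, target), function(v)
    partial_correlation(v, target, control), 0)
  expect_true(ps[which.max(obs)] <= ps[which.min(obs)])
})

test_that("surrogate p-values are approximately uniform under independence", {
  ps <- vapply(1:200, function(i) {
    oscirsa:::with_seed(1000 + i, {
      x <- stats::rnorm(60); y <- stats::rnorm(60); z <- stats::rnorm(60)
    })
    surrogate_test(x, y, z, n_iter = 400, seed = 2000 + i)$p
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the label-permutation scheme preserves RDM structure", {
  r <- compute_rdm(tiny_geometry(10, d = 4, seed = 3))
  target <- vectorize_rdm(compute_rdm(tiny_geometry(10, d = 4, seed = 4)))
  control <- vectorize_rdm(compute_rdm(tiny_geometry(10, d = 4, seed = 5)))
  st <- surrogate_test(vectorize_rdm(r), target, control, n_iter = 200,
                       seed = 3, scheme = "labels")
  expect_true(st$p >= 1 / 201 && st$p <= 1)
  expect_error(surrogate_test(1:11 / 11, target[1:11], control[1:11],
                              n_iter = 10, seed = 1, scheme = "labels"),
               "vectorized RDM")
})

test_that("feature centering removes the planted offset and only that", {
  gl <- tiny_geometry(15, d = 5, seed = 7)
  gh <- tiny_geometry(15, d = 5, seed = 8)
  fs <- simulate_layered_features(gl, gh, n_layers = 5, mean_offset_scale = 6,
                                  seed = 9)
  cen <- center_features(fs)
  # self-centering gives exactly zero column means
  self <- fs
  self$centering <- fs$layers
  zc <- center_features(self)
  expect_lt(max(abs(colMeans(zc$layers[[3]]))), 1e-12)
  # the common offset compresses raw dissimilarities toward 0 (the images sit
  # in a remote corner, so pairwise correlations are dominated by the offset);
  # centering restores distances on the planted geometry's scale
  v_raw <- vectorize_rdm(compute_rdm(fs$layers[[1]]))
  v_cen <- vectorize_rdm(compute_rdm(cen$layers[[1]]))
  expect_lt(mean(v_raw), 0.5 * mean(v_cen))
  expect_gt(rdm_correlation(v_cen, vectorize_rdm(compute_rdm(gl))), 0.99)
  bad <- fs
  bad$centering[[2]] <- bad$centering[[2]][, 1:3]
  expect_error(center_features(bad), "layer 2")
})

test_that("centroid-origin distance measures the offset in SD units", {
  oscirsa:::with_seed(10, f0 <- matrix(stats::rnorm(30 * 8), 30))
  f0 <- sweep(f0, 2, colMeans(f0))           # exactly centered cloud
  expect_equal(centroid_origin_distance(list(f0)), 0, tolerance = 1e-12)
  mu <- rep(2, 8)
  f1 <- sweep(f0, 2, mu, "+")
  d1 <- centroid_origin_distance(list(f1))
  f2 <- sweep(f0, 2, 3 * mu, "+")            # scaling the offset scales the
  d2 <- centroid_origin_distance(list(f2))   # distance linearly
  expect_equal(d2 / d1, 3, tolerance = 1e-9)
  # centering a planted-offset hierarchy collapses the curve toward 0
  gl <- tiny_geometry(15, d = 5, seed = 11); gh <- tiny_geometry(15, d = 5, seed = 12)
  fs <- simulate_layered_features(gl, gh, n_layers = 4, mean_offset_scale = 6,
                                  seed = 13)
  before <- centroid_origin_distance(fs)
  after <- centroid_origin_distance(center_features(fs))
  # centering removes the planted offset; what remains is the O(sqrt(p/n))
  # sampling distance of the image centroid itself
  expect_lt(max(after), min(before) / 3)
  expect_error(centroid_origin_distance(list(matrix(1, 5, 3))), "zero feature variance")
})

test_that("hierarchy complexity normalizes the best-matching layer to [0, 1]", {
  gl <- tiny_geometry(18, d = 5, seed = 14)
  gh <- tiny_geometry(18, d = 5, seed = 15)
  fs <- center_features(simulate_layered_features(gl, gh, n_layers = 6,
                                                  noise_sd = 0.02, seed = 16))
  # centroid equal to the (centered) first-layer RDM: position 0
  cen1 <- vectorize_rdm(compute_rdm(fs$layers[[1]]))
  h1 <- hierarchy_complexity(cen1, list(fs))
  expect_equal(h1$per_hierarchy$argmax_layer, 1L)
  expect_equal(h1$mean_position, 0)
  # centroid equal to the high geometry RDM: position 1
  cenH <- vectorize_rdm(compute_rdm(gh))
  hH <- hierarchy_complexity(cenH, list(fs))
  expect_equal(hH$per_hierarchy$argmax_layer, 6L)
  expect_equal(hH$mean_position, 1)
  # seven hierarchies are averaged into one score and reported individually
  hier <- simulate_hierarchies(gl, gh, n_features = 64, seed = 17)
  hs <- hierarchy_complexity(cenH, lapply(hier, center_features))
  expect_equal(nrow(hs$per_hierarchy), 7L)
  expect_equal(hs$per_hierarchy$n_layers, c(5, 13, 12, 16, 17, 14, 8))
  expect_equal(hs$mean_position, mean(hs$per_hierarchy$position))
  expect_gt(hs$mean_position, 0.7)
})
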